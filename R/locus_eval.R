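# Locus scanning, shuffle robustness and evaluation against curated modifier
# lists: the glue for combining the expression screen with association or
# linkage studies.

#' Apply the Step-1 test to the genes of a candidate locus
#'
#' Reports each locus gene's raw overlap p-value against two Bonferroni
#' thresholds at `alpha`: a locus-local one (corrected for the eligible genes
#' of the locus) and a global one (corrected for every eligible gene in the
#' matrix). Genes absent from the matrix or ineligible are reported with a
#' status and no p-value.
#'
#' @param matrix healthy-cohort gene-by-sample matrix.
#' @param gcd_id causal gene identifier.
#' @param locus_genes gene-list data frame or character vector, in locus
#'   position order.
#' @param fraction bottom fraction (default 0.10).
#' @param alpha significance level for both thresholds (default 0.05).
#' @return Data frame `gene_id`, `position_index`, `status`
#'   (`tested` / `missing` / `ineligible`), `p_raw`, `significant_local`,
#'   `significant_global`.
#' @export
locus_step1_scan <- function(matrix, gcd_id, locus_genes, fraction = 0.10,
                             alpha = 0.05) {
  ids <- as_gene_ids(locus_genes)
  step1 <- run_step1(matrix, gcd_id, fraction = fraction, alpha = alpha)
  elig <- setdiff(eligible_genes(matrix, fraction), gcd_id)
  m_global <- length(elig)
  m_local <- sum(ids %in% elig)
  if (m_local == 0L)
    abort_argument("no locus gene is present and eligible in the matrix")
  p <- step1$p_raw[match(ids, step1$gene_id)]
  status <- ifelse(!ids %in% rownames(matrix), "missing",
                   ifelse(!ids %in% elig, "ineligible", "tested"))
  p[status != "tested"] <- NA_real_
  data.frame(gene_id = ids, position_index = seq_along(ids), status = status,
             p_raw = p,
             significant_local = !is.na(p) & p < alpha / m_local,
             significant_global = !is.na(p) & p < alpha / m_global)
}

#' Shuffle-robustness p-value of a Step-1 hit set
#'
#' Randomly permutes the causal gene's expression vector across samples
#' `n_shuffles` times and reports the fraction of shuffles in which at least
#' one gene of `gene_set` still passes the Bonferroni-corrected Step-1 test.
#' A fraction of 0 is best reported as `< 1/n_shuffles` (the formatted bound
#' is attached as the `"label"` attribute).
#'
#' @param matrix healthy-cohort gene-by-sample matrix.
#' @param gcd_id causal gene identifier.
#' @param gene_set genes to screen each shuffle (character vector or
#'   gene-list data frame).
#' @param n_shuffles number of random permutations (default 10000).
#' @param fraction bottom fraction (default 0.10).
#' @param alpha family-wise level of the per-shuffle Bonferroni test
#'   (default 0.01, matching Step 1).
#' @param seed integer seed.
#' @return Numeric fraction in `[0, 1]` with attribute `label`.
#' @export
shuffle_null_pvalue <- function(matrix, gcd_id, gene_set, n_shuffles = 10000L,
                                fraction = 0.10, alpha = 0.01, seed) {
  validate_expression_matrix(matrix)
  if (!is.numeric(n_shuffles) || length(n_shuffles) != 1L || n_shuffles < 1L)
    abort_argument("n_shuffles must be a positive integer")
  if (!gcd_id %in% rownames(matrix))
    abort_missing_gene(sprintf("GCD '%s' absent from the matrix", gcd_id))
  ids <- setdiff(as_gene_ids(gene_set), gcd_id)
  elig <- intersect(ids, eligible_genes(matrix, fraction))
  if (!length(elig)) abort_argument("no eligible gene in gene_set")
  n <- ncol(matrix)
  gcd_vals <- matrix[gcd_id, ]
  k_gcd <- floor(fraction * n)
  low_idx <- low_mask_indices(matrix, elig, fraction)
  n_low <- nrow(low_idx)
  m <- length(elig)
  threshold <- alpha / m
  # per-gene low-set membership, samples x genes
  member <- matrix(FALSE, nrow = n, ncol = m)
  member[cbind(as.vector(low_idx), rep(seq_len(m), each = n_low))] <- TRUE
  set.seed(seed)
  hits <- 0L
  for (s in seq_len(n_shuffles)) {
    shuffled <- gcd_vals[sample.int(n)]
    sel <- order(shuffled)[seq_len(k_gcd)]
    k <- colSums(member[sel, , drop = FALSE])
    p <- stats::phyper(k - 1, k_gcd, n - k_gcd, n_low, lower.tail = FALSE)
    if (any(p < threshold)) hits <- hits + 1L
  }
  frac <- hits / n_shuffles
  attr(frac, "label") <- if (hits == 0L) sprintf("< %g", 1 / n_shuffles)
                         else format(frac)
  frac
}

#' Hypergeometric enrichment of predictions in a reference modifier list
#'
#' Upper-tail probability of the observed overlap between the predicted and
#' reference gene sets within an explicit universe; the same tail computation
#' as the Step-1 overlap test.
#'
#' @param predicted,reference gene sets (character vectors or gene-list data
#'   frames); must be subsets of `universe`.
#' @param universe the gene universe the sets were drawn from.
#' @return Hypergeometric upper-tail p-value.
#' @export
overlap_enrichment <- function(predicted, reference, universe) {
  pred <- unique(as_gene_ids(predicted))
  ref <- unique(as_gene_ids(reference))
  uni <- unique(as_gene_ids(universe))
  off <- c(setdiff(pred, uni), setdiff(ref, uni))
  if (length(off))
    abort_domain(sprintf("gene(s) outside the universe: %s",
                         paste(utils::head(off, 10L), collapse = ", ")))
  hypergeometric_upper_tail(length(uni), length(ref), length(pred),
                            length(intersect(pred, ref)))
}

#' Confusion counts and ratios of predictions against a reference list
#'
#' Reference genes with no measurement in the case-control data can be
#' excluded from the positives via `measured` (they could never be detected at
#' Step 2); a note is emitted when that happens. Ratios with a zero
#' denominator are returned as `NA`, never silently as 0/0.
#'
#' @param predicted,reference gene sets, subsets of `universe`.
#' @param universe the evaluation universe.
#' @param measured optional character vector of genes measured in the
#'   case-control data.
#' @return A list of class `evaluation_summary`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
evaluate_predictions <- function(predicted, reference, universe,
                                 measured = NULL) {
  pred <- unique(as_gene_ids(predicted))
  ref <- unique(as_gene_ids(reference))
  uni <- unique(as_gene_ids(universe))
  off <- c(setdiff(pred, uni), setdiff(ref, uni))
  if (length(off))
    abort_domain(sprintf("gene(s) outside the universe: %s",
                         paste(utils::head(off, 10L), collapse = ", ")))
  if (!is.null(measured)) {
    dropped <- setdiff(ref, as_gene_ids(measured))
    if (length(dropped)) {
      message(sprintf("dropping %d reference gene(s) unmeasured in the case-control data: %s",
                      length(dropped), paste(dropped, collapse = ", ")))
      ref <- setdiff(ref, dropped)
    }
  }
  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref, pred))
  tn <- length(uni) - tp - fp - fn
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %s  specificity %s  PPV %s\n",
              format(x$sensitivity), format(x$specificity), format(x$ppv)))
  invisible(x)
}
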