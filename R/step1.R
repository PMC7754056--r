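# Step 1: potential modifiers (PMs). A PM is a gene whose bottom-fraction
# expression samples significantly overlap the bottom-fraction samples of the
# gene causal of disease (GCD) in healthy tissue, under a Bonferroni-corrected
# hypergeometric upper-tail test.

#' Bottom-fraction sample mask for one gene
#'
#' Selects exactly `floor(fraction * n)` samples with the smallest values.
#' Ties at the boundary are broken deterministically: samples earlier in the
#' cohort's column order are selected first, so the mask is reproducible.
#'
#' @param values numeric vector of per-sample abundances (finite, >= 0),
#'   optionally named by sample identifier.
#' @param fraction fraction of the cohort in the low set; default 0.10, the
#'   conventional bottom-decile cut.
#' @return A list of class `low_mask` with elements `idx` (selected positions,
#'   in the cohort's sample order), `sample_ids_selected` (names, if `values`
#'   is named), `fraction` and `k_low`.
#' @export
low_expression_mask <- function(values, fraction = 0.10) {
  if (!is.numeric(values) || any(!is.finite(values)))
    abort_value("expression values must be finite numbers")
  if (any(values < 0)) abort_value("expression values must be >= 0")
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    abort_argument("fraction must be a single number in (0, 1)")
  k_low <- floor(fraction * length(values))
  if (k_low < 1L)
    abort_sample_size(sprintf(
      "cohort too small: floor(%g x %d) < 1 sample in the low set",
      fraction, length(values)))
  # order() is stable: among tied values the earlier sample wins.
  idx <- sort(order(values)[seq_len(k_low)])
  structure(list(idx = idx,
                 sample_ids_selected = if (!is.null(names(values))) names(values)[idx],
                 fraction = fraction, k_low = as.integer(k_low)),
            class = "low_mask")
}

#' Genes eligible for the bottom-fraction overlap test
#'
#' A gene is eligible when its low mask is meaningful: its values are not
#' constant, and fewer than `n - k_low` samples are tied at the minimum (so
#' selecting the bottom `k_low` is not an arbitrary choice over a majority of
#' tied zeros, a common situation for lowly expressed genes).
#'
#' @param matrix gene-by-sample numeric matrix.
#' @param fraction low-set fraction (default 0.10).
#' @return Character vector of eligible gene identifiers, in matrix order.
#' @export
eligible_genes <- function(matrix, fraction = 0.10) {
  validate_expression_matrix(matrix)
  n <- ncol(matrix)
  k_low <- floor(fraction * n)
  if (k_low < 1L)
    abort_sample_size(sprintf("cohort too small for fraction %g", fraction))
  mins <- apply(matrix, 1L, min)
  maxs <- apply(matrix, 1L, max)
  ties_at_min <- rowSums(matrix == mins)
  rownames(matrix)[maxs > mins & ties_at_min < (n - k_low)]
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability that a size-`n` draw from a population of `N` with `K` marked
#' members contains `k` or more marked members; the tail is evaluated in
#' log space by the underlying distribution function, so tiny p-values keep
#' full relative precision.
#'
#' @param N population size.
#' @param K marked members.
#' @param n draw size.
#' @param k observed overlap; must lie in `[max(0, K + n - N), min(K, n)]`.
#' @return p-value in (0, 1].
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  for (v in list(N, K, n, k))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v))
      abort_domain("N, K, n, k must be single integers")
  if (K < 0 || n < 0 || K > N || n > N)
    abort_domain("require 0 <= K, n <= N")
  if (k < max(0, K + n - N) || k > min(K, n))
    abort_domain(sprintf("k = %d outside support [%d, %d]",
                         k, max(0, K + n - N), min(K, n)))
  if (k <= max(0, K + n - N)) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Low-mask index matrix (k_low x n_genes) for a set of rows of `matrix`;
# shared by run_step1 and the shuffle-null routine.
low_mask_indices <- function(matrix, gene_ids, fraction) {
  n <- ncol(matrix)
  k_low <- floor(fraction * n)
  idx <- vapply(gene_ids,
                function(g) sort(order(matrix[g, ])[seq_len(k_low)]),
                integer(k_low))
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = k_low,
                                     dimnames = list(NULL, gene_ids))
  idx
}

#' Run Step 1: flag potential modifiers of a causal gene
#'
#' For every eligible gene except the GCD itself, tests whether the gene's
#' bottom-fraction samples overlap the GCD's bottom-fraction samples more than
#' chance predicts. Family-wise error is controlled by Bonferroni over the
#' `m` genes actually tested: a gene is a PM when `p_raw < alpha / m`.
#'
#' @param matrix healthy-cohort gene-by-sample numeric matrix.
#' @param gcd_id identifier of the gene causal of disease.
#' @param fraction bottom fraction defining the GCD low set (default 0.10).
#' @param alpha family-wise significance level (default 0.01).
#' @param gene_fraction bottom fraction for candidate genes; defaults to
#'   `fraction`. Exposed separately so threshold sensitivity can be probed on
#'   either side of the overlap.
#' @return Data frame with columns `gene_id`, `N`, `K`, `n`, `k`, `p_raw`,
#'   `p_bonferroni`, `is_pm`, sorted by `p_raw` (ties by gene id).
#' @export
run_step1 <- function(matrix, gcd_id, fraction = 0.10, alpha = 0.01,
                      gene_fraction = fraction) {
  validate_expression_matrix(matrix)
  if (!gcd_id %in% rownames(matrix))
    abort_missing_gene(sprintf("GCD '%s' absent from the matrix", gcd_id))
  if (!gcd_id %in% eligible_genes(matrix, fraction))
    abort_eligibility(sprintf("GCD '%s' is not eligible at fraction %g",
                              gcd_id, fraction))
  genes <- setdiff(eligible_genes(matrix, gene_fraction), gcd_id)
  N <- ncol(matrix)
  gcd_mask <- low_expression_mask(matrix[gcd_id, ], fraction)
  K <- gcd_mask$k_low
  m <- length(genes)
  if (m == 0L)
    return(data.frame(gene_id = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), is_pm = logical()))
  low_idx <- low_mask_indices(matrix, genes, gene_fraction)
  in_gcd_low <- logical(N)
  in_gcd_low[gcd_mask$idx] <- TRUE
  k <- colSums(matrix(in_gcd_low[low_idx], nrow = nrow(low_idx)))
  n_low <- nrow(low_idx)
  p_raw <- stats::phyper(k - 1, K, N - K, n_low, lower.tail = FALSE)
  p_raw[k == max(0, K + n_low - N)] <- 1
  out <- data.frame(gene_id = genes, N = N, K = K, n = n_low, k = as.integer(k),
                    p_raw = p_raw, p_bonferroni = pmin(1, m * p_raw),
                    is_pm = p_raw < alpha / m)
  out <- out[order(out$p_raw, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect PM calls across tissues
#'
#' When several tissues are affected, Step 1 is run per tissue and only genes
#' flagged in every tissue are carried to Step 2.
#'
#' @param pm_sets list of Step-1 result data frames (or character vectors of
#'   PM gene identifiers).
#' @return Sorted character vector of genes flagged in every input set.
#' @export
intersect_tissues <- function(pm_sets) {
  if (!is.list(pm_sets) || !length(pm_sets))
    abort_argument("pm_sets must be a non-empty list")
  sets <- lapply(pm_sets, function(x) {
    if (is.data.frame(x)) x$gene_id[x$is_pm] else as.character(x)
  })
  sort(Reduce(intersect, sets))
}
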