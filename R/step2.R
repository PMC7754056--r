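# Step 2: disease-associated potential modifiers (DPMs). A PM survives when
# its case-vs-control downregulation is NOT as strong as its downregulation in
# GCD-low versus other healthy samples. Because the case-control data come
# from a different platform and possibly a different tissue, the comparison is
# made on ordered-pair counts -- a rank construction that is invariant to any
# strictly increasing transform applied within either dataset.

#' Count strictly lower ordered pairs between two groups
#'
#' Number of ordered pairs `(a, b)` with `a` from `group_a`, `b` from
#' `group_b` and `a < b`; ties contribute nothing.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return Integer in `[0, length(a) * length(b)]`.
#' @export
count_lower_pairs <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    abort_argument("both groups must be non-empty")
  if (any(!is.finite(group_a)) || any(!is.finite(group_b)))
    abort_value("pair counting requires finite values")
  sum(outer(group_a, group_b, `<`))
}

#' Sample the null distribution of pair counts from the healthy cohort
#'
#' Each replicate draws `n_cases` samples without replacement from the GCD-low
#' stratum and `n_controls` from its complement, then counts pairs where the
#' PM's value in the low draw falls strictly below its value in the not-low
#' draw. This is the reference behaviour of a gene whose expression tracks the
#' GCD; a candidate modifier's case-control pair count is judged against it.
#'
#' @param pm_values named numeric vector of the PM's healthy per-sample values.
#' @param gcd_low_samples sample identifiers of the GCD-low stratum.
#' @param n_cases,n_controls draw sizes, matching the real study arms.
#' @param reps number of replicates (default 10000).
#' @param seed integer seed; the returned sequence is a deterministic function
#'   of it.
#' @return A list of class `null_pair_counts` with `counts` (length `reps`),
#'   `max_pairs` and `rng_seed`.
#' @export
sample_null_pair_counts <- function(pm_values, gcd_low_samples, n_cases,
                                    n_controls, reps = 10000L, seed) {
  if (is.null(names(pm_values)))
    abort_argument("pm_values must be named by sample identifier")
  if (reps < 1L) abort_argument("reps must be >= 1")
  low <- match(gcd_low_samples, names(pm_values))
  if (anyNA(low)) abort_argument("gcd_low_samples must all name pm_values entries")
  high <- setdiff(seq_along(pm_values), low)
  if (length(low) < n_cases)
    abort_sample_size(sprintf(
      "GCD-low stratum has %d samples, fewer than the %d cases required",
      length(low), n_cases))
  if (length(high) < n_controls)
    abort_sample_size(sprintf(
      "not-low stratum has %d samples, fewer than the %d controls required",
      length(high), n_controls))
  v_low <- pm_values[low]; v_high <- pm_values[high]
  set.seed(seed)
  counts <- integer(reps)
  for (i in seq_len(reps)) {
    a <- v_low[sample.int(length(v_low), n_cases)]
    b <- v_high[sample.int(length(v_high), n_controls)]
    counts[i] <- sum(outer(a, b, `<`))
  }
  structure(list(counts = counts,
                 max_pairs = as.integer(n_cases) * as.integer(n_controls),
                 rng_seed = as.integer(seed)),
            class = "null_pair_counts")
}

#' Empirical p-value of a disease pair count against the sampled null
#'
#' `T` counts null replicates whose pair count is not exceeded by the observed
#' disease pair count (`observed >= P_i`); the p-value is `T / reps`, with no
#' add-one smoothing, so 0 is attainable. A small p-value means the disease
#' samples show a weaker drop than the healthy GCD-low stratum predicts --
#' evidence that the gene is not simply co-expressed with the GCD in disease.
#'
#' @param disease_pair_count observed `count_lower_pairs(cases, controls)`.
#' @param null_counts a `null_pair_counts` object.
#' @return p-value in `[0, 1]`.
#' @export
empirical_dpm_pvalue <- function(disease_pair_count, null_counts) {
  if (!inherits(null_counts, "null_pair_counts"))
    abort_argument("null_counts must come from sample_null_pair_counts()")
  sum(disease_pair_count >= null_counts$counts) / length(null_counts$counts)
}

#' Run Step 2: filter PMs to disease-associated PMs
#'
#' For each PM measured in the case-control study, compares the observed
#' case-vs-control pair count to the null distribution resampled from the
#' healthy cohort's GCD-low / not-low strata at the study's arm sizes. A PM
#' becomes a DPM when the empirical p-value falls below `alpha`; PMs absent
#' from the study matrix are reported as `not_measured`. Per-gene random
#' substreams are derived from the master seed and the gene identifier, so
#' results do not depend on gene order.
#'
#' @param pm_genes character vector (or gene-list data frame) of Step-1 PMs.
#' @param healthy healthy-cohort gene-by-sample matrix.
#' @param gcd_id identifier of the gene causal of disease.
#' @param study a `case_control_study`.
#' @param fraction GCD low-set fraction (default 0.10).
#' @param reps null replicates per gene (default 10000).
#' @param alpha decision threshold on the empirical p-value (default 0.05,
#'   uncorrected across PMs by design).
#' @param seed master integer seed.
#' @return Data frame with columns `gene_id`, `disease_pair_count`,
#'   `max_pairs`, `T`, `reps`, `p_empirical`, `status`
#'   (`dpm` / `rejected` / `not_measured`), in input gene order.
#' @export
run_step2 <- function(pm_genes, healthy, gcd_id, study, fraction = 0.10,
                      reps = 10000L, alpha = 0.05, seed) {
  validate_expression_matrix(healthy)
  if (!inherits(study, "case_control_study"))
    abort_argument("study must be a case_control_study")
  pm_genes <- as_gene_ids(pm_genes)
  missing_h <- setdiff(pm_genes, rownames(healthy))
  if (length(missing_h))
    abort_missing_gene(sprintf("PM gene(s) absent from healthy matrix: %s",
                               paste(utils::head(missing_h, 5L), collapse = ", ")))
  if (!gcd_id %in% rownames(healthy))
    abort_missing_gene(sprintf("GCD '%s' absent from healthy matrix", gcd_id))
  n_cases <- length(study$case_ids)
  n_controls <- length(study$control_ids)
  gcd_mask <- low_expression_mask(healthy[gcd_id, ], fraction)
  low_ids <- colnames(healthy)[gcd_mask$idx]
  if (length(low_ids) < n_cases)
    abort_sample_size(sprintf(
      "GCD-low stratum (%d) smaller than the case arm (%d)",
      length(low_ids), n_cases))
  if (ncol(healthy) - length(low_ids) < n_controls)
    abort_sample_size(sprintf(
      "not-low stratum (%d) smaller than the control arm (%d)",
      ncol(healthy) - length(low_ids), n_controls))
  max_pairs <- n_cases * n_controls
  rows <- lapply(pm_genes, function(g) {
    if (!g %in% rownames(study$matrix)) {
      return(data.frame(gene_id = g, disease_pair_count = NA_integer_,
                        max_pairs = max_pairs, T = NA_integer_,
                        reps = as.integer(reps), p_empirical = NA_real_,
                        status = "not_measured"))
    }
    obs <- count_lower_pairs(study$matrix[g, study$case_ids],
                             study$matrix[g, study$control_ids])
    null <- sample_null_pair_counts(healthy[g, ], low_ids, n_cases, n_controls,
                                    reps = reps, seed = derive_seed(seed, g))
    p <- empirical_dpm_pvalue(obs, null)
    data.frame(gene_id = g, disease_pair_count = as.integer(obs),
               max_pairs = max_pairs,
               T = as.integer(round(p * reps)), reps = as.integer(reps),
               p_empirical = p,
               status = if (p < alpha) "dpm" else "rejected")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
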