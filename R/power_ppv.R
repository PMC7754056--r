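# Resampling estimates of Step-2 operating characteristics, computed from the
# healthy matrix alone: detection power at a prospective case/control size N
# (type-II control) and type-I error / prospective predictive value.

step2_test_once <- function(pm_values, low_ids, case_vals, control_vals,
                            reps, alpha, seed, null = NULL) {
  obs <- count_lower_pairs(case_vals, control_vals)
  if (is.null(null))
    null <- sample_null_pair_counts(pm_values, low_ids, length(case_vals),
                                    length(control_vals), reps = reps, seed = seed)
  empirical_dpm_pvalue(obs, null) < alpha
}

#' Detection confidence for one PM at case/control size N
#'
#' Emulates the favourable scenario where the PM is a true modifier: both
#' pseudo-arms are drawn from the GCD-low stratum, so the pseudo-cases are not
#' extra-low in the PM and Step 2 should accept. Each of the `R` replicates
#' runs the full Step-2 test (a fresh null is resampled every time); the
#' confidence is the fraction of replicates that accept. When `2N` fits in
#' the stratum the two pseudo-arms are drawn jointly without replacement and
#' are disjoint; otherwise they are independent draws that may overlap, with
#' a warning.
#'
#' @param healthy healthy-cohort gene-by-sample matrix.
#' @param gcd_id causal gene identifier.
#' @param pm_id PM gene identifier.
#' @param N per-arm pseudo-sample count.
#' @param R replicates (default 10).
#' @param fraction GCD low-set fraction (default 0.10).
#' @param reps Step-2 null replicates per run (default 10000).
#' @param alpha Step-2 decision threshold (default 0.05).
#' @param seed master integer seed.
#' @return One-row data frame: `gene_id`, `N`, `R`, `accepted_count`,
#'   `confidence`.
#' @export
dpm_detection_confidence <- function(healthy, gcd_id, pm_id, N, R = 10L,
                                     fraction = 0.10, reps = 10000L,
                                     alpha = 0.05, seed) {
  validate_expression_matrix(healthy)
  for (g in c(gcd_id, pm_id))
    if (!g %in% rownames(healthy))
      abort_missing_gene(sprintf("gene '%s' absent from the matrix", g))
  mask <- low_expression_mask(healthy[gcd_id, ], fraction)
  low_ids <- colnames(healthy)[mask$idx]
  if (N > length(low_ids))
    abort_sample_size(sprintf("N = %d exceeds the GCD-low stratum (%d samples)",
                              N, length(low_ids)))
  pm_vals <- healthy[pm_id, ]
  pm_low <- pm_vals[low_ids]
  overlap_ok <- 2L * N <= length(low_ids)
  if (!overlap_ok)
    warning(sprintf(
      "2N = %d exceeds the GCD-low stratum (%d); pseudo-arms drawn independently and may overlap",
      2L * N, length(low_ids)), call. = FALSE)
  accepted <- 0L
  for (r in seq_len(R)) {
    set.seed(derive_seed(seed, sprintf("power/%s/%d/%d", pm_id, N, r)))
    if (overlap_ok) {
      pick <- sample.int(length(pm_low), 2L * N)
      cases <- pm_low[pick[seq_len(N)]]
      controls <- pm_low[pick[N + seq_len(N)]]
    } else {
      cases <- pm_low[sample.int(length(pm_low), N)]
      controls <- pm_low[sample.int(length(pm_low), N)]
    }
    hit <- step2_test_once(pm_vals, low_ids, cases, controls, reps, alpha,
                           seed = derive_seed(seed, sprintf("power-null/%s/%d/%d", pm_id, N, r)))
    accepted <- accepted + hit
  }
  data.frame(gene_id = pm_id, N = as.integer(N), R = as.integer(R),
             accepted_count = as.integer(accepted), confidence = accepted / R)
}

#' Minimal case/control size meeting an average-confidence threshold
#'
#' Evaluates [dpm_detection_confidence()] for every PM at each size in an
#' ascending grid and returns the smallest size whose mean confidence across
#' PMs reaches the threshold (0.8 by default). A grid search is used rather
#' than bisection because the Monte-Carlo confidence is not strictly
#' monotone.
#'
#' @inheritParams dpm_detection_confidence
#' @param pm_list character vector (or gene-list data frame) of PMs.
#' @param n_grid ascending integer vector of candidate per-arm sizes.
#' @param threshold required mean confidence (default 0.8).
#' @return A list of class `minimal_n_result`: `minimal_n` (integer, or `NA`
#'   if never reached), `grid` (data frame `N`, `mean_confidence`) and
#'   `per_gene` (all per-PM rows).
#' @export
minimal_case_control_size <- function(healthy, gcd_id, pm_list, n_grid,
                                      threshold = 0.8, R = 10L,
                                      fraction = 0.10, reps = 10000L,
                                      alpha = 0.05, seed) {
  if (!length(n_grid)) abort_argument("n_grid must be non-empty")
  if (is.unsorted(n_grid, strictly = TRUE)) abort_argument("n_grid must be strictly ascending")
  pm_list <- as_gene_ids(pm_list)
  rows <- list()
  for (N in n_grid) {
    for (g in pm_list)
      rows[[length(rows) + 1L]] <-
        dpm_detection_confidence(healthy, gcd_id, g, N, R = R,
                                 fraction = fraction, reps = reps,
                                 alpha = alpha, seed = seed)
  }
  per_gene <- do.call(rbind, rows)
  grid <- stats::aggregate(confidence ~ N, data = per_gene, FUN = mean)
  names(grid)[2L] <- "mean_confidence"
  grid <- grid[order(grid$N), , drop = FALSE]
  hit <- which(grid$mean_confidence >= threshold)
  structure(list(minimal_n = if (length(hit)) grid$N[hit[1L]] else NA_integer_,
                 grid = grid, per_gene = per_gene),
            class = "minimal_n_result")
}

#' @export
print.minimal_n_result <- function(x, ...) {
  print(x$grid)
  cat(if (is.na(x$minimal_n)) "threshold never reached on the grid\n"
      else sprintf("minimal N meeting the threshold: %d\n", x$minimal_n))
  invisible(x)
}

#' Type-I error of Step 2 under the null, per PM
#'
#' Emulates the unfavourable scenario: pseudo-cases are drawn from the
#' GCD-low stratum and pseudo-controls from its complement, so the PM's
#' healthy co-expression pattern holds and any Step-2 acceptance is a false
#' positive. One null pair-count distribution is sampled per PM (it depends
#' only on the PM, the strata and N) and each pseudo-study replicate is
#' scored against it.
#'
#' @inheritParams dpm_detection_confidence
#' @param pm_list character vector (or gene-list data frame) of PMs.
#' @param replicates pseudo-study replicates per PM (default 100).
#' @return A list of class `type1_summary`: `estimates` (data frame
#'   `gene_id`, `N`, `replicates`, `rejection_rate`) and `fraction_controlled`
#'   (share of PMs with rejection rate below `alpha`).
#' @export
type1_error_summary <- function(healthy, gcd_id, pm_list, N, replicates = 100L,
                                fraction = 0.10, reps = 10000L, alpha = 0.05,
                                seed) {
  validate_expression_matrix(healthy)
  pm_list <- as_gene_ids(pm_list)
  if (!gcd_id %in% rownames(healthy))
    abort_missing_gene(sprintf("GCD '%s' absent from the matrix", gcd_id))
  mask <- low_expression_mask(healthy[gcd_id, ], fraction)
  low_ids <- colnames(healthy)[mask$idx]
  high_ids <- setdiff(colnames(healthy), low_ids)
  if (N > length(low_ids))
    abort_sample_size(sprintf("N = %d exceeds the GCD-low stratum (%d)", N, length(low_ids)))
  if (N > length(high_ids))
    abort_sample_size(sprintf("N = %d exceeds the not-low stratum (%d)", N, length(high_ids)))
  rows <- lapply(pm_list, function(g) {
    if (!g %in% rownames(healthy))
      abort_missing_gene(sprintf("PM '%s' absent from the matrix", g))
    pm_vals <- healthy[g, ]
    null <- sample_null_pair_counts(pm_vals, low_ids, N, N, reps = reps,
                                    seed = derive_seed(seed, paste0("t1-null/", g)))
    pm_low <- pm_vals[low_ids]; pm_high <- pm_vals[high_ids]
    set.seed(derive_seed(seed, paste0("t1-draws/", g)))
    rejections <- 0L
    for (r in seq_len(replicates)) {
      cases <- pm_low[sample.int(length(pm_low), N)]
      controls <- pm_high[sample.int(length(pm_high), N)]
      p <- empirical_dpm_pvalue(count_lower_pairs(cases, controls), null)
      rejections <- rejections + (p < alpha)
    }
    data.frame(gene_id = g, N = as.integer(N),
               replicates = as.integer(replicates),
               rejection_rate = rejections / replicates)
  })
  estimates <- do.call(rbind, rows)
  structure(list(estimates = estimates,
                 fraction_controlled = mean(estimates$rejection_rate < alpha)),
            class = "type1_summary")
}

#' @export
print.type1_summary <- function(x, ...) {
  print(x$estimates)
  cat(sprintf("fraction of PMs with type-I error below alpha: %.3f\n",
              x$fraction_controlled))
  invisible(x)
}
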