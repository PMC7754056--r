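# Step 3 (disease-specific): rank DPMs by one-sided rank-sum association
# between low candidate expression and a high full-length/truncated isoform
# ratio of a compensating paralog in the healthy cohort. The motivating
# instance is SMA, where a high ratio of exon-included to exon-skipped SMN2
# transcript marks compensating splicing; the implementation is generic over
# any isoform pair.

#' Read a per-sample isoform pair table
#'
#' Three tab-separated columns: sample identifier, full-length (exon-included)
#' abundance, truncated (exon-skipped) abundance. A header row is detected and
#' skipped.
#'
#' @param path path to the TSV.
#' @return Data frame with columns `sample_id`, `fl`, `trunc`.
#' @export
read_isoform_pair <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- split_tsv_lines(lines)
  if (any(lengths(parts) < 3L))
    abort_format("isoform file must have three tab-separated columns")
  if (is.na(suppressWarnings(as.numeric(parts[[1L]][2L])))) parts <- parts[-1L]
  out <- data.frame(sample_id = vapply(parts, `[[`, character(1L), 1L),
                    fl = as.numeric(vapply(parts, `[[`, character(1L), 2L)),
                    trunc = as.numeric(vapply(parts, `[[`, character(1L), 3L)))
  if (anyNA(out$fl) || anyNA(out$trunc)) abort_value("non-numeric isoform abundance")
  if (any(out$fl < 0) || any(out$trunc < 0)) abort_value("isoform abundances must be >= 0")
  if (anyDuplicated(out$sample_id)) abort_duplicate("duplicate sample identifiers in isoform file")
  out
}

#' Partition samples by full-length / truncated isoform ratio
#'
#' A sample is `high` when the full-length abundance strictly exceeds the
#' truncated one (equivalent to ratio > 1, but defined even when the truncated
#' abundance is 0). Samples with equal abundances -- including 0/0, common for
#' lowly expressed transcripts -- are excluded rather than assigned.
#'
#' @param pair data frame with columns `sample_id`, `fl`, `trunc` (see
#'   [read_isoform_pair()]).
#' @return A list of class `ratio_groups` with character vectors
#'   `high_ratio_samples`, `low_ratio_samples`, `excluded_samples`.
#' @export
ratio_groups <- function(pair) {
  if (!is.data.frame(pair) || !all(c("sample_id", "fl", "trunc") %in% names(pair)))
    abort_argument("pair must have columns sample_id, fl, trunc")
  if (!nrow(pair)) abort_argument("isoform pair table is empty")
  high <- pair$sample_id[pair$fl > pair$trunc]
  low <- pair$sample_id[pair$fl < pair$trunc]
  excl <- pair$sample_id[pair$fl == pair$trunc]
  if (!length(high) || !length(low))
    abort_partition(sprintf(
      "degenerate ratio partition: %d high, %d low (%d excluded ties)",
      length(high), length(low), length(excl)))
  structure(list(high_ratio_samples = high, low_ratio_samples = low,
                 excluded_samples = excl),
            class = "ratio_groups")
}

#' One-sided rank-sum test that the high-ratio group expresses lower
#'
#' Tests the alternative that values in `values_high_group` are stochastically
#' smaller than in `values_low_group`. For a combined size of at most 12 the
#' p-value is exact: every assignment of the pooled values to the two groups
#' is enumerated and `P(rank sum <= observed)` reported, observed assignment
#' included (no mid-p). Larger samples use the normal approximation with
#' midrank tie correction and a 0.5 continuity correction.
#'
#' @param values_high_group,values_low_group non-empty numeric vectors.
#' @return One-sided p-value in (0, 1].
#' @export
rank_sum_one_sided <- function(values_high_group, values_low_group) {
  a <- as.numeric(values_high_group); b <- as.numeric(values_low_group)
  if (!length(a) || !length(b)) abort_argument("both groups must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort_value("values must be finite")
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  r <- rank(pooled)  # midranks under ties
  s_obs <- sum(r[seq_len(n1)])
  if (n <= 12L) {
    combos <- utils::combn(n, n1)
    s_perm <- colSums(matrix(r[combos], nrow = n1))
    return(mean(s_perm <= s_obs + 1e-9))
  }
  n2 <- n - n1
  ties <- table(pooled)
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all values tied: no evidence either way
  stats::pnorm((s_obs - mu + 0.5) / sqrt(sigma2))
}

#' Run Step 3: rank DPMs by isoform-ratio association
#'
#' Splits the healthy cohort by the compensating paralog's isoform ratio and
#' scores each DPM with the one-sided rank-sum test for lower expression in
#' the high-ratio group. The resulting order is a ranking criterion: the
#' top-ranked gene is the pipeline's headline candidate.
#'
#' @param dpms Step-2 result data frame (rows with `status == "dpm"` are
#'   used) or a character vector of DPM gene identifiers.
#' @param healthy healthy-cohort gene-by-sample matrix.
#' @param pair isoform pair data frame (`sample_id`, `fl`, `trunc`); sample
#'   identifiers must be present among the healthy matrix columns.
#' @return Data frame with columns `gene_id`, `p_ranksum`, `rank`, sorted by
#'   p-value ascending (ties by gene id).
#' @export
run_step3 <- function(dpms, healthy, pair) {
  validate_expression_matrix(healthy)
  genes <- if (is.data.frame(dpms) && "status" %in% names(dpms))
    dpms$gene_id[dpms$status == "dpm"] else as_gene_ids(dpms)
  if (!length(genes)) abort_argument("no DPM genes to rank")
  missing <- setdiff(genes, rownames(healthy))
  if (length(missing))
    abort_missing_gene(sprintf("DPM gene(s) absent from healthy matrix: %s",
                               paste(utils::head(missing, 5L), collapse = ", ")))
  if (!all(pair$sample_id %in% colnames(healthy)))
    abort_argument("isoform samples must all appear in the healthy matrix")
  groups <- ratio_groups(pair)
  p <- vapply(genes, function(g)
    rank_sum_one_sided(healthy[g, groups$high_ratio_samples],
                       healthy[g, groups$low_ratio_samples]), numeric(1L))
  out <- data.frame(gene_id = genes, p_ranksum = unname(p))
  out <- out[order(out$p_ranksum, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
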