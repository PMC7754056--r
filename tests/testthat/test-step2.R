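test_that("pair counting is strict and conserves the pair total", {
  expect_identical(count_lower_pairs(c(1, 2), c(3, 4)), 4L)
  expect_identical(count_lower_pairs(c(3, 4), c(1, 2)), 0L)
  expect_identical(count_lower_pairs(c(1, 3), c(3, 5)), 3L)
  expect_error(count_lower_pairs(numeric(0), 1), class = "gendulf_argument_error")

  set.seed(4)
  for (i in 1:20) {
    a <- sample(0:5, 6, replace = TRUE)
    b <- sample(0:5, 4, replace = TRUE)
    ties <- sum(outer(a, b, `==`))
    expect_identical(count_lower_pairs(a, b) + count_lower_pairs(b, a) + ties,
                     length(a) * length(b))
  }
})

test_that("empirical p-value counts null replicates not exceeding the observation", {
  null <- structure(list(counts = c(2L, 4L, 6L, 8L), max_pairs = 9L,
                         rng_seed = 1L), class = "null_pair_counts")
  expect_equal(empirical_dpm_pvalue(5, null), 0.5)
  expect_equal(empirical_dpm_pvalue(9, null), 1.0)
  expect_equal(empirical_dpm_pvalue(0, null), 0.0)
  # monotone in the observed count
  p <- vapply(0:9, empirical_dpm_pvalue, numeric(1), null_counts = null)
  expect_true(all(diff(p) >= 0))
})

test_that("null sampling respects strata, separation and determinism", {
  v <- stats::setNames(c(1:6 / 10, 6:11), paste0("s", 1:12))
  low <- paste0("s", 1:6)
  null <- sample_null_pair_counts(v, low, 3, 3, reps = 5, seed = 7)
  expect_length(null$counts, 5L)
  expect_true(all(null$counts == 9L))  # perfect separation

  again <- sample_null_pair_counts(v, low, 3, 3, reps = 5, seed = 7)
  expect_identical(null$counts, again$counts)

  expect_error(sample_null_pair_counts(v, low, 7, 3, reps = 5, seed = 1),
               class = "gendulf_sample_size_error")
  expect_error(sample_null_pair_counts(v, low, 3, 7, reps = 5, seed = 1),
               class = "gendulf_sample_size_error")
})

test_that("run_step2 flags extreme both-way separation and unmeasured genes", {
  # healthy: pm low exactly where gcd low; study: pm higher in cases
  set.seed(2)
  n <- 40L
  gcd <- stats::setNames(seq_len(n) + stats::runif(n, 0, 0.1), sprintf("h%02d", 1:n))
  pm <- gcd + stats::runif(n, 0, 0.01)  # same order: pm low when gcd low
  healthy <- rbind(GCD = gcd, PM = pm, OTHER = rev(gcd))
  colnames(healthy) <- names(gcd)

  study_mat <- rbind(GCD = c(0.1, 0.2, 5, 6),
                     PM = c(9, 10, 1, 2))
  colnames(study_mat) <- c("d1", "d2", "c1", "c2")
  study <- case_control_study(study_mat, c("d1", "d2"), c("c1", "c2"))

  res <- run_step2(c("PM", "OTHER"), healthy, "GCD", study,
                   reps = 500, seed = 11)
  pm_row <- res[res$gene_id == "PM", ]
  expect_identical(pm_row$status, "dpm")
  expect_equal(pm_row$p_empirical, 0.0)
  expect_identical(pm_row$disease_pair_count, 0L)
  expect_identical(res[res$gene_id == "OTHER", "status"], "not_measured")
  expect_true(is.na(res[res$gene_id == "OTHER", "p_empirical"]))
})

test_that("run_step2 is deterministic under a fixed seed and gene-order invariant", {
  m <- toy_matrix(n_genes = 8, n_samples = 60, seed = 21)
  study_mat <- toy_matrix(n_genes = 8, n_samples = 10, seed = 22)
  colnames(study_mat) <- c(sprintf("d%d", 1:5), sprintf("c%d", 1:5))
  study <- case_control_study(study_mat, sprintf("d%d", 1:5), sprintf("c%d", 1:5))
  genes <- c("G002", "G003", "G004")
  r1 <- run_step2(genes, m, "G001", study, reps = 300, seed = 5)
  r2 <- run_step2(rev(genes), m, "G001", study, reps = 300, seed = 5)
  r2 <- r2[match(r1$gene_id, r2$gene_id), , drop = FALSE]
  rownames(r2) <- NULL
  expect_identical(r1, r2)
  r3 <- run_step2(genes, m, "G001", study, reps = 300, seed = 5)
  expect_identical(r1, r3)
})

test_that("step-2 records are invariant to monotone transforms of either matrix", {
  m <- toy_matrix(n_genes = 6, n_samples = 60, seed = 31)
  study_mat <- toy_matrix(n_genes = 6, n_samples = 8, seed = 32)
  colnames(study_mat) <- c(sprintf("d%d", 1:4), sprintf("c%d", 1:4))
  mk_study <- function(vals) case_control_study(vals, sprintf("d%d", 1:4),
                                                sprintf("c%d", 1:4))
  genes <- c("G002", "G005")
  base <- run_step2(genes, m, "G001", mk_study(study_mat), reps = 400, seed = 9)
  warped_study <- run_step2(genes, m, "G001", mk_study(study_mat^3 + 1),
                            reps = 400, seed = 9)
  expect_identical(base, warped_study)
  warped_healthy <- run_step2(genes, log1p(m) * 7, "G001", mk_study(study_mat),
                              reps = 400, seed = 9)
  expect_identical(base, warped_healthy)
})

test_that("stratum-size violations abort before any gene is processed", {
  m <- toy_matrix(n_genes = 4, n_samples = 30, seed = 41)  # k_low = 3
  study_mat <- toy_matrix(n_genes = 4, n_samples = 10, seed = 42)
  colnames(study_mat) <- c(sprintf("d%d", 1:5), sprintf("c%d", 1:5))
  study <- case_control_study(study_mat, sprintf("d%d", 1:5), sprintf("c%d", 1:5))
  expect_error(run_step2("G002", m, "G001", study, reps = 100, seed = 1),
               class = "gendulf_sample_size_error")
})
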