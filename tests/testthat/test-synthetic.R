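test_that("cohort specs validate their invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_planted_pm = 600, n_decoy_coregulated = 500),
               class = "gendulf_spec_error")
  expect_error(cohort_spec(n_true_dpm = 60, n_planted_pm = 50),
               class = "gendulf_spec_error")
  expect_error(cohort_spec(coupling_rho = 1.2), class = "gendulf_spec_error")
  expect_error(cohort_spec(decoy_case_effect = 0), class = "gendulf_spec_error")
})

test_that("generated data satisfy the matrix invariants and label partition", {
  spec <- cohort_spec(n_samples = 60, n_genes = 40, n_planted_pm = 6,
                      n_decoy_coregulated = 4, n_true_dpm = 4, seed = 2)
  sim <- simulate_healthy(spec)
  expect_silent(validate_expression_matrix(sim$matrix))
  expect_identical(dim(sim$matrix), c(40L, 60L))
  expect_identical(sum(sim$truth$label == "gcd"), 1L)
  expect_identical(nrow(sim$truth), 40L)
  expect_identical(sum(sim$truth$label == "step3_modifier"), 2L)

  study <- simulate_case_control(spec, sim$truth)
  expect_s3_class(study, "case_control_study")
  expect_length(study$case_ids, spec$n_cases)
  expect_silent(validate_expression_matrix(study$matrix))
})

test_that("the generator is a pure function of the spec", {
  spec <- cohort_spec(n_samples = 50, n_genes = 30, n_planted_pm = 5,
                      n_decoy_coregulated = 3, n_true_dpm = 3, seed = 77)
  a <- simulate_healthy(spec); b <- simulate_healthy(spec)
  expect_identical(a, b)
  expect_identical(simulate_case_control(spec, a$truth),
                   simulate_case_control(spec, b$truth))
  expect_identical(simulate_isoforms(spec, a$truth, a$matrix),
                   simulate_isoforms(spec, b$truth, b$matrix))
})

test_that("copula lower-tail co-occurrence matches the bivariate-normal oracle", {
  spec <- cohort_spec(seed = 8)
  sim <- simulate_healthy(spec)
  gcd <- sim$matrix["G0001", ]
  planted <- sim$truth$gene_id[grepl("planted|step3", sim$truth$label)]
  q_gcd <- stats::quantile(gcd, 0.1, type = 1)
  cooc <- vapply(planted, function(g) {
    v <- sim$matrix[g, ]
    mean(v[gcd <= q_gcd] <= stats::quantile(v, 0.1, type = 1))
  }, numeric(1))
  # Monte-Carlo oracle of P(Z2 in bottom decile | Z1 in bottom decile)
  set.seed(1)
  z1 <- rnorm(2e5); z2 <- spec$coupling_rho * z1 +
    sqrt(1 - spec$coupling_rho^2) * rnorm(2e5)
  oracle <- mean(z2[z1 <= stats::quantile(z1, 0.1)] <= stats::quantile(z2, 0.1))
  expect_lt(abs(mean(cooc) - oracle), 0.02)
  # and far above the independent baseline of 0.1
  expect_gt(mean(cooc), 0.3)
})

test_that("rho = 0 produces planted genes independent of the causal gene", {
  spec <- cohort_spec(n_samples = 200, n_genes = 100, n_planted_pm = 20,
                      n_decoy_coregulated = 0, n_true_dpm = 10,
                      coupling_rho = 0, seed = 14)
  sim <- simulate_healthy(spec)
  res <- run_step1(sim$matrix, "G0001")
  # under independence the Bonferroni family-wise hit rate is ~alpha
  expect_lte(sum(res$is_pm), 1L)
})

test_that("decoys collapse onto true DPMs when the case effect vanishes", {
  spec <- cohort_spec(n_samples = 150, n_genes = 60, n_planted_pm = 10,
                      n_decoy_coregulated = 5, n_true_dpm = 5,
                      decoy_case_effect = 0.999, seed = 3)
  sim <- simulate_healthy(spec)
  study <- simulate_case_control(spec, sim$truth)
  genes <- sim$truth$gene_id[grepl("planted|step3|coreg", sim$truth$label)]
  res <- run_step2(genes, sim$matrix, "G0001", study, reps = 2000, seed = 5)
  tab <- merge(res, sim$truth)
  pass <- function(lbl) mean(tab$status[tab$label %in% lbl] == "dpm")
  expect_lt(abs(pass(c("planted_pm_true_dpm", "step3_modifier")) -
                pass(c("planted_pm_decoy", "coregulated_decoy"))), 0.45)
})

test_that("isoform link puts planted modifiers at the top of the step-3 ranking", {
  spec <- cohort_spec(seed = 6)
  sim <- simulate_healthy(spec)
  iso <- simulate_isoforms(spec, sim$truth, sim$matrix)
  dpm_like <- sim$truth$gene_id[grepl("planted_pm_true|step3", sim$truth$label)]
  res <- run_step3(dpm_like, sim$matrix, iso)
  mods <- sim$truth$gene_id[sim$truth$label == "step3_modifier"]
  ranks <- res$rank[match(mods, res$gene_id)]
  expect_true(all(ranks <= ceiling(0.1 * nrow(res))))
})

test_that("a zero link weight severs the ratio from every gene", {
  spec <- cohort_spec(n_samples = 300, n_genes = 50, n_planted_pm = 8,
                      n_decoy_coregulated = 0, n_true_dpm = 8,
                      isoform_link_weight = 0, seed = 10)
  sim <- simulate_healthy(spec)
  iso <- simulate_isoforms(spec, sim$truth, sim$matrix)
  res <- run_step3(sim$truth$gene_id[-1], sim$matrix, iso)
  # p-values roughly uniform: none should be extreme after Bonferroni
  expect_gt(min(res$p_ranksum) * nrow(res), 0.01)
})
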