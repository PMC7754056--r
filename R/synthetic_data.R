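# Synthetic cohorts with planted ground truth. A Gaussian copula couples each
# planted modifier to the causal gene's latent variable while keeping
# log-normal marginals, producing the lower-tail co-occurrence the Step-1 test
# looks for without imposing global linear correlation on the abundance scale.
# The case-control study is emitted on a deliberately different measurement
# scale (global factor plus multiplicative noise): every downstream statistic
# is rank-based within dataset and must shrug this off.

#' Specification of a synthetic cohort
#'
#' Defaults describe the study conditions the package is exercised under: a
#' GTEx-scale healthy cohort (400 samples, 1000 genes), a small 7 + 7
#' case-control study on another platform, strong copula coupling (rho = 0.9)
#' for planted modifiers, and log-normal marginals with meanlog 2 and sdlog
#' 0.4 (a typical within-tissue dispersion of roughly 0.6 sd in log2 units,
#' under which a gene perfectly tracking the causal gene at its 2% quantile
#' drops to about 40% of its median -- making the 0.3x decoy case effect a
#' coherent "tracks the causal gene" signal).
#'
#' @param n_samples healthy cohort size.
#' @param n_genes total genes, including the causal gene.
#' @param n_planted_pm genes copula-coupled to the causal gene (Step-1
#'   positives). The first `n_true_dpm` of them behave as true modifiers in
#'   the case-control study; the rest are planted decoys.
#' @param n_decoy_coregulated additional coupled genes, generated identically
#'   to planted PMs; they differ only in the case-control stage.
#' @param n_true_dpm planted PMs that are NOT downregulated in cases (true
#'   disease-associated modifiers). Must be `<= n_planted_pm`.
#' @param n_step3_modifiers true DPMs that causally drive the isoform ratio
#'   (default 2, mirroring the two-splicing-factor situation the third step
#'   was designed around).
#' @param coupling_rho latent copula correlation between causal gene and each
#'   coupled gene, in `[0, 1]`.
#' @param marginal_log_mean,marginal_log_sd log-normal marginal parameters of
#'   every gene's healthy abundance.
#' @param case_gcd_quantile cases' causal-gene values are drawn below this
#'   healthy quantile (default 0.02: severe loss of function).
#' @param decoy_case_effect multiplicative drop applied to decoys in cases
#'   (default 0.3).
#' @param noise_sd sd of multiplicative log-normal measurement noise on the
#'   case-control platform.
#' @param platform_scale global scale factor of the case-control platform.
#' @param isoform_link_weight logistic weight tying low modifier expression to
#'   a high full-length/truncated ratio (default 3).
#' @param n_cases,n_controls case-control arm sizes (default 7 and 7).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 400L, n_genes = 1000L, n_planted_pm = 50L,
                        n_decoy_coregulated = 20L, n_true_dpm = 20L,
                        n_step3_modifiers = 2L, coupling_rho = 0.9,
                        marginal_log_mean = 2, marginal_log_sd = 0.4,
                        case_gcd_quantile = 0.02, decoy_case_effect = 0.3,
                        noise_sd = 0.2, platform_scale = 100,
                        isoform_link_weight = 3,
                        n_cases = 7L, n_controls = 7L, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_planted_pm = as.integer(n_planted_pm),
               n_decoy_coregulated = as.integer(n_decoy_coregulated),
               n_true_dpm = as.integer(n_true_dpm),
               n_step3_modifiers = as.integer(n_step3_modifiers),
               coupling_rho = coupling_rho,
               marginal_log_mean = marginal_log_mean,
               marginal_log_sd = marginal_log_sd,
               case_gcd_quantile = case_gcd_quantile,
               decoy_case_effect = decoy_case_effect,
               noise_sd = noise_sd, platform_scale = platform_scale,
               isoform_link_weight = isoform_link_weight,
               n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
               seed = as.integer(seed))
  with(spec, {
    if (n_samples < 10L || n_genes < 2L) abort_spec("cohort too small")
    if (n_planted_pm < 0L || n_decoy_coregulated < 0L || n_true_dpm < 0L)
      abort_spec("gene counts must be >= 0")
    if (n_planted_pm + n_decoy_coregulated >= n_genes)
      abort_spec("planted + decoy genes must leave room for background genes")
    if (n_true_dpm > n_planted_pm) abort_spec("n_true_dpm must be <= n_planted_pm")
    if (n_step3_modifiers > n_true_dpm)
      abort_spec("n_step3_modifiers must be <= n_true_dpm")
    if (coupling_rho < 0 || coupling_rho > 1) abort_spec("coupling_rho must be in [0, 1]")
    if (case_gcd_quantile <= 0 || case_gcd_quantile >= 1)
      abort_spec("case_gcd_quantile must be in (0, 1)")
    if (decoy_case_effect <= 0 || decoy_case_effect >= 1)
      abort_spec("decoy_case_effect must be in (0, 1)")
    if (marginal_log_sd <= 0 || noise_sd < 0 || platform_scale <= 0)
      abort_spec("scale parameters must be positive")
    if (n_cases < 1L || n_controls < 1L) abort_spec("arms must be non-empty")
  })
  structure(spec, class = "cohort_spec")
}

gene_labels <- function(spec) {
  n_bg <- spec$n_genes - 1L - spec$n_planted_pm - spec$n_decoy_coregulated
  c("gcd",
    rep("step3_modifier", spec$n_step3_modifiers),
    rep("planted_pm_true_dpm", spec$n_true_dpm - spec$n_step3_modifiers),
    rep("planted_pm_decoy", spec$n_planted_pm - spec$n_true_dpm),
    rep("coregulated_decoy", spec$n_decoy_coregulated),
    rep("background", n_bg))
}

# Genes that behave as true modifiers in the case-control stage.
true_dpm_labels <- c("step3_modifier", "planted_pm_true_dpm")
# Genes that track the causal gene in cases (downregulated decoys).
decoy_labels <- c("planted_pm_decoy", "coregulated_decoy")

#' Simulate a healthy cohort with planted modifiers
#'
#' The causal gene and background genes are independent log-normal draws; each
#' planted PM and decoy shares a latent Gaussian factor with the causal gene
#' at correlation `coupling_rho`, so its bottom-decile samples co-occur with
#' the causal gene's bottom-decile samples beyond the independent baseline.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `matrix` (gene-by-sample) and `truth` (data frame
#'   `gene_id`, `label`, the labels partitioning the gene set).
#' @export
simulate_healthy <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort_spec("spec must be a cohort_spec")
  set.seed(spec$seed)
  labels <- gene_labels(spec)
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  sample_ids <- sprintf("H%03d", seq_len(spec$n_samples))
  z_gcd <- stats::rnorm(spec$n_samples)
  rho <- spec$coupling_rho
  Z <- matrix(NA_real_, nrow = spec$n_genes, ncol = spec$n_samples)
  Z[1L, ] <- z_gcd
  for (i in seq_len(spec$n_genes)[-1L]) {
    eps <- stats::rnorm(spec$n_samples)
    Z[i, ] <- if (labels[i] %in% c(true_dpm_labels, decoy_labels))
      rho * z_gcd + sqrt(1 - rho^2) * eps else eps
  }
  values <- exp(spec$marginal_log_mean + spec$marginal_log_sd * Z)
  dimnames(values) <- list(gene_ids, sample_ids)
  list(matrix = values,
       truth = data.frame(gene_id = gene_ids, label = labels))
}

#' Simulate the case-control study for a synthetic cohort
#'
#' Cases carry a causal-gene value below the `case_gcd_quantile` of the healthy
#' marginal (severe loss of function). True DPMs are drawn from their
#' unconditional healthy marginal in both arms -- they are NOT downregulated
#' in disease. Decoys are multiplied by `decoy_case_effect` in cases (they
#' track the causal gene), and background genes are unchanged. The whole
#' study matrix is then scaled by `platform_scale` and perturbed by
#' multiplicative log-normal noise, emulating a different platform.
#'
#' @param spec the [cohort_spec()] used for [simulate_healthy()].
#' @param truth the truth data frame returned by [simulate_healthy()].
#' @return A `case_control_study`.
#' @export
simulate_case_control <- function(spec, truth) {
  if (!inherits(spec, "cohort_spec")) abort_spec("spec must be a cohort_spec")
  if (!is.data.frame(truth) || !all(c("gene_id", "label") %in% names(truth)) ||
      nrow(truth) != spec$n_genes || sum(truth$label == "gcd") != 1L)
    abort_spec("truth does not match the cohort spec")
  set.seed(derive_seed(spec$seed, "case_control"))
  n_c <- spec$n_cases; n_k <- spec$n_controls; n_s <- n_c + n_k
  mu <- spec$marginal_log_mean; sd <- spec$marginal_log_sd
  draw <- function(n) stats::rlnorm(n, mu, sd)
  vals <- matrix(NA_real_, nrow = spec$n_genes, ncol = n_s)
  for (i in seq_len(spec$n_genes)) {
    lab <- truth$label[i]
    if (lab == "gcd") {
      u <- stats::runif(n_c, 0, spec$case_gcd_quantile)
      vals[i, ] <- c(stats::qlnorm(u, mu, sd), draw(n_k))
    } else if (lab %in% decoy_labels) {
      vals[i, ] <- c(draw(n_c) * spec$decoy_case_effect, draw(n_k))
    } else {  # true DPMs and background: unconditional in both arms
      vals[i, ] <- draw(n_s)
    }
  }
  noise <- exp(stats::rnorm(length(vals), 0, spec$noise_sd))
  vals <- vals * spec$platform_scale * noise
  case_ids <- sprintf("D%02d", seq_len(n_c))
  control_ids <- sprintf("C%02d", seq_len(n_k))
  dimnames(vals) <- list(truth$gene_id, c(case_ids, control_ids))
  case_control_study(vals, case_ids, control_ids)
}

#' Simulate isoform abundances driven by the planted step-3 modifiers
#'
#' For each healthy sample the probability of a high full-length/truncated
#' ratio follows a logistic link on the (negated) mean standardized
#' log-expression of the step-3 modifier genes: samples where the modifiers
#' are low tend to show compensating exon inclusion. Non-modifier genes
#' influence the ratio only through their correlation with the modifiers.
#'
#' @param spec the [cohort_spec()].
#' @param truth truth data frame from [simulate_healthy()].
#' @param healthy the healthy matrix from [simulate_healthy()].
#' @return Data frame `sample_id`, `fl`, `trunc` aligned to the healthy
#'   cohort samples.
#' @export
simulate_isoforms <- function(spec, truth, healthy) {
  if (!inherits(spec, "cohort_spec")) abort_spec("spec must be a cohort_spec")
  mods <- truth$gene_id[truth$label == "step3_modifier"]
  if (!length(mods)) abort_spec("truth contains no step3_modifier gene")
  if (!all(mods %in% rownames(healthy)))
    abort_spec("step3 modifiers absent from the healthy matrix")
  set.seed(derive_seed(spec$seed, "isoforms"))
  z <- scale(t(log(healthy[mods, , drop = FALSE])))
  z_mod <- rowMeans(z)
  p_high <- stats::plogis(-spec$isoform_link_weight * z_mod)
  high <- stats::rbinom(length(p_high), 1L, p_high) == 1L
  base <- stats::rlnorm(length(p_high), spec$marginal_log_mean, spec$marginal_log_sd)
  margin <- exp(stats::runif(length(p_high), 0.1, 1))  # strictly > 1: no ties
  data.frame(sample_id = colnames(healthy),
             fl = ifelse(high, base * margin, base / margin),
             trunc = ifelse(high, base / margin, base * margin))
}
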