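test_that("prior validation and component variances follow the four-part mixture", {
  pri <- bayesr_priors(sigma_g2 = 100, n_iter = 100, burn_in = 10)
  expect_equal(component_variances(pri), c(0, 0.01, 0.1, 1.0))
  pri1 <- bayesr_priors(sigma_g2 = 1, n_iter = 100, burn_in = 10)
  expect_equal(component_variances(pri1), c(0, 1e-4, 1e-3, 1e-2))
  expect_error(bayesr_priors(sigma_g2 = 0), "sigma_g2")
  expect_error(bayesr_priors(sigma_g2 = 1, n_iter = 100, burn_in = 100),
               "burn_in")
  expect_error(bayesr_priors(sigma_g2 = 1, variance_ratios = c(0.1, 0, 1e-3, 1e-2),
                             n_iter = 100, burn_in = 10), "ratio")
})

test_that("the null-component-only model returns exactly zero effects", {
  set.seed(61)
  g <- hwe_geno(80, 150, seed = 62)
  d <- plain_design(rnorm(80), g$ids)
  pri <- bayesr_priors(sigma_g2 = 1, n_iter = 300, burn_in = 50, seed = 4,
                       pi_fixed = c(1, 0, 0, 0))
  bf <- run_bayesr(d, g, pri)
  expect_true(all(bf$snp_effect_means == 0))
  expect_true(all(bf$gbv == 0))
  expect_equal(unname(bf$component_probs[, 1]), rep(1, ncol(bf$component_probs) * 0 +
                                                      nrow(bf$component_probs)))
})

test_that("chains are reproducible under a seed and internally consistent", {
  set.seed(63)
  g <- hwe_geno(100, 200, seed = 64)
  p <- colMeans(g$calls) / 2
  M <- sweep(g$calls, 2, 2 * p)
  y <- drop(M %*% rnorm(200, 0, 0.05)) + rnorm(100, 0, 0.7)
  d <- plain_design(y, g$ids)
  pri <- bayesr_priors(sigma_g2 = 0.3, n_iter = 1500, burn_in = 300, seed = 11)
  b1 <- run_bayesr(d, g, pri)
  b2 <- run_bayesr(d, g, pri)
  expect_identical(b1$snp_effect_means, b2$snp_effect_means)
  expect_identical(b1$sigma_e_trace, b2$sigma_e_trace)
  # no drift between incremental and recomputed residuals
  expect_lt(b1$residual_drift, 1e-6)
  # membership probabilities are proper
  expect_equal(unname(rowSums(b1$component_probs)),
               rep(1, nrow(b1$component_probs)), tolerance = 1e-9)
  expect_equal(sum(b1$pi_mean), 1, tolerance = 1e-9)
  # chain stability: nonzero-SNP count agrees across two seeds within
  # Monte-Carlo error
  pri2 <- bayesr_priors(sigma_g2 = 0.3, n_iter = 1500, burn_in = 300, seed = 12)
  b3 <- run_bayesr(d, g, pri2)
  mc_se <- sd(b1$nnz_trace) / sqrt(effective_sample_size(b1$nnz_trace)) +
    sd(b3$nnz_trace) / sqrt(effective_sample_size(b3$nnz_trace))
  expect_lt(abs(mean(b1$nnz_trace) - mean(b3$nnz_trace)), 4 * mc_se + 1)
})

test_that("the degenerate one-component prior reproduces GBLUP", {
  set.seed(65)
  n <- 300; m <- 600
  g <- hwe_geno(n, m, seed = 66)
  p <- colMeans(g$calls) / 2
  c2 <- 2 * sum(p * (1 - p))
  M <- sweep(g$calls, 2, 2 * p)
  y <- drop(M %*% rnorm(m, 0, sqrt(0.4 / c2))) + rnorm(n, 0, sqrt(0.6))
  d <- plain_design(y, g$ids)
  vc <- variance_components(v_additive = 0.4, v_residual = 0.6)
  pr <- solve_mme(d, compute_grm(g), vc)
  # pi fixed to the heaviest component, its variance matched to SNP-BLUP
  pri <- bayesr_priors(sigma_g2 = (0.4 / c2) / 0.01, n_iter = 6000,
                       burn_in = 1500, seed = 13, pi_fixed = c(0, 0, 0, 1))
  bf <- run_bayesr(d, g, pri)
  expect_gt(cor(bf$gbv, pr$all_gbv[names(bf$gbv)]), 0.99)
})

test_that("a large tagged QTL is assigned to the heavy mixture component", {
  set.seed(67)
  n <- 500; m <- 400
  p0 <- runif(m, 0.2, 0.8)
  calls <- matrix(rbinom(n * m, 2, rep(p0, each = n)), n)
  # SNP 200 tags the causal locus perfectly (r2 = 1)
  qtl_dose <- calls[, 200]
  tbv <- (qtl_dose - mean(qtl_dose)) * 1
  v_qtl <- var(tbv)
  y <- tbv + rnorm(n, 0, sqrt(v_qtl * 7 / 3))   # QTL explains 30% of variance
  g <- genotype_matrix(calls, sprintf("I%03d", 1:n), sprintf("S%03d", 1:m),
                       rep(1, m), 1:m)
  d <- plain_design(y, g$ids)
  pri <- bayesr_priors(sigma_g2 = v_qtl, n_iter = 2000, burn_in = 500,
                       seed = 14)
  bf <- run_bayesr(d, g, pri)
  expect_gt(bf$component_probs["S200", 4], 0.5)
  # the tagged SNP carries (nearly) the full signal
  expect_equal(which.max(abs(bf$snp_effect_means)), 200, ignore_attr = TRUE)
})

test_that("invalid chain settings are rejected", {
  g <- hwe_geno(20, 30, seed = 68)
  d <- plain_design(rnorm(20), g$ids)
  expect_error(run_bayesr(d, subset_geno(g, ids = g$ids[1:10]),
                          bayesr_priors(1, n_iter = 100, burn_in = 10)),
               "cover")
})
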