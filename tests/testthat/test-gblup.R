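test_that("three-animal solutions equal the hand-assembled Henderson system", {
  y <- c(1.0, 2.0, 0.5)
  d <- plain_design(y, c("a", "b", "c"))
  A <- relmat(diag(3), c("a", "b", "c"), source = "pedigree")
  pr <- solve_mme(d, A, variance_components(v_additive = 1, v_residual = 1))
  # 4x4 MME with lambda = 1: [n 1'; 1 I + I] [b; a] = [1'y; y]
  C <- rbind(c(3, 1, 1, 1), cbind(1, diag(2, 3)))
  sol <- solve(C, c(sum(y), y))
  expect_equal(unname(pr$fixed_solutions), sol[1], tolerance = 1e-10)
  expect_equal(unname(pr$gbv), sol[2:4], tolerance = 1e-10)
  expect_lt(pr$mme_residual, 1e-6 * pr$rhs_scale)
})

test_that("breeding values shrink to zero as additive variance vanishes", {
  set.seed(51)
  g <- hwe_geno(50, 200, seed = 52)
  d <- plain_design(rnorm(50), g$ids)
  G <- compute_grm(g)
  pr <- solve_mme(d, G, variance_components(v_additive = 1e-8,
                                            v_residual = 1))
  expect_lt(max(abs(pr$gbv)), 1e-6)
})

test_that("GBLUP equals ridge SNP-BLUP back-solved to animals", {
  set.seed(53)
  n <- 200; m <- 500
  g <- hwe_geno(n, m, seed = 54)
  y <- rnorm(n)
  d <- plain_design(y, g$ids)
  G <- compute_grm(g)
  va <- 0.8; ve <- 1.2
  pr <- solve_mme(d, G, variance_components(v_additive = va,
                                            v_residual = ve))
  # oracle: joint (mean, SNP) ridge system with per-SNP variance
  # va / (2 sum p(1-p)), GEBV = M g_hat
  p <- colMeans(g$calls) / 2
  M <- sweep(g$calls, 2, 2 * p)
  c2 <- 2 * sum(p * (1 - p))
  lam <- ve / (va / c2)
  C <- rbind(cbind(n, t(colSums(M))),
             cbind(colSums(M), crossprod(M) + diag(lam, m)))
  sol <- solve(C, c(sum(y), drop(crossprod(M, y))))
  gebv <- drop(M %*% sol[-1])
  expect_lt(max(abs(gebv - unname(pr$gbv))), 1e-6)
})

test_that("unphenotyped animals are predicted through their relationships", {
  sim <- fix_sim()
  d <- fix_design()
  G <- fix_grm()
  fit <- fit_reml(d, G)
  val <- sim$ped$id[grepl("validation", sim$ped$role)]
  pr <- solve_mme(d, G, fit$components, predict_ids = val)
  expect_setequal(names(pr$gbv), val)
  expect_true(all(is.finite(pr$gbv)))
  expect_lt(pr$mme_residual, 1e-6 * pr$rhs_scale)
  # prediction has real skill on true breeding values
  expect_gt(cor(pr$gbv, sim$truth$tbv[val]), 0.3)
  expect_error(solve_mme(d, G, fit$components, predict_ids = "nobody"),
               "nobody")
})

test_that("adding a constant to the phenotype shifts only the intercept", {
  set.seed(55)
  g <- hwe_geno(80, 300, seed = 56)
  y <- rnorm(80)
  G <- compute_grm(g)
  vc <- variance_components(v_additive = 0.5, v_residual = 0.5)
  p1 <- solve_mme(plain_design(y, g$ids), G, vc)
  p2 <- solve_mme(plain_design(y + 5, g$ids), G, vc)
  expect_equal(p2$fixed_solutions[["(Intercept)"]],
               p1$fixed_solutions[["(Intercept)"]] + 5, tolerance = 1e-8)
  expect_equal(p1$gbv, p2$gbv, tolerance = 1e-8)
})

test_that("predictions are invariant to SNP column permutation", {
  set.seed(57)
  g <- hwe_geno(60, 250, seed = 58)
  y <- rnorm(60)
  d <- plain_design(y, g$ids)
  vc <- variance_components(v_additive = 0.5, v_residual = 0.5)
  perm <- sample(250)
  g2 <- genotype_matrix(g$calls[, perm], g$ids, g$snp_ids[perm],
                        g$chrom[perm], g$pos[perm])
  p1 <- solve_mme(d, compute_grm(g), vc)
  p2 <- solve_mme(d, compute_grm(g2), vc)
  expect_equal(p1$gbv, p2$gbv, tolerance = 1e-10)
})

test_that("prediction accuracy is non-decreasing in reference size", {
  accs <- sapply(1:10, function(rep) {
    set.seed(600 + rep)
    m <- 600
    n_max <- 900
    p0 <- runif(m, 0.1, 0.9)
    calls <- matrix(rbinom((n_max + 50) * m, 2, rep(p0, each = n_max + 50)),
                    n_max + 50)
    ids <- sprintf("I%04d", seq_len(n_max + 50))
    g <- genotype_matrix(calls, ids, sprintf("S%03d", 1:m), rep(1, m), 1:m)
    p <- colMeans(calls) / 2
    M <- sweep(calls, 2, 2 * p)
    c2 <- 2 * sum(p * (1 - p))
    u <- rnorm(m, 0, sqrt(0.4 / c2))
    tbv <- drop(M %*% u)
    y <- tbv + rnorm(n_max + 50, 0, sqrt(0.6))
    tgt <- ids[(n_max + 1):(n_max + 50)]
    vc <- variance_components(v_additive = 0.4, v_residual = 0.6)
    sapply(c(300, 600, 900), function(nr) {
      sub <- ids[1:nr]
      d <- plain_design(y[1:nr], sub)
      G <- compute_grm(subset_geno(g, ids = c(sub, tgt)))
      pr <- solve_mme(d, G, vc, predict_ids = tgt)
      cor(pr$gbv, tbv[(n_max + 1):(n_max + 50)])
    })
  })
  means <- rowMeans(accs)
  expect_true(all(diff(means) > 0))
})

test_that("reliability behaves as a squared accuracy", {
  set.seed(59)
  g <- hwe_geno(60, 300, seed = 60)
  y <- rnorm(60)
  d <- plain_design(y, g$ids)
  # an unphenotyped animal unrelated to every phenotyped one
  V <- compute_grm(g)$values
  ids2 <- c(g$ids, "stranger")
  V2 <- rbind(cbind(V, 0), 0)
  V2[61, 61] <- 1
  G2 <- relmat(V2, ids2, source = "markers")
  vc <- variance_components(v_additive = 0.5, v_residual = 0.5)
  r <- reliability(d, G2, vc, ids = "stranger")
  expect_lt(r[["stranger"]], 1e-10)
  # phenotyped animal, heritability -> 1: reliability -> 1
  vc_hi <- variance_components(v_additive = 1, v_residual = 1e-6)
  r_hi <- reliability(d, G2, vc_hi, ids = g$ids[1])
  expect_gt(r_hi[[1]], 0.99)
  # bounded on random instances
  r_all <- reliability(d, G2, vc)
  expect_true(all(r_all >= 0 & r_all <= 1))
})
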