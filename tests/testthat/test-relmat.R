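test_that("VanRaden G matches the hand-computed two-individual case", {
  g <- genotype_matrix(matrix(c(2L, 0L), 2, 1), c("i1", "i2"), "s1", "1", 1)
  G <- compute_grm(g)
  # p = 0.5, M = (1, -1), denominator 2 * 0.25 = 0.5
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_equal(scale_diagnostics(G)$mean_diagonal, 2)
  expect_equal(scale_diagnostics(G)$mean_offdiagonal, -2)
})

test_that("G entries sum to zero under observed-frequency centering", {
  g <- hwe_geno(80, 400, seed = 12)
  G <- compute_grm(g)
  expect_lt(abs(sum(G$values)), 1e-8)
  d <- scale_diagnostics(G)
  expect_equal(d$mean_offdiagonal, -d$mean_diagonal / (nrow(G$values) - 1),
               tolerance = 1e-10)
})

test_that("G scale on an equilibrium population matches the expected unit diagonal", {
  g <- hwe_geno(500, 3000, seed = 14)
  G <- compute_grm(g)
  d <- scale_diagnostics(G)
  expect_gt(d$mean_diagonal, 0.97)
  expect_lt(d$mean_diagonal, 1.03)
  expect_lt(abs(d$mean_offdiagonal), 0.01)
})

test_that("monomorphic SNPs contribute nothing and all-monomorphic errors", {
  g <- hwe_geno(30, 50, seed = 15)
  calls2 <- cbind(g$calls, matrix(2L, 30, 5))
  g2 <- genotype_matrix(calls2, g$ids, sprintf("S%04d", 1:55), rep(1L, 55),
                        1:55)
  expect_equal(compute_grm(g2)$values, compute_grm(g)$values,
               tolerance = 1e-12)
  gm <- genotype_matrix(matrix(2L, 4, 3), paste0("i", 1:4), paste0("s", 1:3),
                        rep("1", 3), 1:3)
  expect_error(compute_grm(gm), "monomorphic")
})

test_that("G is positive semidefinite up to numerical tolerance", {
  sim <- fix_sim()
  qc <- apply_qc(sim$geno)
  G <- compute_grm(qc$geno)
  ev <- eigen(G$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("pedigree A reproduces textbook relationships", {
  # unrelated founders
  p0 <- pedigree(c("f1", "f2", "f3"),
                 breed_fractions = matrix(1, 3, 1, dimnames = list(NULL, "A")))
  expect_equal(unname(compute_nrm(p0)$values), diag(3))
  # parent-offspring 0.5; full sibs 0.5; offspring of full sibs F = 0.25
  p1 <- pedigree(c("f1", "f2", "s1", "s2", "x"),
                 sire = c(NA, NA, "f1", "f1", "s1"),
                 dam = c(NA, NA, "f2", "f2", "s2"),
                 breed_fractions = matrix(1, 5, 1, dimnames = list(NULL, "A")))
  A <- compute_nrm(p1)$values
  expect_equal(A["f1", "s1"], 0.5)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["x", "x"], 1.25)
  expect_equal(A["f1", "x"], 0.5)   # grandparent through both sibs
})

test_that("pedigree A agrees with a gene-dropping IBD estimator", {
  # three-generation 9-animal pedigree with inbreeding
  ped <- pedigree(c("a", "b", "c", "d", "e", "f", "g", "h", "i"),
                  sire = c(NA, NA, NA, "a", "a", "d", "d", "f", "f"),
                  dam  = c(NA, NA, NA, "b", "c", "e", "e", "g", "c"),
                  breed_fractions = matrix(1, 9, 1,
                                           dimnames = list(NULL, "A")))
  A <- compute_nrm(ped)$values
  # oracle: drop unique founder alleles through the pedigree 1e5 times and
  # count identity by descent
  R <- 1e5
  set.seed(77)
  al1 <- list(); al2 <- list()
  for (k in seq_len(nrow(ped))) {
    s <- ped$sire[k]; d <- ped$dam[k]
    if (is.na(s)) {
      al1[[k]] <- rep(2L * k - 1L, R); al2[[k]] <- rep(2L * k, R)
    } else {
      si <- match(s, ped$id); di <- match(d, ped$id)
      pick <- runif(R) < 0.5
      al1[[k]] <- ifelse(pick, al1[[si]], al2[[si]])
      pick <- runif(R) < 0.5
      al2[[k]] <- ifelse(pick, al1[[di]], al2[[di]])
    }
  }
  for (i in c(4, 6, 8, 9)) for (j in seq_len(i)) {
    f_ij <- if (i == j) mean(al1[[i]] == al2[[i]]) else
      (mean(al1[[i]] == al1[[j]]) + mean(al1[[i]] == al2[[j]]) +
         mean(al2[[i]] == al1[[j]]) + mean(al2[[i]] == al2[[j]])) / 4
    a_est <- if (i == j) 1 + f_ij else 2 * f_ij
    expect_equal(a_est, A[i, j], tolerance = 0.02)
  }
})

test_that("relatedness classification follows the top-k mean and max rules", {
  ids <- c(sprintf("r%02d", 1:40), "hi", "lo", "mid")
  V <- diag(length(ids))
  rownames(V) <- colnames(V) <- ids
  V["hi", sprintf("r%02d", 1:30)] <- 0.25
  V[sprintf("r%02d", 1:30), "hi"] <- 0.25
  V["lo", sprintf("r%02d", 1:40)] <- 0.05
  V[sprintf("r%02d", 1:40), "lo"] <- 0.05
  # top-30 mean 0.15 but max 0.30: fails both rules
  V["mid", sprintf("r%02d", 1:30)] <- 0.15
  V[sprintf("r%02d", 1:30), "mid"] <- 0.15
  V["mid", "r01"] <- V["r01", "mid"] <- 0.30
  V["mid", sprintf("r%02d", 2:30)] <- 0.1448276
  V[sprintf("r%02d", 2:30), "mid"] <- 0.1448276
  G <- relmat(V, ids, source = "markers")
  grp <- classify_relatedness(G, reference = sprintf("r%02d", 1:40),
                              candidates = c("hi", "lo", "mid"))
  expect_equal(grp$high, "hi")
  expect_equal(grp$low, "lo")
  expect_equal(grp$neither, "mid")
  expect_warning(
    classify_relatedness(G, reference = sprintf("r%02d", 1:5),
                         candidates = "hi"),
    "k_top")
})

test_that("moderate and dense panels give nearly identical relationships", {
  cf <- sim_config(n_breeds = 1, breed_labels = "A",
                   n_founders_per_breed = 80, n_reference = 250,
                   n_validation_sires_per_breed = 4, n_snps_dense = 5000,
                   density_ratio = 0.2, n_qtl = 100,
                   divergence_generations = 30, ne = 60, seed = 19)
  sim <- simulate_population(cf)
  ids <- sim$ped$id[sim$ped$role == "reference"]
  gd <- subset_geno(sim$geno, ids = ids)
  gm <- subset_density(gd, cf$density_ratio, seed = 3)
  Gd <- compute_grm(gd)$values
  Gm <- compute_grm(gm)$values
  off <- upper.tri(Gd)
  expect_gt(cor(Gd[off], Gm[off]), 0.95)
})
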