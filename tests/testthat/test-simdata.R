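test_that("configuration invariants are enforced", {
  expect_error(sim_config(density_ratio = 0), "density_ratio")
  expect_error(sim_config(h2_target = 0.6, var_maternal = 0.2, var_breed = 0.2,
                          var_sireflock = 0.1), "residual")
  expect_error(sim_config(n_qtl = 5000, n_snps_dense = 1000), "n_qtl")
  expect_error(sim_config(n_breeds = 2, breed_labels = c("A", "B"),
                          cross_design = data.frame(sire_breed = "C",
                                                    dam_breed = "A",
                                                    n_offspring = 10)),
               "breed_labels")
  expect_error(sim_config(n_breeds = 2, breed_labels = c("A", "B"),
                          cross_design = data.frame(sire_breed = character(0),
                                                    dam_breed = character(0),
                                                    n_offspring = integer(0))),
               "non-empty")
})

test_that("simulated population has the configured shape and is seed-reproducible", {
  cf <- sim_config(n_breeds = 2, breed_labels = c("A", "B"),
                   n_founders_per_breed = 100, n_reference = 100,
                   n_validation_sires_per_breed = 4, n_snps_dense = 1000,
                   n_qtl = 40, divergence_generations = 5, ne = 30, seed = 42)
  sim <- simulate_population(cf)
  expect_equal(sum(sim$ped$role == "founder"), 200)   # 100 per breed
  expect_equal(ncol(sim$geno$calls), 1000)
  expect_true(all(sim$geno$calls %in% 0:2))
  expect_equal(sum(sim$ped$role == "reference"), 100)
  # parents precede offspring and breed fractions are proper
  Q <- breed_fractions(sim$ped)
  expect_true(all(abs(rowSums(Q) - 1) < 1e-9))
  expect_true(all(Q >= 0))
  sim2 <- simulate_population(cf)
  expect_identical(sim$geno$calls, sim2$geno$calls)
  expect_identical(sim$truth$tbv, sim2$truth$tbv)
})

test_that("true breeding values are the centered QTL dosage dot product", {
  sim <- fix_sim()
  qi <- match(sim$truth$qtl_ids, sim$geno$snp_ids)
  Zq <- sim$geno$calls[, qi, drop = FALSE]
  ctr <- sweep(Zq, 2, 2 * sim$truth$qtl_freq)
  expect_equal(drop(ctr %*% sim$truth$qtl_effects), unname(sim$truth$tbv),
               ignore_attr = TRUE, tolerance = 1e-12)
  founders <- sim$ped$id[sim$ped$role == "founder"]
  expect_equal(var(sim$truth$tbv[founders]), sim$config$h2_target,
               tolerance = 1e-10)
})

test_that("breed divergence grows with drift generations (Hudson FST oracle)", {
  fst_hudson <- function(p1, p2, n1, n2) {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
  }
  fst_at <- function(gens) {
    cf <- sim_config(n_breeds = 2, breed_labels = c("A", "B"),
                     n_founders_per_breed = 60, n_reference = 40,
                     n_validation_sires_per_breed = 2, n_snps_dense = 500,
                     n_qtl = 20, divergence_generations = gens, ne = 100,
                     seed = 99)
    sim <- simulate_population(cf)
    f <- sim$ped$role == "founder"
    a <- sim$ped$id[f & breed_fractions(sim$ped)[, "A"] == 1]
    b <- sim$ped$id[f & breed_fractions(sim$ped)[, "B"] == 1]
    p1 <- colMeans(sim$geno$calls[a, ]) / 2
    p2 <- colMeans(sim$geno$calls[b, ]) / 2
    fst_hudson(p1, p2, 2 * length(a), 2 * length(b))
  }
  f10 <- fst_at(10)
  f200 <- fst_at(200)
  expect_gt(f200, f10)
  expect_gt(f200, 0.3)   # ~ 1 - exp(-200/(2*100))
  expect_lt(f10, 0.15)
})

test_that("offspring allele frequencies are unbiased for parental frequencies", {
  set.seed(31)
  m <- 400
  pos <- sort(runif(m))
  chr <- rep(1L, m)
  H <- matrix(rbinom(80 * m, 1, 0.5), nrow = 80)  # 40 parents
  p_parent <- colMeans(H)
  deltas <- replicate(30, {
    par <- sample.int(40, 120, replace = TRUE)
    G <- ovinepred:::drop_gametes_cpp(H, par - 1L, pos, chr)
    mean(colMeans(G) - p_parent)
  })
  # mean change across replicates is zero within Monte-Carlo error
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 1e-3)
})

test_that("panel thinning keeps the demanded evenly spaced subset", {
  g <- hwe_geno(4, 200, seed = 5)
  expect_identical(subset_density(g, 1), g)
  g2 <- subset_density(g, 0.25, seed = 3)
  expect_equal(ncol(g2$calls), 50)
  expect_false(is.unsorted(order(g2$chrom, g2$pos)))
  # reproducible under the seed, different under another
  expect_identical(subset_density(g, 0.25, seed = 3)$snp_ids, g2$snp_ids)
  # arithmetic forced: 0.095 of 10,000 candidate columns -> 950
  big <- genotype_matrix(matrix(0L, 2, 10000), c("a", "b"),
                         sprintf("S%05d", 1:10000), rep(1L, 10000), 1:10000)
  expect_equal(ncol(subset_density(big, 0.095, seed = 1)$calls), 950)
  # excluded QTL appear on no panel
  excl <- g$snp_ids[c(10, 20, 30)]
  g3 <- subset_density(g, 1, seed = 1, exclude = excl)
  expect_false(any(excl %in% g3$snp_ids))
  expect_equal(ncol(g3$calls), 197)
})

test_that("QTL architectures produce the intended variance-share profiles", {
  share <- function(truth) {
    w <- 2 * truth$qtl_freq * (1 - truth$qtl_freq) * truth$qtl_effects^2
    w / sum(w)
  }
  cf_g <- sim_config(n_breeds = 1, breed_labels = "A",
                     n_founders_per_breed = 80, n_reference = 50,
                     n_validation_sires_per_breed = 2, n_snps_dense = 2000,
                     n_qtl = 1000, divergence_generations = 5, ne = 40,
                     qtl_effect_distribution = "gaussian", seed = 13)
  s_g <- share(simulate_population(cf_g)$truth)
  expect_lt(max(s_g), 0.02)
  cf_f <- sim_config(n_breeds = 1, breed_labels = "A",
                     n_founders_per_breed = 80, n_reference = 50,
                     n_validation_sires_per_breed = 2, n_snps_dense = 2000,
                     n_qtl = 100, divergence_generations = 5, ne = 40,
                     qtl_effect_distribution = "few_large", seed = 13)
  s_f <- share(simulate_population(cf_f)$truth)
  expect_gte(max(s_f), 0.10)
})

test_that("phenotypes realize the configured variance fractions", {
  # degenerate case: pure additive, no fixed effects -> y equals tbv
  sim <- fix_sim()
  cf0 <- sim$config
  cf0$h2_target <- 1; cf0$var_maternal <- 0; cf0$var_breed <- 0
  cf0$var_sireflock <- 0
  d0 <- simulate_phenotypes(sim$geno, sim$ped, sim$truth, cf0, seed = 4,
                            fixed_effects = FALSE)
  expect_equal(unname(d0$y), unname(sim$truth$tbv[d0$ids]), tolerance = 1e-12)

  # h2 = 0.3 at n = 2000: realized additive fraction inside [0.25, 0.35]
  cf <- sim_config(n_breeds = 1, breed_labels = "A",
                   n_founders_per_breed = 150, n_reference = 2000,
                   n_validation_sires_per_breed = 4, n_snps_dense = 800,
                   n_qtl = 80, divergence_generations = 10, ne = 60,
                   h2_target = 0.3, var_maternal = 0, var_breed = 0,
                   var_sireflock = 0, seed = 23)
  sim2 <- simulate_population(cf)
  d <- simulate_phenotypes(sim2$geno, sim2$ped, sim2$truth, cf, seed = 5,
                           fixed_effects = FALSE)
  ratio <- var(sim2$truth$tbv[d$ids]) / var(d$y)
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.35)
  # total phenotypic variance within 10% of the implied target
  expect_equal(var(d$y), d$realized_var_components$sigma_p2_target,
               tolerance = 0.10)
})

test_that("progeny-test EBVs follow the half-sib reliability model", {
  fake_truth <- list(tbv = setNames(rnorm(500, 0, sqrt(0.3)),
                                    sprintf("S%03d", 1:500)),
                     realized_var_components = list(v_additive = 0.3))
  # closed-form accuracy from the stated reliability formula
  eb <- simulate_progeny_ebv(fake_truth, names(fake_truth$tbv),
                             n_progeny = 100, h2 = 0.3, seed = 8)
  # 0.25 * 100 * 0.3 = 7.5 over 1 + 0.25 * 99 * 0.3 = 8.425
  expect_equal(unique(eb$accuracy), sqrt(7.5 / 8.425), tolerance = 1e-12)
  eb_big <- simulate_progeny_ebv(fake_truth, names(fake_truth$tbv)[1:3],
                                 n_progeny = 1e6, h2 = 0.3, seed = 8)
  expect_gt(min(eb_big$accuracy), 0.99)
  # generative contract: realized correlation matches the recorded accuracy
  expect_equal(cor(eb$ebv, fake_truth$tbv[eb$sire_id]), eb$accuracy[1],
               tolerance = 0.05)
  expect_error(simulate_progeny_ebv(fake_truth, "S001", 10, h2 = 1.2), "h2")
})
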