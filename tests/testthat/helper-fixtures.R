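# Shared fixtures, built once per test run and memoised.

memo <- local({
  cache <- list()
  function(key, fn) {
    if (is.null(cache[[key]])) cache[[key]] <<- fn()
    cache[[key]]
  }
})

# small two-breed crossbred population used by several module tests
fix_sim <- function() memo("sim", function() {
  simulate_population(sim_config(
    n_breeds = 2, breed_labels = c("A", "B"), n_founders_per_breed = 60,
    n_reference = 300, n_validation_sires_per_breed = 10,
    n_snps_dense = 800, n_qtl = 60, divergence_generations = 20,
    ne = 50, n_chr = 3, seed = 7))
})

fix_design <- function() memo("design", function() {
  sim <- fix_sim()
  simulate_phenotypes(sim$geno, sim$ped, sim$truth, sim$config, seed = 2)
})

fix_grm <- function() memo("grm", function() {
  sim <- fix_sim()
  d <- fix_design()
  val <- sim$ped$id[grepl("validation", sim$ped$role)]
  compute_grm(subset_geno(sim$geno, ids = unique(c(d$ids, val))))
})

# unstructured HWE genotypes (independent of the gene-dropping engine)
hwe_geno <- function(n, m, seed, maf_range = c(0.1, 0.9)) {
  set.seed(seed)
  p0 <- runif(m, maf_range[1], maf_range[2])
  calls <- matrix(rbinom(n * m, 2, rep(p0, each = n)), n)
  genotype_matrix(calls, sprintf("I%04d", seq_len(n)),
                  sprintf("S%04d", seq_len(m)), rep(1L, m), seq_len(m))
}

# single-group design with intercept-only fixed effects
plain_design <- function(y, ids = sprintf("I%04d", seq_along(y))) {
  tab <- data.frame(id = ids, trait = y, stringsAsFactors = FALSE)
  ped <- pedigree(ids, breed_fractions =
                    matrix(1, length(ids), 1, dimnames = list(NULL, "A")))
  build_design(tab, ped, "trait")
}

# independent REML log-likelihood for an additive + residual model,
# computed straight from the definition (V-inverse via solve())
loglik_two_comp <- function(y, X, K, va, ve) {
  n <- length(y)
  V <- va * K + diag(ve, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y))
}

# deterministic genotype column with given counted-allele frequency,
# genotype counts rounded to Hardy-Weinberg proportions
hw_counts <- function(q, n = 100) {
  n2 <- round(n * q^2); n1 <- round(n * 2 * q * (1 - q))
  rep(c(2L, 1L, 0L), c(n2, n1, n - n1 - n2))
}

# 100 x 20 panel with one planted violation per SNP rule
planted_panel <- function() {
  mafs <- c(0.12, 0.13, 0.14, 0.15, 0.16, 0.12, 0.13, 0.14, 0.15, 0.16,
            0.13, 0.14, 0.15, 0.14)
  calls <- do.call(cbind, lapply(mafs, hw_counts))    # S01..S14 clean
  calls <- cbind(calls, hw_counts(0.14))              # S15 on chromosome X
  s16 <- hw_counts(0.14); s16[1:11] <- NA             # S16 call rate 0.89
  calls <- cbind(calls, s16)
  calls <- cbind(calls, hw_counts(0.14))              # S17 low GC score
  calls <- cbind(calls, rep(1L, 100))                 # S18 fully heterozygous
  calls <- cbind(calls, rep(0L, 100))                 # S19 monomorphic
  calls <- cbind(calls, rep(c(2L, 1L, 0L), c(47, 6, 47)))  # S20 HWE outlier
  qual <- matrix(1, 100, 20); qual[, 17] <- 0.5
  genotype_matrix(calls, sprintf("A%03d", 1:100), sprintf("S%02d", 1:20),
                  c(rep("1", 14), "X", rep("1", 5)), 1:20,
                  call_quality = qual)
}

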