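#' Effective sample size of an MCMC scalar trace
#'
#' Initial-positive-sequence estimator: `n / (1 + 2 * sum(rho_k))` with the
#' autocorrelation sum truncated at the first non-positive lag.
#'
#' @param x numeric vector, one scalar per saved MCMC sample.
#' @return Effective sample size (numeric scalar, capped at `length(x)`).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(as.numeric(n))
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts, summing the probabilities of all genotype configurations no more
#' likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab           # minor-or-not does not matter: symmetric
  rare <- min(n_a, 2L * n - n_a)
  # heterozygote counts share the parity of the rare allele count
  het_obs <- n_ab
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_ab = h | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-12)])
}

#' Hardy-Weinberg test p-value (chi-square with exact fallback)
#'
#' One-degree-of-freedom chi-square test of the genotype counts against
#' Hardy-Weinberg proportions, switching to the exact conditional test when
#' any expected genotype count is below 5.
#'
#' @inheritParams hwe_exact_test
#' @return p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expd < 5)) return(hwe_exact_test(n_aa, n_ab, n_bb))
  obs <- c(n_aa, n_ab, n_bb)
  keep <- expd > 0
  stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# md5 of an arbitrary R object, for pipeline stage caching
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
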