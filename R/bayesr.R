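#' BayesR prior settings
#'
#' Four-component Gaussian mixture for SNP effects with variances
#' `(0, 0.0001, 0.001, 0.01) * sigma_g2`, a Dirichlet prior on the mixture
#' proportions, and a Gibbs chain of 50,000 iterations with 10,000 burn-in
#' by default.
#'
#' @param sigma_g2 assumed total genetic variance (typically the additive
#'   variance from a GREML fit).
#' @param variance_ratios nondecreasing, first element 0.
#' @param dirichlet_alpha Dirichlet concentration per component.
#' @param n_iter,burn_in,thin chain controls.
#' @param seed integer seed; identical seeds give identical chains.
#' @param pi_fixed optional fixed mixture proportions (length 4; disables
#'   the Dirichlet update) — used for degenerate-prior cross-checks.
#' @param update_sigma_g if `TRUE`, `sigma_g2` is re-sampled from its
#'   scaled-inverse-chi-square full conditional instead of being held
#'   fixed.
#' @return A `bayesr_priors` list.
#' @export
bayesr_priors <- function(sigma_g2,
                          variance_ratios = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_alpha = c(1, 1, 1, 1),
                          n_iter = 50000, burn_in = 10000, thin = 10,
                          seed = 1, pi_fixed = NULL,
                          update_sigma_g = FALSE) {
  if (sigma_g2 <= 0) stop("sigma_g2 must be positive")
  if (variance_ratios[1] != 0) stop("first variance ratio must be 0")
  if (is.unsorted(variance_ratios)) stop("variance ratios must be nondecreasing")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (length(dirichlet_alpha) != length(variance_ratios))
    stop("dirichlet_alpha must match variance_ratios in length")
  if (!is.null(pi_fixed)) {
    if (length(pi_fixed) != length(variance_ratios) ||
        abs(sum(pi_fixed) - 1) > 1e-9 || any(pi_fixed < 0))
      stop("pi_fixed must be a probability vector over the components")
  }
  structure(list(variance_ratios = variance_ratios, sigma_g2 = sigma_g2,
                 dirichlet_alpha = dirichlet_alpha, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), pi_fixed = pi_fixed,
                 update_sigma_g = update_sigma_g),
            class = "bayesr_priors")
}

#' Mixture component variances implied by the priors
#'
#' @param priors a [bayesr_priors()].
#' @return `variance_ratios * sigma_g2`.
#' @export
component_variances <- function(priors) {
  stopifnot(inherits(priors, "bayesr_priors"))
  priors$variance_ratios * priors$sigma_g2
}

#' Fit BayesR by Gibbs sampling
#'
#' Single-site Gibbs sampler for
#' `y = Xb + M1 m + Ww + Z1 Qq + Z2 s + e` with each SNP effect drawn from
#' one of four Gaussian components (the first a point mass at zero).
#' Genotypes are centered by twice the allele frequency (same coding as
#' [compute_grm()]). Per iteration: fixed effects, each nuisance random
#' term and its variance (scaled-inverse-chi-square, nu = 4), every SNP in
#' a re-randomized order (component membership from the
#' effect-integrated likelihood, then the effect from its Gaussian full
#' conditional), the mixture proportions from
#' `Dirichlet(alpha + counts)`, and the residual variance.
#'
#' @param design a [build_design()] result.
#' @param geno a [genotype_matrix()] covering at least the phenotyped
#'   animals; predictions are produced for every individual in it.
#' @param priors a [bayesr_priors()].
#' @param random override of nuisance random terms (see [fit_reml()]).
#' @return A `bayesr_fit`: `snp_effect_means`, `component_probs` (m x 4,
#'   rows sum to 1), `pi_mean`, `gbv` (named, for all individuals in
#'   `geno`), `other_effect_means`, `chain_diagnostics` (effective sample
#'   sizes of the residual variance and of the nonzero-SNP count),
#'   `residual_drift` (max difference between the incrementally updated
#'   and the recomputed residual) and the thinned traces.
#' @export
run_bayesr <- function(design, geno, priors, random = NULL) {
  stopifnot(inherits(design, "pheno_design"), inherits(geno, "genotype_matrix"),
            inherits(priors, "bayesr_priors"))
  if (!all(design$ids %in% geno$ids))
    stop("genotypes must cover all phenotyped animals")
  terms <- active_terms(design, random)

  Z <- geno$calls
  storage.mode(Z) <- "double"
  p <- colMeans(Z, na.rm = TRUE) / 2
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) stop("all SNPs monomorphic")
  Z <- Z[, keep, drop = FALSE]
  p <- p[keep]
  Mall <- sweep(Z, 2, 2 * p)
  Mall[is.na(Mall)] <- 0
  M <- Mall[match(design$ids, geno$ids), , drop = FALSE]

  class_idx <- list(); class_nlev <- integer(0); class_scale <- numeric(0)
  term_names <- character(0)
  vp <- var(design$y)
  if ("maternal" %in% terms) {
    dl <- sort(unique(design$dam[!is.na(design$dam)]))
    class_idx <- c(class_idx, list(ifelse(is.na(design$dam), -1L,
                                          match(design$dam, dl) - 1L)))
    class_nlev <- c(class_nlev, length(dl))
    class_scale <- c(class_scale, 0.05 * vp)
    term_names <- c(term_names, "maternal")
  }
  if ("sireflock" %in% terms) {
    sl <- sort(unique(design$sf[!is.na(design$sf)]))
    class_idx <- c(class_idx, list(ifelse(is.na(design$sf), -1L,
                                          match(design$sf, sl) - 1L)))
    class_nlev <- c(class_nlev, length(sl))
    class_scale <- c(class_scale, 0.05 * vp)
    term_names <- c(term_names, "sireflock")
  }
  Qm <- if ("breed" %in% terms) design$Q else
    matrix(0, design$n, 0)

  set.seed(priors$seed)
  res <- bayesr_gibbs_cpp(design$y, design$X, M,
                          class_idx, as.integer(class_nlev), class_scale,
                          Qm, 0.05 * vp,
                          priors$variance_ratios, priors$sigma_g2,
                          priors$dirichlet_alpha,
                          priors$n_iter, priors$burn_in, priors$thin,
                          priors$pi_fixed %||% numeric(0),
                          priors$update_sigma_g,
                          4, 4, 0.5 * vp)

  snp_means <- setNames(res$snp_effect_means, geno$snp_ids[keep])
  comp_probs <- res$component_probs
  rownames(comp_probs) <- geno$snp_ids[keep]
  gbv <- drop(Mall %*% res$snp_effect_means)
  names(gbv) <- geno$ids
  other <- list()
  for (i in seq_along(term_names)) other[[term_names[i]]] <- res$class_means[[i]]
  if (ncol(Qm) > 0) other$breed <- setNames(res$breed_means, colnames(design$Q))
  diag_ <- list(ess_sigma_e = effective_sample_size(res$sigma_e_trace),
                ess_n_nonzero = effective_sample_size(res$nnz_trace))
  structure(list(snp_effect_means = snp_means,
                 component_probs = comp_probs,
                 pi_mean = res$pi_mean,
                 gbv = gbv,
                 fixed_means = setNames(res$fixed_means, colnames(design$X)),
                 other_effect_means = other,
                 chain_diagnostics = diag_,
                 sigma_e_trace = res$sigma_e_trace,
                 sigma_g_trace = res$sigma_g_trace,
                 nnz_trace = res$nnz_trace,
                 n_saved = res$n_saved,
                 residual_drift = res$residual_drift,
                 priors = priors,
                 method = "BayesR"),
            class = "bayesr_fit")
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat(sprintf("BayesR fit: %d SNPs, %d saved samples\n",
              length(x$snp_effect_means), x$n_saved))
  cat("  posterior mixture proportions:",
      paste(sprintf("%.4f", x$pi_mean), collapse = ", "), "\n")
  cat(sprintf("  ESS(sigma_e2) = %.0f, ESS(#nonzero) = %.0f, residual drift %.2e\n",
              x$chain_diagnostics$ess_sigma_e,
              x$chain_diagnostics$ess_n_nonzero, x$residual_drift))
  invisible(x)
}

#' @export
coef.bayesr_fit <- function(object, ...) object$snp_effect_means
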