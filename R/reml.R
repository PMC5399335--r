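#' Restricted maximum likelihood for the multi-breed mixed model
#'
#' Estimates the variance components of
#' `y = Xb + Z1 a + W w + Z1 Q q + Z2 s + e` with `a ~ N(0, K sigma_a^2)`
#' (`K` the pedigree or genomic relationship matrix) and i.i.d. maternal,
#' breed and sire-by-flock terms, by average-information REML with an
#' expectation-maximization fallback whenever an AI update would leave the
#' parameter space. Components are bounded below at `1e-8` times the total
#' variance. Standard errors come from the inverse average-information
#' matrix; the heritability and its standard error (delta method) use the
#' denominator `v_additive + v_maternal + v_sireflock + v_residual`.
#'
#' @param design a [build_design()] result.
#' @param rel a [relmat()] covering the phenotyped animals.
#' @param start optional [variance_components()] starting values; the
#'   default assigns half the phenotypic variance to the residual and
#'   splits the rest equally among the modeled random terms.
#' @param random override of the nuisance random terms to fit (subset of
#'   `"maternal"`, `"breed"`, `"sireflock"`); default: all terms the
#'   design supports.
#' @param max_iter,tol_loglik,tol_grad convergence controls: iteration cap,
#'   relative log-likelihood change, gradient norm.
#' @param verbose print per-iteration progress.
#' @return A `reml_fit` with `components` ([variance_components()] with
#'   `se_h2` filled), `loglik`, `n_iter`, `converged`, `se`, `gradient`
#'   and the average-information matrix `ai`.
#' @export
fit_reml <- function(design, rel, start = NULL, random = NULL,
                     max_iter = 200, tol_loglik = 1e-8, tol_grad = 1e-6,
                     verbose = FALSE) {
  stopifnot(inherits(design, "pheno_design"), inherits(rel, "relmat"))
  terms <- active_terms(design, random)
  K <- term_covariances(design, rel, terms)
  tnames <- names(K)
  y <- design$y
  X <- design$X
  n <- length(y)
  vp <- var(y)

  theta <- if (is.null(start)) {
    k <- length(tnames) - 1L
    setNames(c(rep(0.5 * vp / k, k), 0.5 * vp), tnames)
  } else {
    s0 <- c(additive = start$v_additive, maternal = start$v_maternal,
            breed = start$v_breed, sireflock = start$v_sireflock,
            residual = start$v_residual)[tnames]
    if (any(s0 <= 0)) stop("starting variances must be positive")
    s0
  }
  floor_fun <- function(th) pmax(th, 1e-8 * sum(th))

  eval_point <- function(th) {
    V <- matrix(0, n, n)
    for (t_ in tnames) V <- V + th[[t_]] * K[[t_]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(V + diag(1e-6 * mean(diag(V)), n))
    }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    chx <- chol(XtViX)
    P <- Vi - crossprod(XtVi, chol2inv(chx) %*% XtVi)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    grad <- vapply(tnames, function(t_)
      -0.5 * (sum(P * K[[t_]]) - drop(crossprod(Py, K[[t_]] %*% Py))),
      numeric(1))
    U <- vapply(tnames, function(t_) drop(K[[t_]] %*% Py), numeric(n))
    AI <- 0.5 * crossprod(U, P %*% U)
    em_num <- vapply(tnames, function(t_)
      drop(crossprod(Py, K[[t_]] %*% Py)), numeric(1))
    em_den <- vapply(tnames, function(t_) sum(P * K[[t_]]), numeric(1))
    list(ll = ll, grad = grad, AI = AI, em_num = em_num, em_den = em_den)
  }

  ev <- eval_point(theta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$AI, ev$grad), error = function(e) NULL)
    prop <- if (is.null(step)) NULL else theta + step
    use_em <- is.null(prop) || any(prop <= 0)
    if (use_em) {
      # EM-like multiplicative update: keeps every component positive
      ratio <- ifelse(ev$em_den > 0, ev$em_num / ev$em_den, 1)
      prop <- theta * ratio
    }
    prop <- floor_fun(prop)
    ev_new <- eval_point(prop)
    halves <- 0
    while (ev_new$ll < ev$ll - 1e-10 && halves < 8) {
      prop <- floor_fun((theta + prop) / 2)
      ev_new <- eval_point(prop)
      halves <- halves + 1
    }
    if (ev_new$ll < ev$ll - 1e-10) {
      # no uphill step found: declare convergence at the current point
      break
    }
    dll <- ev_new$ll - ev$ll
    theta <- prop
    ev <- ev_new
    if (verbose)
      message(sprintf("iter %d: logLik %.6f (%s)", it, ev$ll,
                      if (use_em) "EM" else "AI"))
    at_floor <- theta <= 1.0000001e-8 * sum(theta)
    gproj <- ev$grad
    gproj[at_floor & gproj < 0] <- 0
    if (abs(dll) < tol_loglik * (1 + abs(ev$ll)) ||
        sqrt(sum(gproj^2)) < tol_grad) {
      converged <- TRUE
      break
    }
  }

  se <- tryCatch(sqrt(diag(solve(ev$AI))), error = function(e)
    rep(NA_real_, length(theta)))
  names(se) <- tnames
  get0v <- function(nm) if (nm %in% tnames) unname(theta[nm]) else 0
  comp <- variance_components(v_additive = get0v("additive"),
                              v_maternal = get0v("maternal"),
                              v_breed = get0v("breed"),
                              v_sireflock = get0v("sireflock"),
                              v_residual = get0v("residual"))
  # delta-method SE for h2 (breed variance not in the denominator)
  dn <- setdiff(tnames, "breed")
  S <- sum(theta[dn])
  d <- setNames(numeric(length(tnames)), tnames)
  d[dn] <- -theta[["additive"]] / S^2
  d["additive"] <- (S - theta[["additive"]]) / S^2
  covm <- tryCatch(solve(ev$AI), error = function(e) NULL)
  comp$se_h2 <- if (is.null(covm)) NA_real_ else
    sqrt(max(0, drop(t(d) %*% covm %*% d)))

  structure(list(components = comp, loglik = ev$ll, n_iter = it,
                 converged = converged, se = se, gradient = ev$grad,
                 ai = ev$AI, terms = tnames, n = n,
                 rel_source = rel$source, trait = design$trait_label),
            class = "reml_fit")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the REML criterion
#' `-0.5 (log|V| + log|X'V^-1 X| + y' P y)` for a supplied set of
#' components — useful for profiling and for grid-search cross-checks.
#'
#' @inheritParams fit_reml
#' @param vc a [variance_components()].
#' @return The restricted log-likelihood (numeric scalar).
#' @export
reml_loglik <- function(design, rel, vc, random = NULL) {
  terms <- active_terms(design, random)
  K <- term_covariances(design, rel, terms)
  th <- c(additive = vc$v_additive, maternal = vc$v_maternal,
          breed = vc$v_breed, sireflock = vc$v_sireflock,
          residual = vc$v_residual)[names(K)]
  n <- length(design$y)
  V <- matrix(0, n, n)
  for (t_ in names(K)) V <- V + th[[t_]] * K[[t_]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(design$X, Vi)
  XtViX <- XtVi %*% design$X
  chx <- chol(XtViX)
  Py <- drop((Vi - crossprod(XtVi, chol2inv(chx) %*% XtVi)) %*% design$y)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
            sum(design$y * Py))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s relationships), trait '%s', n = %d\n",
              x$rel_source, x$trait, x$n))
  cat(sprintf("  logLik %.4f after %d iterations (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  print(x$components)
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  v <- unlist(object$components[c("v_additive", "v_maternal", "v_breed",
                                  "v_sireflock", "v_residual")])
  keep <- c("additive", "maternal", "breed", "sireflock", "residual") %in%
    object$terms
  out <- data.frame(component = names(v)[keep], estimate = unname(v)[keep],
                    se = unname(object$se), stringsAsFactors = FALSE)
  structure(list(table = out, h2 = object$components$h2,
                 se_h2 = object$components$se_h2, loglik = object$loglik,
                 converged = object$converged), class = "summary.reml_fit")
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("h2 = %.3f (SE %.3f), logLik = %.3f\n", x$h2, x$se_h2, x$loglik))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) {
  v <- c(additive = object$components$v_additive,
         maternal = object$components$v_maternal,
         breed = object$components$v_breed,
         sireflock = object$components$v_sireflock,
         residual = object$components$v_residual)
  v[object$terms]
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$terms), class = "logLik")
}
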