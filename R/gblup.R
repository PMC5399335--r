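# incidence matrix: rows = observations, columns = levels (dense; sizes in
# this package stay well inside dense-solver territory)
incidence <- function(labels, levels) {
  Z <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  ok <- !is.na(labels)
  Z[cbind(which(ok), match(labels[ok], levels))] <- 1
  Z
}

# random-term blocks shared by solve_mme and reliability
mme_blocks <- function(design, rel, vc, random) {
  terms <- active_terms(design, random)
  terms <- terms[c(maternal = vc$v_maternal, breed = vc$v_breed,
                   sireflock = vc$v_sireflock)[terms] > 0]
  blocks <- list()
  if ("maternal" %in% terms) {
    dl <- sort(unique(design$dam[!is.na(design$dam)]))
    blocks$maternal <- list(Z = incidence(design$dam, dl), v = vc$v_maternal)
  }
  if ("breed" %in% terms)
    blocks$breed <- list(Z = design$Q, v = vc$v_breed)
  if ("sireflock" %in% terms) {
    sl <- sort(unique(design$sf[!is.na(design$sf)]))
    blocks$sireflock <- list(Z = incidence(design$sf, sl), v = vc$v_sireflock)
  }
  blocks
}

# phenotypic covariance V = va K_obs + sum_t vt Z_t Z_t' + ve I and its
# pieces; Kobs rows/cols follow the observation order
mme_core <- function(design, rel, vc, blocks) {
  oi <- match(design$ids, rel$ids)
  if (anyNA(oi))
    stop("relationship matrix does not cover all phenotyped animals")
  n <- design$n
  V <- vc$v_additive * rel$values[oi, oi, drop = FALSE]
  for (b in blocks) V <- V + b$v * tcrossprod(b$Z)
  diag(V) <- diag(V) + vc$v_residual
  ch <- chol(V)
  Vi <- chol2inv(ch)
  X <- design$X
  XtVi <- crossprod(X, Vi)
  beta <- drop(solve(XtVi %*% X, XtVi %*% design$y))
  r <- design$y - drop(X %*% beta)
  Vir <- drop(Vi %*% r)
  list(oi = oi, Vi = Vi, XtVi = XtVi, beta = beta, Vir = Vir)
}

#' Solve the mixed-model equations for breeding values
#'
#' Best linear unbiased prediction for
#' `y = Xb + Z1 a + W w + Z1 Q q + Z2 s + e` at fixed variance components,
#' with `a` covering every individual in the relationship matrix: animals
#' without phenotypes (e.g. validation sires) receive predictions through
#' their relationship rows. Fixed effects are the generalized
#' least-squares solutions. The solutions are computed through the
#' phenotypic covariance `V` (equivalent to Henderson's equations but
#' valid even when the genomic relationship matrix is singular, as the
#' VanRaden matrix is under observed-frequency centering); the returned
#' diagnostic `mme_residual` is the maximum absolute residual of the
#' Henderson system in its G-multiplied form, which must be tiny relative
#' to `rhs_scale`.
#'
#' @param design a [build_design()] result.
#' @param rel a [relmat()] covering phenotyped animals and `predict_ids`.
#' @param vc a [variance_components()] (e.g. from [fit_reml()]).
#' @param predict_ids ids whose breeding values to report (default: every
#'   individual in `rel`).
#' @param method tag stored on the result (e.g. `"GBLUP-50k"`).
#' @param random override of the nuisance random terms (see [fit_reml()]).
#' @return A `gbv_prediction`: `ids`, `gbv`, `fixed_solutions`, `method`,
#'   `mme_residual`, and the solutions for every animal in `$all_gbv`.
#' @export
solve_mme <- function(design, rel, vc, predict_ids = NULL,
                      method = "GBLUP", random = NULL) {
  stopifnot(inherits(design, "pheno_design"), inherits(rel, "relmat"),
            inherits(vc, "variance_components"))
  if (vc$v_residual <= 0) stop("residual variance must be positive")
  if (vc$v_additive <= 0) stop("additive variance must be positive")
  predict_ids <- as.character(predict_ids %||% rel$ids)
  missing_ids <- setdiff(predict_ids, rel$ids)
  if (length(missing_ids))
    stop("predict_ids not in the relationship matrix: ",
         paste(head(missing_ids, 5), collapse = ", "))

  blocks <- mme_blocks(design, rel, vc, random)
  core <- mme_core(design, rel, vc, blocks)
  a_hat <- vc$v_additive *
    drop(rel$values[, core$oi, drop = FALSE] %*% core$Vir)
  names(a_hat) <- rel$ids
  u_hat <- lapply(blocks, function(b)
    setNames(b$v * drop(crossprod(b$Z, core$Vir)), colnames(b$Z)))

  # Henderson-system consistency check (a-rows premultiplied by G so the
  # check is defined for singular G): G Za'(fit - y) + (ve/va) a = 0, etc.
  Za <- incidence(design$ids, rel$ids)
  fit_obs <- drop(design$X %*% core$beta) + a_hat[design$ids]
  for (t_ in names(blocks))
    fit_obs <- fit_obs + drop(blocks[[t_]]$Z %*% u_hat[[t_]])
  dres <- fit_obs - design$y
  res_b <- crossprod(design$X, dres)
  res_a <- rel$values %*% crossprod(Za, dres) +
    (vc$v_residual / vc$v_additive) * a_hat
  res_u <- unlist(lapply(names(blocks), function(t_)
    crossprod(blocks[[t_]]$Z, dres) +
      (vc$v_residual / blocks[[t_]]$v) * u_hat[[t_]]))
  mme_res <- max(abs(c(res_b, res_a, res_u)))
  rhs_scale <- max(abs(c(crossprod(design$X, design$y),
                         rel$values %*% crossprod(Za, design$y))))

  structure(list(ids = predict_ids,
                 gbv = a_hat[predict_ids],
                 all_gbv = a_hat,
                 other_solutions = u_hat,
                 fixed_solutions = setNames(core$beta, colnames(design$X)),
                 method = method,
                 mme_residual = mme_res,
                 rhs_scale = rhs_scale,
                 vc = vc,
                 terms = names(blocks)),
            class = "gbv_prediction")
}

#' @export
print.gbv_prediction <- function(x, ...) {
  cat(sprintf("%s predictions for %d individuals (MME residual %.2e, rhs scale %.2e)\n",
              x$method, length(x$ids), x$mme_residual, x$rhs_scale))
  print(summary(unname(x$gbv)))
  invisible(x)
}

#' @export
coef.gbv_prediction <- function(object, ...) object$fixed_solutions

#' Prediction-error-variance based reliability
#'
#' `1 - PEV_i / (v_additive * K_ii)` where
#' `PEV_i = v_additive K_ii - v_additive^2 k_i' P k_i`, `k_i` the
#' relationship row of animal `i` to the phenotyped animals and `P` the
#' REML projection of the phenotypic covariance — an unphenotyped animal
#' unrelated to every phenotyped one has reliability 0, and reliability
#' approaches 1 for a phenotyped animal as heritability approaches 1.
#'
#' @inheritParams solve_mme
#' @param ids animals to report (default: every individual in `rel`).
#' @return Named numeric vector of reliabilities in `[0, 1]`.
#' @export
reliability <- function(design, rel, vc, ids = NULL, random = NULL) {
  ids <- as.character(ids %||% rel$ids)
  if (!all(ids %in% rel$ids)) stop("ids must be in the relationship matrix")
  blocks <- mme_blocks(design, rel, vc, random)
  core <- mme_core(design, rel, vc, blocks)
  X <- design$X
  P <- core$Vi - crossprod(core$XtVi, solve(core$XtVi %*% X, core$XtVi))
  Ki <- rel$values[ids, core$oi, drop = FALSE]
  num <- vc$v_additive * rowSums((Ki %*% P) * Ki)
  kii <- diag(rel$values)[match(ids, rel$ids)]
  r2 <- ifelse(kii > 0, num / kii, 0)
  setNames(pmin(pmax(r2, 0), 1), ids)
}
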