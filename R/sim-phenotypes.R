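#' Simulate phenotypes under the multi-breed mixed model
#'
#' Generates one trait record per reference animal as
#' `y = Xb + tbv + maternal(dam) + breed + sire-by-flock + e`.
#' Fixed effects are birth type, rearing type, gender, age at measurement
#' and contemporary group (site x birth year x management group), all with
#' modest magnitudes (at most 0.5 phenotypic SD). Random-term variances are
#' the configured fractions of the phenotypic variance; the additive
#' fraction is anchored on the realized variance of the true breeding
#' values among the phenotyped animals so that the configured heritability
#' holds for the simulated records.
#'
#' @param geno,ped,truth components of a [simulate_population()] result.
#' @param config the [sim_config()] used (supplies the variance fractions).
#' @param seed integer seed for the environmental draws.
#' @param fixed_effects if `FALSE`, no fixed effects (not even an
#'   intercept) are simulated: with all nuisance variances zero and
#'   `h2_target` at 1 the record equals the true breeding value.
#' @return A `pheno_design` (see [build_design()]) with the raw phenotype
#'   table in `$table` and the realized variance components in
#'   `$realized_var_components`.
#' @export
simulate_phenotypes <- function(geno, ped, truth, config, seed = 1,
                                fixed_effects = TRUE) {
  set.seed(as.integer(seed))
  ref <- ped[ped$role == "reference", , drop = FALSE]
  n <- nrow(ref)
  if (n == 0) stop("no reference animals to phenotype")
  if (config$var_maternal > 0 && anyNA(ref$dam))
    stop("maternal variance requested but some phenotyped animals have no dam")
  if (!all(ref$id %in% geno$ids)) stop("phenotyped animals must be genotyped")

  tbv <- truth$tbv[ref$id]
  v_add <- var(tbv)
  h2 <- config$h2_target
  sigma_p2 <- v_add / h2                     # anchor the fractions on realized V_A
  v_mat <- config$var_maternal * sigma_p2
  v_brd <- config$var_breed * sigma_p2
  v_sf <- config$var_sireflock * sigma_p2
  v_res <- sigma_p2 * (1 - h2 - config$var_maternal - config$var_breed -
                         config$var_sireflock)
  sd_p <- sqrt(sigma_p2)

  dams <- unique(ref$dam)
  mat_eff <- setNames(rnorm(length(dams), 0, sqrt(v_mat)), dams)
  breeds <- attr(ped, "breeds")
  breed_eff <- setNames(rnorm(length(breeds), 0, sqrt(v_brd)), breeds)
  Q <- breed_fractions(ped, ref$id)
  sf_class <- paste(ref$sire, ref$flock, sep = ":")
  sf_lev <- unique(sf_class)
  sf_eff <- setNames(rnorm(length(sf_lev), 0, sqrt(v_sf)), sf_lev)
  e <- rnorm(n, 0, sqrt(v_res))

  tab <- data.frame(id = ref$id, stringsAsFactors = FALSE)
  xb <- numeric(n)
  if (fixed_effects) {
    tab$birth_type <- sample(1:3, n, replace = TRUE, prob = c(0.40, 0.45, 0.15))
    tab$rearing_type <- pmin(tab$birth_type, sample(1:2, n, replace = TRUE))
    tab$gender <- ref$sex
    tab$age <- round(runif(n, 210, 270))
    tab$mgmt <- sample(1:2, n, replace = TRUE)
    xb <- 10 +
      c(0, -0.3, -0.5)[tab$birth_type] * sd_p +
      c(0, -0.2)[tab$rearing_type] * sd_p +
      ifelse(tab$gender == "M", 0.3, 0) * sd_p +
      (tab$age - 240) / 30 * 0.3 * sd_p
  } else {
    tab$age <- NA_real_
  }
  tab$dam <- ref$dam
  tab$sire <- ref$sire
  tab$flock <- ref$flock
  tab$birth_year <- ref$birth_year
  tab$trait <- xb + tbv + mat_eff[ref$dam] + drop(Q %*% breed_eff) +
    sf_eff[sf_class] + e

  realized <- list(v_additive = v_add,
                   v_maternal = var(mat_eff[ref$dam]),
                   v_breed = var(drop(Q %*% breed_eff)),
                   v_sireflock = var(sf_eff[sf_class]),
                   v_residual = var(e),
                   sigma_p2_target = sigma_p2)
  design <- build_design(tab, ped, trait = "trait")
  design$realized_var_components <- realized
  design
}

#' Simulate progeny-test EBVs for validation sires
#'
#' The benchmark breeding values come from a half-sib progeny-mean model:
#' the reliability (squared accuracy) of a sire EBV from `n` progeny is
#' `acc^2 = 0.25 n h2 / (1 + 0.25 (n - 1) h2)`, and the EBV is generated as
#' `acc^2 * tbv + acc * sqrt(1 - acc^2) * sigma_a * z` with `z` standard
#' normal, so that `cor(ebv, tbv) = acc` by construction.
#'
#' @param truth `truth` component of a simulation (supplies `tbv` and the
#'   additive standard deviation).
#' @param sires ids of the validation sires.
#' @param n_progeny progeny count per sire (scalar or vector).
#' @param h2 heritability of the progeny-tested trait, in (0, 1].
#' @param seed integer seed.
#' @return Data frame with columns `sire_id`, `ebv`, `accuracy`,
#'   `n_progeny`.
#' @export
simulate_progeny_ebv <- function(truth, sires, n_progeny, h2, seed = 1) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  sires <- as.character(sires)
  if (!all(sires %in% names(truth$tbv))) stop("sires must have true breeding values")
  n_progeny <- rep_len(n_progeny, length(sires))
  if (any(n_progeny < 1)) stop("n_progeny must be at least 1")
  set.seed(as.integer(seed))
  acc <- sqrt(0.25 * n_progeny * h2 / (1 + 0.25 * (n_progeny - 1) * h2))
  sigma_a <- sqrt(truth$realized_var_components$v_additive %||%
                    truth$realized_var_components$v_additive_founders)
  tbv <- truth$tbv[sires]
  ebv <- acc^2 * tbv + acc * sqrt(1 - acc^2) * sigma_a * rnorm(length(sires))
  data.frame(sire_id = sires, ebv = ebv, accuracy = acc,
             n_progeny = n_progeny, row.names = NULL,
             stringsAsFactors = FALSE)
}
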