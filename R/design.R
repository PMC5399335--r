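#' Build the mixed-model design from a phenotype table
#'
#' Assembles the response and the fixed-effect design for the model
#' `y = Xb + Z1 a + W w + Z1 Q q + Z2 s + e`: categorical covariates
#' (birth type, rearing type, gender, contemporary group) are dummy-coded
#' with a dropped reference level, continuous covariates (age, weight) are
#' centered, the contemporary group is site x birth year x management
#' group, and the incidence structures for the additive, maternal,
#' breed-proportion and sire-by-flock terms are recorded as per-row labels
#' (the matrices themselves are formed at solve time).
#'
#' @param pheno_table data frame with columns `id`, the trait, and any of
#'   `birth_type`, `rearing_type`, `gender`, `age`, `weight`, `mgmt`,
#'   `flock`, `birth_year`, `dam`, `sire`.
#' @param ped a [pedigree()] covering the phenotyped animals (supplies the
#'   breed-proportion rows).
#' @param trait name of the trait column.
#' @return A `pheno_design` list: `y`, `X` (full-column-rank fixed design),
#'   `ids`, `dam` (NA for unknown: an all-zero maternal incidence row),
#'   `sf` (sire-by-flock class), `Q` (breed fractions), flags for which
#'   random terms are identifiable, and a log of dropped rows.
#' @export
build_design <- function(pheno_table, ped, trait) {
  if (!trait %in% names(pheno_table))
    stop("trait column '", trait, "' not found")
  tab <- as.data.frame(pheno_table, stringsAsFactors = FALSE)
  drop_log <- character(0)
  miss <- is.na(tab[[trait]])
  if (any(miss)) {
    drop_log <- sprintf("%s: missing %s", tab$id[miss], trait)
    tab <- tab[!miss, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no phenotyped rows left")
  y <- tab[[trait]]
  ids <- as.character(tab$id)

  # contemporary group: site x birth year x management group
  site <- tab$flock %||% rep("S1", nrow(tab))
  byr <- tab$birth_year %||% rep("Y1", nrow(tab))
  mgmt <- tab$mgmt %||% rep(1L, nrow(tab))
  cg <- factor(paste(site, byr, mgmt, sep = ":"))

  terms <- list()
  for (v in c("birth_type", "rearing_type", "gender")) {
    if (!is.null(tab[[v]])) {
      f <- factor(tab[[v]])
      if (nlevels(f) >= 2) terms[[v]] <- f
    }
  }
  if (nlevels(cg) >= 2) terms[["cg"]] <- cg
  cont <- list()
  for (v in c("age", "weight")) {
    x <- tab[[v]]
    if (!is.null(x) && !all(is.na(x)) && sd(x, na.rm = TRUE) > 0)
      cont[[v]] <- x - mean(x, na.rm = TRUE)
  }
  X <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(terms)) {
    df <- as.data.frame(terms)
    Xf <- model.matrix(~ ., data = df)
    X <- cbind(X, Xf[, -1, drop = FALSE])
  }
  for (v in names(cont)) X <- cbind(X, setNames(data.frame(cont[[v]]), v)[[1]])
  if (length(cont))
    colnames(X)[(ncol(X) - length(cont) + 1):ncol(X)] <- names(cont)

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; confounded columns: ",
         paste(bad, collapse = ", "))
  }

  Q <- breed_fractions(ped, ids)
  has_breed <- qr(Q)$rank > 1
  dam <- as.character(tab$dam %||% rep(NA_character_, nrow(tab)))
  unknown_dam <- is.na(dam)
  if (any(unknown_dam))
    drop_log <- c(drop_log,
                  sprintf("%s: unknown dam (zero maternal incidence row)",
                          ids[unknown_dam]))
  sire <- as.character(tab$sire %||% rep(NA_character_, nrow(tab)))
  sf <- ifelse(is.na(sire) | is.na(site), NA_character_,
               paste(sire, site, sep = ":"))
  has_maternal <- any(!unknown_dam) && length(unique(dam[!unknown_dam])) > 1
  has_sireflock <- any(!is.na(sf)) &&
    length(unique(sf[!is.na(sf)])) > 1 &&
    length(unique(sf[!is.na(sf)])) < length(sf)

  structure(list(y = y, X = X, ids = ids, dam = dam, sf = sf, Q = Q,
                 trait_label = trait, has_breed = has_breed,
                 has_maternal = has_maternal, has_sireflock = has_sireflock,
                 drop_log = drop_log, n = length(y), table = tab),
            class = "pheno_design")
}

#' @export
print.pheno_design <- function(x, ...) {
  cat(sprintf("pheno_design '%s': n = %d, %d fixed-effect columns\n",
              x$trait_label, x$n, ncol(x$X)))
  cat(sprintf("  random terms: additive%s%s%s\n",
              if (x$has_maternal) " + maternal" else "",
              if (x$has_breed) " + breed" else "",
              if (x$has_sireflock) " + sire:flock" else ""))
  if (length(x$drop_log))
    cat(sprintf("  %d rows flagged/dropped\n", length(x$drop_log)))
  invisible(x)
}

# Which random terms (besides additive + residual) enter a fit, from the
# design flags and an optional user override.
active_terms <- function(design, random = NULL) {
  auto <- c("maternal", "breed", "sireflock")[c(design$has_maternal,
                                                design$has_breed,
                                                design$has_sireflock)]
  if (is.null(random)) return(auto)
  random <- match.arg(random, c("maternal", "breed", "sireflock"),
                      several.ok = TRUE)
  intersect(random, auto)
}

# Dense covariance contributions K_t (n x n) for each random term, used by
# the REML likelihood: additive uses the relationship matrix, the class
# terms use same-class indicators, breed uses QQ'.
term_covariances <- function(design, rel, terms) {
  ids <- design$ids
  ri <- match(ids, rel$ids)
  if (anyNA(ri))
    stop("relationship matrix does not cover: ",
         paste(head(ids[is.na(ri)], 5), collapse = ", "))
  K <- list(additive = rel$values[ri, ri, drop = FALSE])
  if ("maternal" %in% terms) {
    d <- design$dam
    Km <- outer(d, d, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
    K$maternal <- Km
  }
  if ("breed" %in% terms) K$breed <- tcrossprod(design$Q)
  if ("sireflock" %in% terms) {
    s <- design$sf
    K$sireflock <- outer(s, s, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
  }
  K$residual <- diag(design$n)
  K
}
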