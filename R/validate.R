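# normalize a prediction object or data frame to (id, gbv)
as_gbv_table <- function(pred) {
  if (inherits(pred, c("gbv_prediction", "bayesr_fit"))) {
    ids <- if (inherits(pred, "gbv_prediction")) pred$ids else names(pred$gbv)
    gbv <- if (inherits(pred, "gbv_prediction")) pred$gbv else pred$gbv
    data.frame(id = as.character(ids), gbv = unname(gbv[ids]),
               stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(pred)
    names(df)[1:2] <- c("id", "gbv")
    df$id <- as.character(df$id)
    df
  }
}

# residualize a variable by removing group means over a label vector
residualize <- function(x, labels) {
  if (length(unique(labels)) < 2) return(x - mean(x))
  x - ave(x, labels, FUN = mean)
}

#' Empirical accuracy of genomic breeding values
#'
#' Pearson correlation of predicted breeding values with progeny-test
#' EBVs, reported per group, with the standard error
#' `sqrt((1 - r^2) / (n - 2))` and the slope of the ordinary least-squares
#' regression of EBV on GBV (the bias check: 1 means unbiased dispersion).
#' When `covariate_adjust` is supplied (e.g. Merino strain labels), both
#' variables are replaced by residuals from group-mean removal over those
#' labels before correlating, so across-stratum mean differences cannot
#' inflate the accuracy.
#'
#' @param pred a `gbv_prediction`, `bayesr_fit` or data frame
#'   (`id`, `gbv`).
#' @param ebv data frame with `sire_id` (or `id`) and `ebv` columns, as
#'   produced by [simulate_progeny_ebv()].
#' @param groups optional named vector mapping id to a reporting label
#'   (e.g. breed); default: a single group `"all"`.
#' @param covariate_adjust optional named vector mapping id to a strain
#'   label fitted out of both variables.
#' @return Data frame with `group_label`, `n`, `r`, `se`,
#'   `regression_coef` and a `flag` column (`"ok"`, `"zero_variance"`, or
#'   `"n_lt_3"`).
#' @export
accuracy <- function(pred, ebv, groups = NULL, covariate_adjust = NULL) {
  gt <- as_gbv_table(pred)
  eb <- as.data.frame(ebv)
  idcol <- if ("sire_id" %in% names(eb)) "sire_id" else "id"
  eb$id <- as.character(eb[[idcol]])
  dat <- merge(gt, eb[, c("id", "ebv")], by = "id")
  if (nrow(dat) == 0) stop("no paired observations")
  dat$group <- if (is.null(groups)) "all" else
    unname(groups[dat$id])
  out <- lapply(split(dat, dat$group), function(d) {
    x <- d$gbv; z <- d$ebv
    if (!is.null(covariate_adjust)) {
      lab <- unname(covariate_adjust[d$id])
      if (!anyNA(lab)) {
        x <- residualize(x, lab)
        z <- residualize(z, lab)
      }
    }
    n <- nrow(d)
    if (n < 3)
      return(data.frame(group_label = d$group[1], n = n, r = NA_real_,
                        se = NA_real_, regression_coef = NA_real_,
                        flag = "n_lt_3", stringsAsFactors = FALSE))
    if (sd(x) == 0 || sd(z) == 0)
      return(data.frame(group_label = d$group[1], n = n, r = NA_real_,
                        se = NA_real_, regression_coef = NA_real_,
                        flag = "zero_variance", stringsAsFactors = FALSE))
    r <- cor(x, z)
    data.frame(group_label = d$group[1], n = n, r = r,
               se = sqrt((1 - r^2) / (n - 2)),
               regression_coef = unname(coef(lm(z ~ x))[2]),
               flag = "ok", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("accuracy_table", "data.frame")
  res
}

#' Compare prediction accuracy across marker panels within strata
#'
#' For each stratum (relatedness class or breed) and each panel, computes
#' the [accuracy()] statistics, plus pairwise panel differences in `r`
#' with a paired-bootstrap percentile interval (ids resampled jointly, so
#' the pairing between panels is preserved).
#'
#' @param pred_by_panel named list of predictions (one per panel).
#' @param ebv as in [accuracy()].
#' @param strata a [classify_relatedness()] result or a named vector
#'   mapping id to stratum label.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param covariate_adjust as in [accuracy()].
#' @return List with `accuracy` (per stratum x panel, with a `low_n` flag
#'   for strata smaller than 10) and `differences` (per stratum and panel
#'   pair: point difference and bootstrap interval).
#' @export
stratified_comparison <- function(pred_by_panel, ebv, strata,
                                  n_boot = 1000, seed = 1,
                                  covariate_adjust = NULL) {
  if (is.null(names(pred_by_panel)))
    stop("pred_by_panel must be a named list")
  labels <- if (inherits(strata, "relatedness_groups")) {
    setNames(strata$stats$group, strata$stats$id)
  } else {
    setNames(as.character(strata), names(strata))
  }
  tabs <- lapply(pred_by_panel, as_gbv_table)
  eb <- as.data.frame(ebv)
  idcol <- if ("sire_id" %in% names(eb)) "sire_id" else "id"
  eb$id <- as.character(eb[[idcol]])
  common <- Reduce(intersect, c(lapply(tabs, `[[`, "id"), list(eb$id)))
  common <- intersect(common, names(labels))
  if (!length(common)) stop("no ids shared across panels, EBVs and strata")

  acc_rows <- list(); diff_rows <- list()
  panels <- names(pred_by_panel)
  set.seed(as.integer(seed))
  for (st in unique(labels[common])) {
    ids <- common[labels[common] == st]
    n <- length(ids)
    e <- eb$ebv[match(ids, eb$id)]
    g <- lapply(tabs, function(tb) tb$gbv[match(ids, tb$id)])
    adj <- if (is.null(covariate_adjust)) NULL else covariate_adjust[ids]
    rs <- vapply(panels, function(pn) {
      x <- g[[pn]]; z <- e
      if (!is.null(adj) && !anyNA(adj)) { x <- residualize(x, adj); z <- residualize(z, adj) }
      if (n < 3 || sd(x) == 0 || sd(z) == 0) NA_real_ else cor(x, z)
    }, numeric(1))
    for (pn in panels) {
      r <- rs[[pn]]
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        stratum = st, panel = pn, n = n, r = r,
        se = if (is.na(r)) NA_real_ else sqrt((1 - r^2) / (n - 2)),
        low_n = n < 10, stringsAsFactors = FALSE)
    }
    if (length(panels) >= 2 && n >= 3) {
      prs <- combn(panels, 2, simplify = FALSE)
      boot <- matrix(NA_real_, n_boot, length(prs))
      for (b in seq_len(n_boot)) {
        take <- sample.int(n, n, replace = TRUE)
        eb_b <- e[take]
        if (sd(eb_b) == 0) next
        r_b <- vapply(panels, function(pn) {
          x <- g[[pn]][take]
          if (sd(x) == 0) NA_real_ else cor(x, eb_b)
        }, numeric(1))
        boot[b, ] <- vapply(seq_along(prs), function(k)
          r_b[[prs[[k]][2]]] - r_b[[prs[[k]][1]]], numeric(1))
      }
      for (k in seq_along(prs)) {
        d0 <- rs[[prs[[k]][2]]] - rs[[prs[[k]][1]]]
        ci <- quantile(boot[, k], c(0.025, 0.975), na.rm = TRUE)
        diff_rows[[length(diff_rows) + 1L]] <- data.frame(
          stratum = st, panel_a = prs[[k]][1], panel_b = prs[[k]][2],
          diff = d0, boot_lo = unname(ci[1]), boot_hi = unname(ci[2]),
          n = n, stringsAsFactors = FALSE)
      }
    }
  }
  list(accuracy = do.call(rbind, acc_rows),
       differences = if (length(diff_rows)) do.call(rbind, diff_rows) else NULL)
}
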