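#' Quality-control thresholds
#'
#' Defaults follow standard SNP-array practice for sheep genomic
#' evaluation: SNPs are removed for call rate below 0.90, per-genotype
#' quality score below 0.6 (when a quality channel is supplied),
#' heterozygosity more than 3 SD from the panel mean, minor allele
#' frequency below 0.01, Hardy-Weinberg departure at p below 1e-15, and
#' location on the sex chromosomes; samples are removed as duplicates at a
#' genotype correlation of 0.98 or more.
#'
#' @param min_call_rate,min_quality_score,min_maf fractions in `[0, 1]`.
#' @param het_sd_limit positive SD multiplier.
#' @param hwe_p_floor probability.
#' @param duplicate_r correlation threshold.
#' @param excluded_chroms chromosome labels to drop.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_quality_score = 0.6,
                          het_sd_limit = 3, min_maf = 0.01,
                          hwe_p_floor = 1e-15, duplicate_r = 0.98,
                          excluded_chroms = c("X", "Y")) {
  fr <- c(min_call_rate, min_quality_score, min_maf)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (het_sd_limit <= 0) stop("het_sd_limit must be positive")
  structure(list(min_call_rate = min_call_rate,
                 min_quality_score = min_quality_score,
                 het_sd_limit = het_sd_limit, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor, duplicate_r = duplicate_r,
                 excluded_chroms = as.character(excluded_chroms)),
            class = "qc_thresholds")
}

qc_report <- function(kept_snps, kept_samples, removal_log, warnings = character(0)) {
  structure(list(kept_snps = kept_snps, kept_samples = kept_samples,
                 removal_log = removal_log, warnings = warnings),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: kept %d SNPs, %d samples; removed %d items\n",
              length(x$kept_snps), length(x$kept_samples),
              nrow(x$removal_log)))
  if (nrow(x$removal_log))
    print(table(x$removal_log$rule))
  invisible(x)
}

#' Filter SNPs by the standard array quality rules
#'
#' Rules are applied in a fixed, documented order — chromosome exclusion,
#' call rate, quality score (skipped when no quality channel is present),
#' heterozygosity deviation, minor allele frequency, Hardy-Weinberg — and
#' each removed SNP is attributed to the first rule it violates. The
#' heterozygosity rule compares each SNP's observed heterozygote fraction
#' with the mean and SD over the SNPs that survived the preceding rules.
#'
#' @param geno a [genotype_matrix()].
#' @param t a [qc_thresholds()].
#' @return A `qc_report` with `kept_snps`, all samples kept, and a
#'   `removal_log` data frame (`id`, `rule`, `value`).
#' @export
filter_snps <- function(geno, t = qc_thresholds()) {
  m <- length(geno$snp_ids)
  if (m == 0) stop("empty genotype matrix")
  calls <- geno$calls
  n_obs <- colSums(!is.na(calls))
  log_id <- character(0); log_rule <- character(0); log_val <- numeric(0)
  alive <- rep(TRUE, m)

  kill <- function(idx, rule, value) {
    idx <- idx[alive[idx]]
    if (length(idx)) {
      log_id <<- c(log_id, geno$snp_ids[idx])
      log_rule <<- c(log_rule, rep(rule, length(idx)))
      log_val <<- c(log_val, value[seq_along(idx)])
      alive[idx] <<- FALSE
    }
  }

  bad <- which(geno$chrom %in% t$excluded_chroms)
  kill(bad, "chromosome", rep(NA_real_, length(bad)))

  cr <- n_obs / nrow(calls)
  bad <- which(alive & cr < t$min_call_rate)
  kill(bad, "call_rate", cr[bad])

  if (!is.null(geno$call_quality)) {
    mq <- colMeans(geno$call_quality, na.rm = TRUE)
    bad <- which(alive & mq < t$min_quality_score)
    kill(bad, "quality_score", mq[bad])
  }

  het <- colMeans(calls == 1L, na.rm = TRUE)
  mu <- mean(het[alive]); s <- sd(het[alive])
  if (is.finite(s) && s > 0) {
    bad <- which(alive & abs(het - mu) > t$het_sd_limit * s)
    kill(bad, "heterozygosity", het[bad])
  }

  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- which(alive & (is.na(maf) | maf < t$min_maf))
  kill(bad, "maf", maf[bad])

  idx_alive <- which(alive)
  if (length(idx_alive)) {
    hwe_p <- vapply(idx_alive, function(j) {
      g <- calls[, j]
      hwe_test(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 0L, na.rm = TRUE))
    }, numeric(1))
    bad <- idx_alive[hwe_p < t$hwe_p_floor]
    kill(bad, "hwe", hwe_p[hwe_p < t$hwe_p_floor])
  }

  if (!any(alive))
    stop("quality control removed every SNP")
  qc_report(kept_snps = geno$snp_ids[alive],
            kept_samples = geno$ids,
            removal_log = data.frame(id = log_id, rule = log_rule,
                                     value = log_val,
                                     stringsAsFactors = FALSE))
}

#' Remove duplicate samples by genotype correlation
#'
#' Pairwise Pearson correlation of the 0/1/2 calls over jointly non-missing
#' SNPs; for each pair at or above the threshold the later-listed sample is
#' removed, so transitive duplicate groups keep exactly their first member.
#' Pairs sharing fewer than 100 SNPs are skipped with a logged warning.
#'
#' @param geno a [genotype_matrix()] with at least 2 samples.
#' @param t a [qc_thresholds()].
#' @return A `qc_report` with `kept_samples`, all SNPs kept, and a
#'   `removal_log` of (`id`, `rule = "duplicate"`, correlation).
#' @export
filter_duplicate_samples <- function(geno, t = qc_thresholds()) {
  n <- length(geno$ids)
  if (n < 2) stop("need at least 2 samples")
  Z <- t(geno$calls)                 # SNPs x samples
  storage.mode(Z) <- "double"
  has_na <- anyNA(Z)
  cc <- suppressWarnings(
    if (has_na) cor(Z, use = "pairwise.complete.obs") else cor(Z))
  overlap <- if (has_na) crossprod(!is.na(Z)) else
    matrix(nrow(Z), n, n)
  removed <- logical(n)
  log_id <- character(0); log_val <- numeric(0)
  warns <- character(0)
  for (i in seq_len(n - 1)) {
    if (removed[i]) next
    for (j in seq((i + 1), n)) {
      if (removed[j]) next
      if (overlap[i, j] < 100) {
        warns <- c(warns, sprintf("pair %s/%s skipped: only %d overlapping SNPs",
                                  geno$ids[i], geno$ids[j], overlap[i, j]))
        next
      }
      r <- cc[i, j]
      if (!is.na(r) && r >= t$duplicate_r) {
        removed[j] <- TRUE
        log_id <- c(log_id, geno$ids[j])
        log_val <- c(log_val, r)
      }
    }
  }
  qc_report(kept_snps = geno$snp_ids,
            kept_samples = geno$ids[!removed],
            removal_log = if (length(log_id))
              data.frame(id = log_id, rule = "duplicate", value = log_val,
                         stringsAsFactors = FALSE)
            else data.frame(id = character(0), rule = character(0),
                            value = numeric(0), stringsAsFactors = FALSE),
            warnings = warns)
}

#' Apply full quality control to a genotype matrix
#'
#' Runs [filter_snps()] then [filter_duplicate_samples()] and returns the
#' filtered genotypes plus the combined report.
#'
#' @inheritParams filter_snps
#' @return List with `geno` (filtered [genotype_matrix()]) and `report`.
#' @export
apply_qc <- function(geno, t = qc_thresholds()) {
  snp_rep <- filter_snps(geno, t)
  g1 <- subset_geno(geno, snps = snp_rep$kept_snps)
  dup_rep <- filter_duplicate_samples(g1, t)
  g2 <- subset_geno(g1, ids = dup_rep$kept_samples)
  report <- qc_report(kept_snps = snp_rep$kept_snps,
                      kept_samples = dup_rep$kept_samples,
                      removal_log = rbind(snp_rep$removal_log,
                                          dup_rep$removal_log),
                      warnings = c(snp_rep$warnings, dup_rep$warnings))
  list(geno = g2, report = report)
}
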