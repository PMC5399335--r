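#' Construct a genotype matrix container
#'
#' Holds biallelic SNP allele counts (dosage of the counted allele, coded
#' 0/1/2, `NA` for missing) for a set of individuals together with the marker
#' map and an optional per-genotype quality channel.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns.
#' @param ids individual identifiers (unique, length `nrow(calls)`).
#' @param snp_ids marker identifiers (unique, length `ncol(calls)`).
#' @param chrom chromosome label per SNP.
#' @param pos base-pair position per SNP.
#' @param counted_allele allele whose dosage is stored (recycled per SNP).
#' @param call_quality optional matrix of per-genotype scores in `[0, 1]`,
#'   same dimensions as `calls`.
#' @param morgan optional map position in Morgans (within chromosome), used
#'   by the simulator's recombination engine.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ids, snp_ids, chrom, pos,
                            counted_allele = "A", call_quality = NULL,
                            morgan = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == length(ids), ncol(calls) == length(snp_ids),
            length(chrom) == length(snp_ids), length(pos) == length(snp_ids))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (anyDuplicated(snp_ids)) stop("snp ids must be unique")
  vals <- calls[!is.na(calls)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("non-missing calls must be 0, 1 or 2")
  if (!is.null(call_quality)) {
    call_quality <- as.matrix(call_quality)
    stopifnot(all(dim(call_quality) == dim(calls)))
  }
  dimnames(calls) <- list(as.character(ids), as.character(snp_ids))
  structure(list(calls = calls,
                 ids = as.character(ids),
                 snp_ids = as.character(snp_ids),
                 chrom = chrom,
                 pos = as.integer(pos),
                 counted_allele = rep_len(counted_allele, length(snp_ids)),
                 call_quality = call_quality,
                 morgan = morgan),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d chromosomes, %.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$chrom)), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param geno a [genotype_matrix()].
#' @param ids individuals to keep (in the given order); `NULL` keeps all.
#' @param snps SNPs to keep; `NULL` keeps all.
#' @return A [genotype_matrix()].
#' @export
subset_geno <- function(geno, ids = NULL, snps = NULL) {
  ri <- if (is.null(ids)) seq_along(geno$ids) else match(ids, geno$ids)
  ci <- if (is.null(snps)) seq_along(geno$snp_ids) else match(snps, geno$snp_ids)
  if (anyNA(ri)) stop("unknown individual ids: ",
                      paste(head(ids[is.na(ri)], 5), collapse = ", "))
  if (anyNA(ci)) stop("unknown snp ids")
  genotype_matrix(geno$calls[ri, ci, drop = FALSE],
                  geno$ids[ri], geno$snp_ids[ci],
                  geno$chrom[ci], geno$pos[ci],
                  geno$counted_allele[ci],
                  if (is.null(geno$call_quality)) NULL
                  else geno$call_quality[ri, ci, drop = FALSE],
                  if (is.null(geno$morgan)) NULL else geno$morgan[ci])
}

#' Construct a pedigree table
#'
#' A data frame with one row per individual in topological order (parents
#' before offspring), carrying parentage, breed composition and cohort
#' labels.
#'
#' @param id,sire,dam identifiers; `NA` for unknown parents.
#' @param breed_fractions numeric matrix (individuals x breeds), rows
#'   nonnegative and summing to one; column names are the breed labels.
#' @param flock,birth_year cohort labels (optional).
#' @param sex "M"/"F" (optional).
#' @param role free label, e.g. "founder", "reference", "validation_high".
#' @return A `pedigree` data frame; breed fractions are stored as columns
#'   named `bf_<breed>`.
#' @export
pedigree <- function(id, sire = NA, dam = NA, breed_fractions, flock = NA,
                     birth_year = NA, sex = NA, role = NA) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  breed_fractions <- as.matrix(breed_fractions)
  if (nrow(breed_fractions) != n) stop("breed_fractions rows must match ids")
  if (any(breed_fractions < -1e-12)) stop("breed fractions must be nonnegative")
  if (any(abs(rowSums(breed_fractions) - 1) > 1e-9))
    stop("breed fractions must sum to 1")
  sire <- as.character(rep_len(sire, n)); dam <- as.character(rep_len(dam, n))
  pos <- seq_len(n); names(pos) <- id
  ps <- pos[sire]; pd <- pos[dam]
  if (any(ps >= pos, na.rm = TRUE) || any(pd >= pos, na.rm = TRUE))
    stop("pedigree must be topologically ordered: parents before offspring")
  df <- data.frame(id = id, sire = sire, dam = dam,
                   flock = rep_len(flock, n),
                   birth_year = rep_len(birth_year, n),
                   sex = rep_len(sex, n), role = rep_len(role, n),
                   stringsAsFactors = FALSE)
  bf <- as.data.frame(breed_fractions)
  names(bf) <- paste0("bf_", colnames(breed_fractions))
  out <- cbind(df, bf)
  attr(out, "breeds") <- colnames(breed_fractions)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Extract the breed-proportion matrix from a pedigree
#'
#' @param ped a [pedigree()] table.
#' @param ids optional subset/order of individuals.
#' @return Numeric matrix, individuals x breeds.
#' @export
breed_fractions <- function(ped, ids = NULL) {
  breeds <- attr(ped, "breeds")
  Q <- as.matrix(ped[, paste0("bf_", breeds), drop = FALSE])
  colnames(Q) <- breeds
  rownames(Q) <- ped$id
  if (!is.null(ids)) {
    ri <- match(as.character(ids), ped$id)
    if (anyNA(ri)) stop("ids not in pedigree")
    Q <- Q[ri, , drop = FALSE]
  }
  Q
}

#' Variance components of the mixed model
#'
#' @param v_additive,v_maternal,v_breed,v_sireflock,v_residual variances
#'   (trait units squared), all nonnegative.
#' @return A `variance_components` object. The heritability is
#'   `v_additive / (v_additive + v_maternal + v_sireflock + v_residual)`:
#'   between-breed variance is not part of the within-population genetic
#'   variance and is excluded from the denominator.
#' @export
variance_components <- function(v_additive, v_maternal = 0, v_breed = 0,
                                v_sireflock = 0, v_residual) {
  v <- c(v_additive = v_additive, v_maternal = v_maternal, v_breed = v_breed,
         v_sireflock = v_sireflock, v_residual = v_residual)
  if (any(v < 0)) stop("variance components must be nonnegative")
  denom <- v_additive + v_maternal + v_sireflock + v_residual
  structure(list(v_additive = v_additive, v_maternal = v_maternal,
                 v_breed = v_breed, v_sireflock = v_sireflock,
                 v_residual = v_residual,
                 h2 = if (denom > 0) v_additive / denom else NA_real_,
                 se_h2 = NA_real_),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components:\n")
  v <- unlist(x[c("v_additive", "v_maternal", "v_breed", "v_sireflock",
                  "v_residual")])
  print(signif(v, 4))
  cat(sprintf("h2 = %.3f", x$h2))
  if (!is.na(x$se_h2)) cat(sprintf(" (SE %.3f)", x$se_h2))
  cat("\n")
  invisible(x)
}
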