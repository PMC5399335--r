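#' Relationship matrix container
#'
#' @param values dense symmetric matrix with dimnames.
#' @param ids individual ids (row/column order of `values`).
#' @param source `"markers"` or `"pedigree"`.
#' @param panel_label free label (e.g. `"dense"`, `"moderate"`).
#' @param freq_source description of the allele-frequency base.
#' @return A `relmat` object.
#' @export
relmat <- function(values, ids, source = c("markers", "pedigree"),
                   panel_label = "", freq_source = "") {
  source <- match.arg(source)
  values <- as.matrix(values)
  ids <- as.character(ids)
  stopifnot(nrow(values) == length(ids), ncol(values) == length(ids))
  if (max(abs(values - t(values))) > 1e-10)
    stop("relationship matrix must be symmetric")
  if (source == "pedigree" && any(diag(values) < 1 - 1e-10))
    stop("pedigree relationship diagonal must be at least 1")
  if (source == "markers" && any(diag(values) < 0))
    stop("marker relationship diagonal must be nonnegative")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, source = source,
                 panel_label = panel_label, freq_source = freq_source),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  d <- scale_diagnostics(x)
  cat(sprintf("relmat (%s%s): %d x %d, mean diagonal %.3f, mean off-diagonal %.4f\n",
              x$source,
              if (nzchar(x$panel_label)) paste0(", ", x$panel_label) else "",
              length(x$ids), length(x$ids), d$mean_diagonal,
              d$mean_offdiagonal))
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 * sum(p_j (1 - p_j)))` where row entries of `M` are
#' `2 - 2p_j`, `1 - 2p_j` and `-2p_j` for dosages 2, 1 and 0 of the counted
#' allele, and `p_j` is the frequency of the counted allele. Missing calls
#' are imputed to the per-SNP mean dosage (which contributes zero after
#' centering). Monomorphic SNPs contribute to neither numerator nor
#' denominator.
#'
#' @param geno a [genotype_matrix()] that has passed quality control.
#' @param freq_ids optional ids defining the allele-frequency base
#'   (default: all supplied individuals).
#' @param panel_label passed to [relmat()].
#' @return A [relmat()] with `source = "markers"`.
#' @export
compute_grm <- function(geno, freq_ids = NULL, panel_label = "") {
  Z <- geno$calls
  storage.mode(Z) <- "double"
  fi <- if (is.null(freq_ids)) seq_len(nrow(Z)) else match(freq_ids, geno$ids)
  if (anyNA(fi)) stop("freq_ids not found in genotypes")
  p <- colMeans(Z[fi, , drop = FALSE], na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) == 0)
    stop("all SNPs are monomorphic: VanRaden denominator is zero")
  Z <- Z[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(Z, 2, 2 * p)
  M[is.na(M)] <- 0            # mean-dosage imputation after centering
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  relmat(G, geno$ids, source = "markers", panel_label = panel_label,
         freq_source = if (is.null(freq_ids)) "all supplied individuals"
         else "user-specified subset")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' `A_ii = 1 + 0.5 A(sire, dam)`; `A_ij = 0.5 (A(j, sire(i)) + A(j, dam(i)))`
#' for `j` earlier in the pedigree; unknown parents contribute zero.
#'
#' @param ped a [pedigree()] (topologically ordered; enforced by the
#'   constructor, and re-checked here).
#' @return A [relmat()] with `source = "pedigree"`.
#' @export
compute_nrm <- function(ped) {
  id <- ped$id
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- pos[ped$sire]; di <- pos[ped$dam]   # NA for unknown
  if (any(si >= pos, na.rm = TRUE) || any(di >= pos, na.rm = TRUE))
    stop("pedigree contains a cycle or is not topologically ordered")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  relmat(A, id, source = "pedigree")
}

#' Mean diagonal and off-diagonal of a relationship matrix
#'
#' The scale check used to compare pedigree and genomic relationship
#' matrices: comparable matrices should have similar average diagonal
#' (about 1) and average off-diagonal (about 0) elements.
#'
#' @param rel a [relmat()] (or plain symmetric matrix), n >= 2.
#' @return List with `mean_diagonal` and `mean_offdiagonal`.
#' @export
scale_diagnostics <- function(rel) {
  V <- if (inherits(rel, "relmat")) rel$values else as.matrix(rel)
  n <- nrow(V)
  if (n < 2) stop("need at least 2 individuals")
  md <- mean(diag(V))
  mo <- (sum(V) - sum(diag(V))) / (n * (n - 1))
  list(mean_diagonal = md, mean_offdiagonal = mo)
}

#' Classify candidates by genomic relatedness to a reference set
#'
#' A candidate is `high` if the mean of its `k_top` largest relationships
#' to the reference is at least `high_threshold`; `low` if its largest
#' relationship to any reference individual is at most `low_threshold`;
#' otherwise `neither`. Ties at the `k_top` boundary are resolved by
#' including all tied values.
#'
#' @param grm a [relmat()] covering reference and candidates.
#' @param reference,candidates disjoint id sets present in `grm`.
#' @param k_top number of largest relationships averaged (default 30).
#' @param high_threshold,low_threshold classification thresholds
#'   (defaults 0.20 and 0.10).
#' @return A `relatedness_groups` list with `high`, `low`, `neither`
#'   (character id vectors partitioning the candidates), the parameters,
#'   and per-candidate statistics in `$stats`.
#' @export
classify_relatedness <- function(grm, reference, candidates, k_top = 30,
                                 high_threshold = 0.20, low_threshold = 0.10) {
  reference <- as.character(reference); candidates <- as.character(candidates)
  if (length(intersect(reference, candidates)))
    stop("reference and candidates must be disjoint")
  ri <- match(reference, grm$ids); ci <- match(candidates, grm$ids)
  if (anyNA(ri) || anyNA(ci)) stop("ids missing from the relationship matrix")
  if (length(reference) < k_top)
    warning("fewer reference individuals than k_top; using all of them")
  top_mean <- max_rel <- numeric(length(candidates))
  for (k in seq_along(ci)) {
    r <- grm$values[ci[k], ri]
    srt <- sort(r, decreasing = TRUE)
    kk <- min(k_top, length(srt))
    cut <- srt[kk]
    top <- srt[srt >= cut]            # include boundary ties
    top_mean[k] <- mean(top)
    max_rel[k] <- srt[1]
  }
  grp <- ifelse(top_mean >= high_threshold, "high",
                ifelse(max_rel <= low_threshold, "low", "neither"))
  structure(list(high = candidates[grp == "high"],
                 low = candidates[grp == "low"],
                 neither = candidates[grp == "neither"],
                 k_top = k_top, high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 stats = data.frame(id = candidates, top_mean = top_mean,
                                    max_rel = max_rel, group = grp,
                                    stringsAsFactors = FALSE)),
            class = "relatedness_groups")
}

#' @export
print.relatedness_groups <- function(x, ...) {
  cat(sprintf("relatedness groups (top-%d mean >= %.2f / max <= %.2f): high %d, low %d, neither %d\n",
              x$k_top, x$high_threshold, x$low_threshold,
              length(x$high), length(x$low), length(x$neither)))
  invisible(x)
}

#' Write a relationship matrix as long-format TSV
#'
#' One row per (i, j) pair with `i <= j`: columns `id1`, `id2`, `value`.
#'
#' @param rel a [relmat()].
#' @param path output file.
#' @export
write_relmat_tsv <- function(rel, path) {
  n <- length(rel$ids)
  ut <- which(upper.tri(rel$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = rel$ids[ut[, 1]], id2 = rel$ids[ut[, 2]],
                   value = rel$values[ut])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
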