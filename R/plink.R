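#' Write genotypes as PLINK BED/BIM/FAM
#'
#' SNP-major binary BED (magic bytes `6c 1b 01`), two bits per genotype:
#' `00` = two copies of the counted allele (dosage 2), `10` = heterozygote,
#' `11` = zero copies, `01` = missing. The counted allele is written as the
#' BIM A1 allele.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  n <- length(geno$ids); m <- length(geno$snp_ids)
  calls <- geno$calls
  # dosage -> 2-bit code
  code <- matrix(1L, n, m)          # missing
  code[!is.na(calls) & calls == 2L] <- 0L
  code[!is.na(calls) & calls == 1L] <- 2L
  code[!is.na(calls) & calls == 0L] <- 3L
  npad <- ceiling(n / 4) * 4
  if (npad > n) code <- rbind(code, matrix(3L, npad - n, m))
  mult <- c(1L, 4L, 16L, 64L)
  bytes <- vapply(seq_len(m), function(j) {
    as.integer(colSums(matrix(code[, j], nrow = 4) * mult))
  }, integer(npad / 4))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  bim <- data.frame(chr = geno$chrom, id = geno$snp_ids, cm = 0,
                    bp = geno$pos,
                    a1 = geno$counted_allele,
                    a2 = ifelse(geno$counted_allele == "A", "B", "A"))
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = geno$ids, iid = geno$ids, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK BED/BIM/FAM genotypes
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triple.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                    stringsAsFactors = FALSE)
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK BED file")
  body <- as.integer(raw[-(1:3)])
  bpl <- ceiling(n / 4)
  # decode 2-bit fields
  q <- matrix(body, nrow = bpl)
  decode <- function(shift) (q %/% shift) %% 4L
  calls <- matrix(NA_integer_, n, m)
  lookup <- c(2L, NA_integer_, 1L, 0L)   # code 0,1,2,3 -> dosage
  for (k in 1:4) {
    rows <- seq.int(k, by = 4, length.out = bpl)
    rows <- rows[rows <= n]
    codes <- decode(c(1L, 4L, 16L, 64L)[k])[seq_along(rows), , drop = FALSE]
    calls[rows, ] <- lookup[codes + 1L]
  }
  genotype_matrix(calls, ids = fam[[2]], snp_ids = bim$id,
                  chrom = bim$chr, pos = bim$bp, counted_allele = bim$a1)
}

#' Write the artifacts of a simulated population to disk
#'
#' PLINK files for the dense and moderate panels, plus TSV tables for the
#' phenotypes, the pedigree (with breed-fraction columns) and the true
#' breeding values.
#'
#' @param sim a [simulate_population()] result.
#' @param design a [simulate_phenotypes()] result (or `NULL` to skip).
#' @param dir output directory (created if needed).
#' @param seed seed for the moderate-panel thinning jitter.
#' @return Named character vector of the files written.
#' @export
write_sim_data <- function(sim, design = NULL, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cf <- sim$config
  excl <- if (cf$qtl_observed) NULL else sim$truth$qtl_ids
  dense <- subset_density(sim$geno, 1, seed = seed, exclude = excl)
  moder <- subset_density(sim$geno, cf$density_ratio, seed = seed,
                          exclude = excl)
  files <- c(dense = write_plink(dense, file.path(dir, "dense")),
             moderate = write_plink(moder, file.path(dir, "moderate")))
  ped_path <- file.path(dir, "pedigree.tsv")
  write.table(as.data.frame(sim$ped), ped_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["pedigree"] <- ped_path
  truth_path <- file.path(dir, "truth.tsv")
  write.table(data.frame(id = names(sim$truth$tbv), tbv = sim$truth$tbv),
              truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- truth_path
  if (!is.null(design)) {
    ph_path <- file.path(dir, "phenotypes.tsv")
    write.table(design$table, ph_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files["phenotypes"] <- ph_path
  }
  files
}
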