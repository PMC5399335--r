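#' Configuration for the synthetic multi-breed population
#'
#' Defines the study conditions for the gene-dropping simulator: breeds
#' diverge from a shared ancestral pool by drift over
#' `divergence_generations` discrete generations (effective size `ne`,
#' random mating, Haldane recombination on `n_chr` one-Morgan chromosomes),
#' founders are drawn from the drifted pools, a crossbreeding design
#' produces the phenotyped reference animals, and two groups of validation
#' sires are bred: sires of reference animals (high relatedness) and a line
#' separated from the reference parents by `validation_depth` generations
#' (low relatedness).
#'
#' @param n_breeds number of breeds.
#' @param breed_labels breed names (length `n_breeds`).
#' @param divergence_generations drift generations separating the breeds.
#' @param n_founders_per_breed founders drawn per breed.
#' @param n_reference total phenotyped reference animals (used when
#'   `cross_design` is `NULL`).
#' @param n_validation_sires_per_breed validation sires per breed, split
#'   roughly half/half between the high- and low-relatedness groups.
#' @param cross_design data frame with columns `sire_breed`, `dam_breed`,
#'   `n_offspring`; `NULL` gives a default design emulating a terminal/
#'   maternal/Merino sire mix over Merino dams (or a purebred design for a
#'   single breed).
#' @param n_snps_dense markers on the dense panel (QTL are a subset).
#' @param density_ratio fraction of the dense panel kept on the moderate
#'   panel (default 0.095, the 50k : 600k panel-size ratio).
#' @param n_qtl number of QTL.
#' @param qtl_effect_distribution `"gaussian"`, `"few_large"` or
#'   `"mixture"`.
#' @param h2_target narrow-sense heritability of the simulated trait.
#' @param var_maternal,var_breed,var_sireflock variance fractions of the
#'   phenotypic variance for the maternal, breed and sire-by-flock terms.
#' @param n_flocks number of flocks (sites).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param ne drift population size per breed.
#' @param n_chr number of one-Morgan chromosomes.
#' @param validation_depth generations separating the low-relatedness sire
#'   line from the founders.
#' @param qtl_observed if `FALSE` (default) QTL are meant to be excluded
#'   from the genotyping panels (see [subset_density()]), so prediction must
#'   work through linkage disequilibrium.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_breeds = 4,
                       breed_labels = c("Merino", "BL", "PD", "WS")[seq_len(n_breeds)],
                       divergence_generations = 50,
                       n_founders_per_breed = 100,
                       n_reference = 2000,
                       n_validation_sires_per_breed = 30,
                       cross_design = NULL,
                       n_snps_dense = 4000,
                       density_ratio = 0.095,
                       n_qtl = 200,
                       qtl_effect_distribution = c("gaussian", "few_large", "mixture"),
                       h2_target = 0.3,
                       var_maternal = 0.05,
                       var_breed = 0.05,
                       var_sireflock = 0.05,
                       n_flocks = 8,
                       seed = 1,
                       ne = 100,
                       n_chr = 5,
                       validation_depth = 3,
                       qtl_observed = FALSE) {
  qtl_effect_distribution <- match.arg(qtl_effect_distribution)
  stopifnot(length(breed_labels) == n_breeds)
  counts <- c(n_breeds, divergence_generations, n_founders_per_breed,
              n_validation_sires_per_breed, n_snps_dense, n_qtl, n_flocks,
              ne, n_chr, validation_depth)
  if (any(counts < 1)) stop("all counts must be positive")
  if (density_ratio <= 0 || density_ratio > 1)
    stop("density_ratio must be in (0, 1]")
  if (h2_target <= 0 || h2_target >= 1) stop("h2_target must be in (0, 1)")
  if (min(var_maternal, var_breed, var_sireflock) < 0)
    stop("variance fractions must be nonnegative")
  if (h2_target + var_maternal + var_breed + var_sireflock >= 1)
    stop("variance fractions must leave positive residual variance")
  if (n_qtl > n_snps_dense) stop("n_qtl cannot exceed n_snps_dense")
  if (is.null(cross_design)) {
    cross_design <- if (n_breeds == 1) {
      data.frame(sire_breed = breed_labels, dam_breed = breed_labels,
                 n_offspring = n_reference, stringsAsFactors = FALSE)
    } else {
      # sire mix over first-breed dams: ~40% breed 1, 20% breed 2, 40% split
      # over the remaining (terminal-type) breeds
      w <- c(0.4, 0.2, rep(0.4 / (n_breeds - 2), n_breeds - 2))[seq_len(n_breeds)]
      w <- w / sum(w)
      data.frame(sire_breed = breed_labels,
                 dam_breed = breed_labels[1],
                 n_offspring = round(n_reference * w),
                 stringsAsFactors = FALSE)
    }
  }
  cross_design <- as.data.frame(cross_design, stringsAsFactors = FALSE)
  if (nrow(cross_design) == 0 && n_breeds > 1)
    stop("cross_design must be non-empty for a multi-breed reference")
  if (!all(c(cross_design$sire_breed, cross_design$dam_breed) %in% breed_labels))
    stop("cross_design breeds must be drawn from breed_labels")
  if (any(cross_design$n_offspring < 1)) stop("cross offspring counts must be positive")
  structure(list(n_breeds = n_breeds, breed_labels = breed_labels,
                 divergence_generations = divergence_generations,
                 n_founders_per_breed = n_founders_per_breed,
                 n_reference = sum(cross_design$n_offspring),
                 n_validation_sires_per_breed = n_validation_sires_per_breed,
                 cross_design = cross_design,
                 n_snps_dense = n_snps_dense, density_ratio = density_ratio,
                 n_qtl = n_qtl,
                 qtl_effect_distribution = qtl_effect_distribution,
                 h2_target = h2_target, var_maternal = var_maternal,
                 var_breed = var_breed, var_sireflock = var_sireflock,
                 n_flocks = n_flocks, seed = as.integer(seed), ne = ne,
                 n_chr = n_chr, validation_depth = validation_depth,
                 qtl_observed = qtl_observed),
            class = "sim_config")
}

# sample from a vector of indices (safe for length-1 pools)
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# sample dams distinct from sires, vectorized rejection
sample_mates <- function(n_pool, n, exclude) {
  d <- sample.int(n_pool, n, replace = TRUE)
  bad <- which(d == exclude)
  while (length(bad)) {
    d[bad] <- sample.int(n_pool, length(bad), replace = TRUE)
    bad <- bad[d[bad] == exclude[bad]]
  }
  d
}

#' Simulate a multi-breed, crossbred sheep-type population
#'
#' Gene-drops haplotypes from a shared ancestral pool through breed-specific
#' drift, draws founders, breeds validation sires and the crossbred
#' reference per the configured design, and assigns QTL effects under the
#' configured architecture. The additive effects are scaled so that the
#' variance of the true breeding values among founders equals
#' `h2_target` (phenotypic variance is 1 by construction).
#'
#' @param config a [sim_config()].
#' @return A `sim_population` list with elements `geno`
#'   ([genotype_matrix()] for all individuals at all dense-panel loci,
#'   QTL included), `ped` ([pedigree()]), `truth` (QTL ids/effects, true
#'   breeding values, realized variance components) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  m <- cf$n_snps_dense
  nb <- cf$n_breeds
  breeds <- cf$breed_labels

  # marker map: contiguous chromosome blocks, 1 Morgan each
  sizes <- diff(round(seq(0, m, length.out = cf$n_chr + 1)))
  chr <- rep(seq_len(cf$n_chr), sizes)
  morgan <- unlist(lapply(sizes, function(k) sort(runif(k))))
  bp <- as.integer(round(morgan * 1e8))
  # enforce strictly increasing bp within chromosome
  for (c_ in seq_len(cf$n_chr)) {
    i <- which(chr == c_)
    bp[i] <- as.integer(cummax(bp[i] + seq_along(i) - 1L))
  }
  snp_ids <- sprintf("SNP%06d", seq_len(m))
  anc <- runif(m, 0.1, 0.9)

  # breed-specific drift from the shared ancestral pool
  pools <- vector("list", nb)
  for (b in seq_len(nb)) {
    H <- matrix(rbinom(2L * cf$ne * m, 1L, rep(anc, each = 2L * cf$ne)),
                nrow = 2L * cf$ne)
    for (g in seq_len(cf$divergence_generations)) {
      s <- sample.int(cf$ne, cf$ne, replace = TRUE)
      d <- sample_mates(cf$ne, cf$ne, s)
      H <- drop_gametes_cpp(H, as.integer(rbind(s, d)) - 1L, morgan, chr)
    }
    pools[[b]] <- H
  }

  nf <- cf$n_founders_per_breed
  nv <- cf$n_validation_sires_per_breed
  n_high <- ceiling(nv / 2)
  n_low <- nv - n_high
  n_lowline <- max(2L * n_low, 4L)
  depth <- cf$validation_depth
  cross <- cf$cross_design
  N <- nb * nf + nb * n_high + nb * depth * n_lowline + sum(cross$n_offspring)

  Hall <- matrix(0L, nrow = 2L * N, ncol = m)
  id <- character(N); sire <- rep(NA_character_, N); dam <- rep(NA_character_, N)
  sex <- character(N); role <- character(N)
  flock <- rep(NA_character_, N); byear <- rep(NA_character_, N)
  bf <- matrix(0, N, nb, dimnames = list(NULL, breeds))
  cur <- 0L
  row_of <- function(k) c(2L * k - 1L, 2L * k)

  add_from_pool <- function(pool, n, prefix, breed_idx, rl) {
    s <- sample.int(nrow(pool) / 2L, n, replace = TRUE)
    d <- sample_mates(nrow(pool) / 2L, n, s)
    G <- drop_gametes_cpp(pool, as.integer(rbind(s, d)) - 1L, morgan, chr)
    idx <- cur + seq_len(n)
    Hall[2L * idx - 1L, ] <<- G[2L * seq_len(n) - 1L, , drop = FALSE]
    Hall[2L * idx, ] <<- G[2L * seq_len(n), , drop = FALSE]
    id[idx] <<- sprintf("%s_%s%04d", breeds[breed_idx], prefix, seq_len(n))
    sex[idx] <<- rep(c("M", "F"), length.out = n)
    role[idx] <<- rl
    bf[idx, breed_idx] <<- 1
    cur <<- cur + n
    idx
  }
  add_offspring <- function(sires_k, dams_k, prefix, rl, flk = NA, by = NA,
                            sx = NULL) {
    n <- length(sires_k)
    par <- as.integer(rbind(sires_k, dams_k)) - 1L
    G <- drop_gametes_cpp(Hall[seq_len(2L * cur), , drop = FALSE], par, morgan, chr)
    idx <- cur + seq_len(n)
    Hall[2L * idx - 1L, ] <<- G[2L * seq_len(n) - 1L, , drop = FALSE]
    Hall[2L * idx, ] <<- G[2L * seq_len(n), , drop = FALSE]
    id[idx] <<- sprintf("%s%05d", prefix, seq_len(n))
    sire[idx] <<- id[sires_k]; dam[idx] <<- id[dams_k]
    sex[idx] <<- if (is.null(sx)) sample(c("M", "F"), n, replace = TRUE) else
      rep_len(sx, n)
    role[idx] <<- rl
    flock[idx] <<- rep_len(flk, n); byear[idx] <<- rep_len(by, n)
    bf[idx, ] <<- (bf[sires_k, , drop = FALSE] + bf[dams_k, , drop = FALSE]) / 2
    cur <<- cur + n
    idx
  }

  founders <- vector("list", nb)
  for (b in seq_len(nb))
    founders[[b]] <- add_from_pool(pools[[b]], nf, "F", b, "founder")

  # high-relatedness validation sires: offspring of founder pairs, later
  # used as sires of the reference animals
  high_sires <- vector("list", nb)
  for (b in seq_len(nb)) {
    fm <- founders[[b]][sex[founders[[b]]] == "M"]
    ff <- founders[[b]][sex[founders[[b]]] == "F"]
    s <- resample(fm, n_high, replace = TRUE)
    d <- ff[sample_mates(length(ff), n_high, rep(0L, n_high))]
    high_sires[[b]] <- add_offspring(s, d, paste0(breeds[b], "_VH"),
                                     "validation_high", sx = "M")
  }

  # low-relatedness line: bred forward from a reserved founder subset
  low_sires <- vector("list", nb)
  for (b in seq_len(nb)) {
    reserve <- founders[[b]][seq.int(nf - ceiling(nf / 3) + 1L, nf)]
    prev <- reserve
    for (g in seq_len(depth)) {
      pm <- prev[sex[prev] == "M"]; pf <- prev[sex[prev] == "F"]
      s <- resample(pm, n_lowline, replace = TRUE)
      d <- resample(pf, n_lowline, replace = TRUE)
      rl <- if (g == depth) "validation_low" else "intermediate"
      prev <- add_offspring(s, d, sprintf("%s_L%d_", breeds[b], g), rl,
                            sx = c("M", "F"))
    }
    males <- prev[sex[prev] == "M"]
    low_sires[[b]] <- males[seq_len(min(n_low, length(males)))]
    role[setdiff(prev, low_sires[[b]])] <- "intermediate"
  }

  # reference animals per the crossbreeding design
  for (r in seq_len(nrow(cross))) {
    sb <- match(cross$sire_breed[r], breeds)
    db <- match(cross$dam_breed[r], breeds)
    n <- cross$n_offspring[r]
    s <- resample(high_sires[[sb]], n, replace = TRUE)
    ff <- founders[[db]][sex[founders[[db]]] == "F"]
    dpool <- resample(ff, min(length(ff), max(2L, ceiling(n / 3))))
    d <- resample(dpool, n, replace = TRUE)
    add_offspring(s, d, sprintf("REF%d_", r), "reference",
                  flk = sample(paste0("FL", seq_len(cf$n_flocks)), n, replace = TRUE),
                  by = sample(c("2009", "2010"), n, replace = TRUE))
  }
  stopifnot(cur == N)

  calls <- Hall[2L * seq_len(N) - 1L, , drop = FALSE] +
    Hall[2L * seq_len(N), , drop = FALSE]
  geno <- genotype_matrix(calls, id, snp_ids, chr, bp, morgan = morgan)
  ped <- pedigree(id, sire, dam, bf, flock = flock, birth_year = byear,
                  sex = sex, role = role)

  # QTL effects under the configured architecture
  qtl_idx <- sort(sample.int(m, cf$n_qtl))
  p_f <- colMeans(calls[role == "founder", qtl_idx, drop = FALSE]) / 2
  a <- switch(cf$qtl_effect_distribution,
    gaussian = rnorm(cf$n_qtl),
    few_large = {
      a0 <- rnorm(cf$n_qtl)
      nl <- max(1L, round(0.01 * cf$n_qtl))
      big <- sample.int(cf$n_qtl, nl)
      w <- 2 * p_f * (1 - p_f) * a0^2
      s_small <- sum(w[-big]); s_big <- sum(w[big])
      if (s_big > 0) a0[big] <- a0[big] * sqrt(max(s_small, 1e-12) / s_big)
      a0
    },
    mixture = {
      comp <- sample.int(3, cf$n_qtl, replace = TRUE, prob = c(0.7, 0.2, 0.1))
      rnorm(cf$n_qtl, sd = sqrt(c(1e-4, 1e-3, 1e-2))[comp])
    })
  tbv <- drop((calls[, qtl_idx, drop = FALSE] -
                 matrix(2 * p_f, N, cf$n_qtl, byrow = TRUE)) %*% a)
  v_f <- var(tbv[role == "founder"])
  if (v_f <= 0) stop("degenerate QTL draw: no additive variance among founders")
  scl <- sqrt(cf$h2_target / v_f)
  a <- a * scl
  tbv <- tbv * scl
  names(tbv) <- id
  truth <- structure(list(qtl_ids = snp_ids[qtl_idx],
                          qtl_effects = setNames(a, snp_ids[qtl_idx]),
                          qtl_freq = setNames(p_f, snp_ids[qtl_idx]),
                          tbv = tbv,
                          realized_var_components =
                            list(v_additive_founders = cf$h2_target)),
                     class = "true_genetic_values")
  structure(list(geno = geno, ped = ped, truth = truth, config = cf),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$ped$role)
  cat(sprintf("sim_population: %d individuals, %d SNPs, %d breeds\n",
              nrow(x$geno$calls), ncol(x$geno$calls), x$config$n_breeds))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Thin a dense marker panel to a lower density
#'
#' Keeps `round(density_ratio * m)` markers, evenly spaced along the map
#' (by chromosome and position) with a seeded jitter, emulating a
#' moderate-density array nested inside a high-density one.
#'
#' @param geno a [genotype_matrix()] (columns sorted by chromosome and
#'   position, as produced by [simulate_population()]).
#' @param density_ratio fraction in (0, 1].
#' @param seed integer seed for the jitter.
#' @param exclude SNP ids to drop before thinning (e.g. `truth$qtl_ids`
#'   when QTL are unobserved by the genotyping assays).
#' @return A [genotype_matrix()] with the retained columns, sorted by
#'   (chromosome, position).
#' @export
subset_density <- function(geno, density_ratio, seed = 1, exclude = NULL) {
  if (density_ratio <= 0 || density_ratio > 1)
    stop("density_ratio must be in (0, 1]")
  keep <- geno$snp_ids
  if (!is.null(exclude)) keep <- setdiff(keep, exclude)
  idx <- match(keep, geno$snp_ids)
  idx <- idx[order(geno$chrom[idx], geno$pos[idx])]
  if (density_ratio == 1 && is.null(exclude)) return(geno)
  k <- round(density_ratio * length(idx))
  k <- max(1L, min(k, length(idx)))
  if (k < length(idx)) {
    set.seed(as.integer(seed))
    grid <- seq(1, length(idx), length.out = k)
    step <- if (k > 1) grid[2] - grid[1] else 0
    grid <- grid + runif(k, -0.45, 0.45) * step
    sel <- unique(pmin(pmax(round(grid), 1L), length(idx)))
    while (length(sel) < k) {  # fill collisions from unused positions
      sel <- sort(c(sel, setdiff(seq_along(idx), sel)[seq_len(k - length(sel))]))
    }
    idx <- idx[sort(sel)]
  }
  subset_geno(geno, snps = geno$snp_ids[idx])
}
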