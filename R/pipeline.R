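#' Experiment configuration
#'
#' Bundles the simulation, QC and BayesR settings with the panel and
#' reference-set choices for an end-to-end run.
#'
#' @param simulation a [sim_config()].
#' @param qc a [qc_thresholds()].
#' @param panels subset of `c("moderate", "dense")`.
#' @param methods subset of `c("GBLUP", "BayesR")`.
#' @param reference_definition `"all"`, `"purebred:<breed>"`,
#'   `"crossbred:<sire>x<dam>"`, or `"combined:<def>+<def>"`.
#' @param bayesr optional list of [bayesr_priors()] arguments other than
#'   `sigma_g2` (which is taken from the GREML fit at run time).
#' @param output_dir directory for artifacts, reports and the stage cache.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(simulation = sim_config(),
                              qc = qc_thresholds(),
                              panels = c("moderate", "dense"),
                              methods = "GBLUP",
                              reference_definition = "all",
                              bayesr = list(n_iter = 5000, burn_in = 1000),
                              output_dir = tempfile("ovinepred_")) {
  panels <- match.arg(panels, c("moderate", "dense"), several.ok = TRUE)
  methods <- match.arg(methods, c("GBLUP", "BayesR"), several.ok = TRUE)
  structure(list(simulation = simulation, qc = qc, panels = panels,
                 methods = methods,
                 reference_definition = reference_definition,
                 bayesr = bayesr, output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML document
#'
#' Top-level keys `simulation`, `qc`, `bayesr` hold the arguments of
#' [sim_config()], [qc_thresholds()] and [bayesr_priors()]; `panels`,
#' `methods`, `reference_definition` and `output_dir` are passed through.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  doc <- yaml::read_yaml(path)
  sim <- do.call(sim_config, doc$simulation %||% list())
  if (!is.null(doc$simulation$cross_design))
    sim$cross_design <- do.call(rbind.data.frame, doc$simulation$cross_design)
  experiment_config(simulation = sim,
                    qc = do.call(qc_thresholds, doc$qc %||% list()),
                    panels = doc$panels %||% c("moderate", "dense"),
                    methods = doc$methods %||% "GBLUP",
                    reference_definition = doc$reference_definition %||% "all",
                    bayesr = doc$bayesr %||% list(n_iter = 5000, burn_in = 1000),
                    output_dir = doc$output_dir %||% tempfile("ovinepred_"))
}

# resolve a reference-definition string to reference ids
resolve_reference <- function(def, ped) {
  ref <- ped[ped$role == "reference", , drop = FALSE]
  Q <- breed_fractions(ped, ref$id)
  pick_one <- function(d) {
    if (d == "all") return(ref$id)
    parts <- strsplit(d, ":", fixed = TRUE)[[1]]
    kind <- parts[1]
    if (kind == "purebred") {
      b <- parts[2]
      if (!b %in% colnames(Q)) stop("unknown breed in reference definition: ", b)
      ref$id[Q[, b] >= 1 - 1e-9]
    } else if (kind == "crossbred") {
      br <- strsplit(parts[2], "x", fixed = TRUE)[[1]]
      if (!all(br %in% colnames(Q))) stop("unknown breed in cross definition")
      ref$id[rowSums(abs(Q[, br, drop = FALSE] - 0.5)) < 1e-9 &
               rowSums(Q[, br, drop = FALSE]) >= 1 - 1e-9]
    } else stop("unknown reference definition: ", d)
  }
  if (startsWith(def, "combined:")) {
    defs <- strsplit(sub("^combined:", "", def), "+", fixed = TRUE)[[1]]
    unique(unlist(lapply(defs, pick_one)))
  } else pick_one(def)
}

# content-addressed stage cache: recompute only when the input key changes
stage <- function(name, key, dir, compute, say) {
  cache <- file.path(dir, "cache", paste0(name, "_", object_md5(key), ".rds"))
  if (file.exists(cache)) {
    say(sprintf("stage %s: cached (%s)", name, basename(cache)))
    return(readRDS(cache))
  }
  say(sprintf("stage %s: computing", name))
  out <- tryCatch(compute(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(out, cache, version = 2)
  out
}

#' Run an end-to-end genomic-prediction experiment
#'
#' Simulate, apply QC, build genomic relationship matrices per panel,
#' estimate variance components by REML, predict validation-sire breeding
#' values by GBLUP (and optionally BayesR), and evaluate accuracy per
#' breed and relatedness stratum against simulated progeny-test EBVs.
#' Every stage result is cached under `output_dir/cache` keyed by the md5
#' of its inputs, so re-running with an unchanged upstream stage skips the
#' recomputation; report tables are written as TSV with an md5 manifest.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return An `experiment_report` list: variance components, accuracy and
#'   comparison tables, file paths, and the per-panel prediction objects.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- if (quiet) function(...) invisible() else function(msg) message(msg)
  cf <- config$simulation

  sim <- stage("simulate", cf, config$output_dir,
               function() simulate_population(cf), say)
  design <- stage("phenotypes", list(cf, "pheno"), config$output_dir,
                  function() simulate_phenotypes(sim$geno, sim$ped, sim$truth,
                                                 cf, seed = cf$seed + 1L), say)
  ref_ids <- resolve_reference(config$reference_definition, sim$ped)
  design_ref <- if (length(ref_ids) < design$n) {
    tab <- design$table[design$table$id %in% ref_ids, , drop = FALSE]
    d <- build_design(tab, sim$ped, trait = "trait")
    d$realized_var_components <- design$realized_var_components
    d
  } else design

  val <- sim$ped[sim$ped$role %in% c("validation_high", "validation_low"), ]
  ebv <- stage("progeny_ebv", list(cf, "ebv"), config$output_dir, function() {
    set.seed(cf$seed + 2L)
    # progeny-group sizes spanning the realistic sire-accuracy range
    np <- round(exp(runif(nrow(val), log(20), log(1000))))
    simulate_progeny_ebv(sim$truth, val$id, np, h2 = cf$h2_target,
                         seed = cf$seed + 2L)
  }, say)
  breeds <- attr(sim$ped, "breeds")
  Qv <- breed_fractions(sim$ped, val$id)
  breed_of <- setNames(breeds[max.col(Qv)], val$id)

  excl <- if (cf$qtl_observed) NULL else sim$truth$qtl_ids
  keep_ids <- unique(c(ref_ids, val$id))
  ratios <- c(moderate = cf$density_ratio, dense = 1)
  vc_tab <- list(); acc_tab <- list(); preds <- list(); grms <- list()
  scale_tab <- list()

  for (panel in config$panels) {
    geno_p <- stage(paste0("panel_", panel), list(cf, panel),
                    config$output_dir, function() {
      g <- subset_density(sim$geno, ratios[[panel]], seed = cf$seed,
                          exclude = excl)
      subset_geno(g, ids = keep_ids)
    }, say)
    qcres <- stage(paste0("qc_", panel), list(cf, panel, config$qc),
                   config$output_dir, function() apply_qc(geno_p, config$qc),
                   say)
    grm <- stage(paste0("grm_", panel), list(cf, panel, config$qc),
                 config$output_dir,
                 function() compute_grm(qcres$geno, panel_label = panel), say)
    grms[[panel]] <- grm
    sdg <- scale_diagnostics(grm)
    scale_tab[[panel]] <- data.frame(panel = panel,
                                     mean_diagonal = sdg$mean_diagonal,
                                     mean_offdiagonal = sdg$mean_offdiagonal)
    fit <- stage(paste0("reml_", panel),
                 list(cf, panel, config$qc, config$reference_definition),
                 config$output_dir,
                 function() fit_reml(design_ref, grm), say)
    vc_tab[[panel]] <- data.frame(panel = panel,
                                  v_additive = fit$components$v_additive,
                                  v_maternal = fit$components$v_maternal,
                                  v_breed = fit$components$v_breed,
                                  v_sireflock = fit$components$v_sireflock,
                                  v_residual = fit$components$v_residual,
                                  h2 = fit$components$h2,
                                  se_h2 = fit$components$se_h2,
                                  converged = fit$converged)
    if ("GBLUP" %in% config$methods) {
      tag <- paste0("GBLUP-", panel)
      pr <- stage(paste0("gblup_", panel),
                  list(cf, panel, config$qc, config$reference_definition),
                  config$output_dir, function()
                    solve_mme(design_ref, grm, fit$components,
                              predict_ids = intersect(val$id, grm$ids),
                              method = tag), say)
      preds[[tag]] <- pr
    }
    if ("BayesR" %in% config$methods) {
      tag <- paste0("BayesR-", panel)
      pr <- stage(paste0("bayesr_", panel),
                  list(cf, panel, config$qc, config$reference_definition,
                       config$bayesr), config$output_dir, function() {
        pri <- do.call(bayesr_priors,
                       c(list(sigma_g2 = fit$components$v_additive),
                         config$bayesr))
        run_bayesr(design_ref, qcres$geno, pri)
      }, say)
      preds[[tag]] <- pr
    }
  }

  rel_groups <- if ("dense" %in% names(grms)) {
    classify_relatedness(grms[["dense"]],
                         reference = intersect(ref_ids, grms[["dense"]]$ids),
                         candidates = intersect(val$id, grms[["dense"]]$ids))
  } else {
    classify_relatedness(grms[[1]],
                         reference = intersect(ref_ids, grms[[1]]$ids),
                         candidates = intersect(val$id, grms[[1]]$ids))
  }

  for (tag in names(preds))
    acc_tab[[tag]] <- cbind(method = tag,
                            accuracy(preds[[tag]], ebv, groups = breed_of))
  comparison <- if (length(preds) >= 2) {
    design_groups <- setNames(sub("validation_", "", val$role), val$id)
    stratified_comparison(preds, ebv, strata = design_groups,
                          n_boot = 500, seed = cf$seed + 3L)
  } else NULL

  report_dir <- file.path(config$output_dir, "report")
  dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, nm) {
    p <- file.path(report_dir, nm)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(wt(do.call(rbind, vc_tab), "variance_components.tsv"),
             wt(do.call(rbind, acc_tab), "accuracy_by_breed.tsv"),
             wt(do.call(rbind, scale_tab), "scale_diagnostics.tsv"))
  if (!is.null(comparison)) {
    files <- c(files, wt(comparison$accuracy, "accuracy_by_stratum.tsv"))
    if (!is.null(comparison$differences))
      files <- c(files, wt(comparison$differences, "panel_differences.tsv"))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  wt(manifest, "manifest.tsv")

  structure(list(variance_components = do.call(rbind, vc_tab),
                 accuracy = do.call(rbind, acc_tab),
                 scale_diagnostics = do.call(rbind, scale_tab),
                 comparison = comparison,
                 relatedness = rel_groups,
                 predictions = preds,
                 files = files,
                 output_dir = config$output_dir),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment report\n")
  cat("variance components:\n"); print(x$variance_components, row.names = FALSE)
  cat("accuracy by breed:\n"); print(x$accuracy, row.names = FALSE)
  invisible(x)
}
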