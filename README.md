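# ovinepred

Genomic prediction of breeding values in multi-breed, crossbred livestock
populations — the sheep-industry setting in which a large crossbred
reference population trains a predictor and purebred industry sires with
accurate progeny-test EBVs serve as the validation set. The package
implements the complete analysis stack and a synthetic population
generator, so every stage is testable end to end with known truth:

* **Simulation** — gene-dropping of haplotypes through breed-specific
  drift (configurable FST), crossbreeding designs, QTL architectures from
  infinitesimal to major-gene, phenotypes under the full mixed model, and
  progeny-test EBVs for validation sires at realistic accuracies
  (0.70–0.99); marker panels at two densities (default ratio 0.095,
  matching a 50k panel nested in a 600k one).
* **Quality control** — the standard SNP array filters (call rate 0.90,
  quality score 0.6, heterozygosity 3 SD, MAF 0.01, HWE 1e-15, sex
  chromosomes) with first-rule attribution, and duplicate-sample removal
  at genotype correlation ≥ 0.98.
* **Relationships** — VanRaden genomic relationship matrix
  `G = MM' / 2Σp(1−p)` and the pedigree numerator matrix A (tabular
  method), with scale diagnostics and relatedness stratification of
  validation animals (top-30 mean ≥ 0.20 = high; max ≤ 0.10 = low).
* **Estimation** — AI-REML variance components for
  `y = Xb + Z1a + Ww + Z1Qq + Z2s + e` (additive, maternal,
  breed-proportion and sire-by-flock terms), GBLUP through the mixed-model
  equations for genotyped-but-unphenotyped animals, and a four-component
  BayesR Gibbs sampler (SNP effect variances `(0, 1e-4, 1e-3, 1e-2)·σg²`,
  Dirichlet prior on the mixture proportions; compiled sampler,
  seed-reproducible chains).
* **Validation** — per-group Pearson accuracy of GBV against progeny-test
  EBV with `se = sqrt((1−r²)/(n−2))`, dispersion-bias regression,
  optional strain adjustment, and panel comparisons per relatedness
  stratum with paired-bootstrap intervals.

See the methods vignette
(`vignettes/genomic-prediction-methods.Rmd`) for the models, priors,
numerical choices and the design decisions behind the simulator.

## Worked example

Simulate a two-breed population, predict validation sires from a dense
panel, and measure their accuracy against progeny-test EBVs:

```r
library(ovinepred)

cf <- sim_config(n_breeds = 2, breed_labels = c("Merino", "PD"),
                 n_founders_per_breed = 80, n_reference = 500,
                 n_validation_sires_per_breed = 20, n_snps_dense = 2000,
                 density_ratio = 0.1, n_qtl = 100, seed = 42)
sim <- simulate_population(cf)
design <- simulate_phenotypes(sim$geno, sim$ped, sim$truth, cf, seed = 43)

val <- sim$ped$id[grepl("validation", sim$ped$role)]
geno <- subset_geno(subset_density(sim$geno, 1, exclude = sim$truth$qtl_ids),
                    ids = c(design$ids, val))
G <- compute_grm(geno, panel_label = "dense")
G
#> relmat (markers, dense): 540 x 540, mean diagonal 0.989, mean off-diagonal -0.0018

fit <- fit_reml(design, G)
summary(fit)
#>   component     estimate         se
#>  v_additive 2.353837e-01 0.07303193
#>  v_maternal 7.545778e-02 0.03804765
#>     v_breed 2.540582e-08 0.23192281
#> v_sireflock 3.315717e-07 0.02680583
#>  v_residual 5.014569e-01 0.04932551
#> h2 = 0.290 (SE 0.077), logLik = -202.975

pred <- solve_mme(design, G, fit$components, predict_ids = val,
                  method = "GBLUP-dense")
ebv <- simulate_progeny_ebv(sim$truth, val, n_progeny = 300,
                            h2 = cf$h2_target, seed = 44)
accuracy(pred, ebv)
#>   group_label  n         r        se regression_coef flag
#> 1         all 40 0.3655501 0.1509943       0.5535966   ok
```

The REML fit recovers the simulated heritability of 0.3 (estimate 0.29,
SE 0.08); the maternal fraction (simulated at 0.05) is estimated at 0.075,
and the breed and sire-by-flock components shrink to the boundary in this
small example. The validation accuracy of 0.37 (SE 0.15) across 40 sires —
half of them deliberately bred three generations away from the reference —
and a dispersion regression below 1 are typical for a reference set of
only 500 records. `run_experiment()` wraps this whole flow (two panels,
stratified comparison, cached stages, TSV reports) behind a single
configuration object.

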