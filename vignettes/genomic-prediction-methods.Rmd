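---
title: "Genomic prediction in a multi-breed sheep population: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in a multi-breed sheep population: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sheep breeding programs in Australia and elsewhere evaluate selection
candidates from genome-wide SNP genotypes: a reference population with both
phenotypes and genotypes trains a predictor, and the genomic breeding values
(GBV) of young, unphenotyped animals are validated against highly accurate
progeny-test EBVs of industry sires. Two questions dominate the design of
such evaluations: how much accuracy a high-density panel (hundreds of
thousands of SNPs) adds over a moderate one (tens of thousands), and for
whom — the benefit is expected to concentrate in animals distantly related
to the reference, where prediction must work through population-level
linkage disequilibrium (LD) rather than close-family co-segregation.

`ovinepred` implements the full analysis stack for this question — data
simulation, quality control, relationship matrices, variance components,
GBLUP, BayesR and stratified validation — so that every stage can be tested
end to end on synthetic data whose truth is known.

## The mixed model

All estimation is built around one linear mixed model for a trait record
$y$:

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Z}_1\mathbf{a} + \mathbf{Ww}
  + \mathbf{Z}_1\mathbf{Qq} + \mathbf{Z}_2\mathbf{s} + \mathbf{e}$$

with fixed effects $\mathbf{b}$ (birth type, rearing type, gender, age at
measurement and a contemporary group defined as site x birth year x
management group), additive genetic effects
$\mathbf{a} \sim N(0, \mathbf{K}\sigma^2_a)$ where $\mathbf{K}$ is either
the pedigree numerator relationship matrix $\mathbf{A}$ or a genomic
relationship matrix $\mathbf{G}$, maternal effects $\mathbf{w}$, breed
effects $\mathbf{q}$ entering through the breed-proportion matrix
$\mathbf{Q}$ (rows sum to one; fractions come from the pedigree), and
sire-by-flock interaction effects $\mathbf{s}$. Breed effects are treated
as random, matching the model as written; many programs treat breed as
fixed, but the random formulation keeps the model estimable when breed
proportions are nearly confounded with other terms.

Heritability is reported as
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_w + \sigma^2_s + \sigma^2_e)$.
The between-breed variance is deliberately excluded from the denominator:
it is variation between breed means, not within-population genetic
variance, and including it would deflate $h^2$ for multi-breed data in a
way that single-breed analyses never see.

## Genomic relationships

`compute_grm()` builds the VanRaden matrix
$\mathbf{G} = \mathbf{MM}'/\,2\textstyle\sum_j p_j(1-p_j)$, where row
entries of $\mathbf{M}$ are $2-2p_j$, $1-2p_j$ and $-2p_j$ for dosages 2,
1 and 0 of the counted allele and $p_j$ is its observed frequency.
Choices worth knowing:

* Frequencies default to the supplied individuals (reference plus
  validation); a `freq_ids` argument restricts them to a subset. The
  source is recorded on the object.
* Missing calls are imputed to the per-SNP mean dosage, which is exactly
  zero after centering — it preserves $p_j$ and adds no spurious
  relationship. (Industrial pipelines would impute with a dedicated tool
  first; mean-fill is the documented fallback here.)
* Monomorphic SNPs contribute to neither numerator nor denominator.
* Because the columns of $\mathbf{M}$ sum to zero under observed
  frequencies, every row and column of $\mathbf{G}$ sums to zero:
  $\mathbf{G}$ is singular by construction, and its mean off-diagonal is
  $-\bar{g}_{ii}/(n-1)$. On an unstructured equilibrium population the
  mean diagonal is 1 and the mean off-diagonal 0 to two decimals — the
  standard scale check for comparing $\mathbf{A}$- and
  $\mathbf{G}$-based variance components.

`compute_nrm()` implements the tabular method for $\mathbf{A}$
($A_{ii} = 1 + \tfrac12 A_{sd}$, unknown parents contribute zero); it is
cross-checked in the test suite against a 100,000-replicate gene-dropping
identity-by-descent estimator.

Because $\mathbf{G}$ is singular, `solve_mme()` computes BLUP through the
phenotypic covariance
$\mathbf{V} = \sigma^2_a\mathbf{K}_{obs} + \sum_t \sigma^2_t
\mathbf{Z}_t\mathbf{Z}_t' + \sigma^2_e\mathbf{I}$: fixed effects by
generalized least squares and every animal's breeding value as
$\hat{a} = \sigma^2_a\,\mathbf{k}_i'\mathbf{V}^{-1}
(\mathbf{y}-\mathbf{X}\hat{b})$. This is algebraically identical to
Henderson's equations where those exist, needs no inversion of
$\mathbf{G}$, and makes the GBLUP/SNP-BLUP equivalence exact to machine
precision (asserted at 1e-6 in the tests). A consistency diagnostic
evaluates the Henderson system premultiplied by $\mathbf{G}$ — a form that
is defined for singular $\mathbf{G}$ — and its maximum residual is
reported on every fit.

## Variance components

`fit_reml()` maximizes the restricted likelihood by average-information
(AI) updates with an expectation–maximization-style multiplicative
fallback whenever an AI step would leave the parameter space, plus step
halving if a step fails to increase the likelihood. Numerical choices:
components are floored at $10^{-8}$ of the total variance; convergence is
declared at a relative log-likelihood change below $10^{-8}$ or a
projected gradient norm below $10^{-6}$ (components at the floor with
outward-pointing gradients are projected out); the iteration cap is 200.
Starting values put half the phenotypic variance on the residual and split
the rest equally among the modeled random terms. Standard errors come from
the inverse AI matrix, and the $h^2$ standard error from the delta method.
The likelihood, gradient and AI matrix are evaluated on the observation
scale (dense $n \times n$ Cholesky); at the problem sizes this package
targets (up to a few thousand records) this is faster and simpler than a
mixed-model-equations formulation, and the tests pin the optimum against
an independent 41 x 41 grid search of the restricted likelihood.

## BayesR

`run_bayesr()` is a single-site Gibbs sampler for the same model with the
additive term replaced by SNP regressions: each SNP effect comes from a
four-component Gaussian mixture with variances $(0, 10^{-4}, 10^{-3},
10^{-2})\,\sigma^2_g$, where $\sigma^2_g$ is the assumed total genetic
variance taken from the GREML fit. Mixture proportions get a
Dirichlet(1,1,1,1) prior; class-term and residual variances are
scaled-inverse-chi-square ($\nu = 4$, weakly informative scales); the
default chain is 50,000 iterations with 10,000 burn-in, thinned by 10
(module tests and the pipeline default use shorter chains sized to their
problem). Genotypes are centered by $2p_j$ — the same coding as the
relationship matrix, which is what makes the degenerate-prior cross-check
meaningful: with $\pi$ fixed to the fourth component and $\sigma^2_4$ set
to the SNP-BLUP per-marker variance, the posterior-mean GBV must reproduce
GBLUP (correlation at least 0.99 in the acceptance suite).

Implementation notes: SNP update order is re-randomized every iteration
(seeded) to avoid order artifacts; membership is sampled from the
effect-integrated likelihood; residuals are updated incrementally and
recomputed from scratch at chain end — the maximum discrepancy is reported
(`residual_drift`, asserted below $10^{-6}$). $\sigma^2_g$ is held fixed
by default; a flag (`update_sigma_g`) re-samples it from its full
conditional, since published descriptions are ambiguous on whether the
GREML value is a constant or a starting value. Chains are reproducible:
identical seeds give identical output. Posterior summaries are means over
the thinned post-burn-in samples; effective sample sizes of the residual
variance and of the nonzero-SNP count are reported as chain diagnostics.

## The synthetic population

`simulate_population()` stands in for industry data that cannot be
shipped. Haplotypes are gene-dropped: each breed drifts from a shared
ancestral pool (allele frequencies uniform on 0.1–0.9) through
`divergence_generations` discrete generations of random mating at
effective size `ne`, with recombination on `n_chr` one-Morgan chromosomes
under a Haldane map. This reproduces the two features of real data the
methods depend on — within-breed LD of extent $\approx 1/(1 + 4N_e c)$ and
between-breed allele-frequency divergence growing with separation time
(mean FST $\approx 1 - e^{-g/2N_e}$, verified against a Hudson estimator
in the tests).

The default configuration emulates the study conditions the package
targets: four breeds (Merino, Border Leicester, Poll Dorset, White
Suffolk) with a sire mix of roughly 40% Merino, 20% maternal and 40%
terminal over Merino dams; two panels at a 0.095 density ratio (the 50k :
600k panel-size ratio); heritabilities configurable over the 0.13–0.88
range seen across weight, carcass and wool traits; maternal, breed and
sire-by-flock variance fractions of 5% each by default; eight flocks; and
validation-sire EBV accuracies spanning 0.70–0.99 (progeny groups of
20–1000 under the half-sib reliability formula
$r^2 = 0.25\,n h^2 / (1 + 0.25(n-1)h^2)$). Desk-scale marker counts
(thousands of SNPs, hundreds to thousands of animals) keep every stage
runnable in seconds to minutes; they are stated in each test and are a
deliberate scaling-down of panel sizes, not a change of structure.

Validation sires come in two designed groups: sires of the reference
animals (high relatedness) and a line bred `validation_depth` generations
(default 3) from a reserved founder subset never used for the reference
(low relatedness). QTL are a random subset of dense-panel loci and are by
default removed from both genotyping panels, so prediction must work
through LD — the package's premise; `qtl_observed = TRUE` keeps them,
emulating a dense panel that captures causal variants directly. Effect
architectures: `gaussian` (many small effects), `few_large` (about 1% of
QTL rescaled to carry half the additive variance — a major-gene trait) and
`mixture`. Effects are rescaled once so the variance of true breeding
values among founders equals the target additive variance; phenotype
simulation anchors the other variance fractions on the realized additive
variance among the phenotyped animals, so the configured $h^2$ holds for
the records actually analyzed. Fixed-effect sizes default to at most 0.5
phenotypic SD; breed means are drawn with SD $\sqrt{\text{var\_breed}}$.
Neither is an inference about any real dataset — real fixed-effect and
breed-mean magnitudes are unknown here, and the defaults are placeholders
chosen once.

What the generator does **not** emulate: genotyping error beyond an
optional per-call quality channel, selection across generations, realistic
ovine map positions, sequence-level variation, and imputation error.
Passing tests therefore demonstrate the correctness and the qualitative
behaviour of the estimators, not field performance on industry data.

## Quality control

`filter_snps()` applies, in a fixed documented order: chromosome exclusion
(X/Y) → call rate < 0.90 → mean per-genotype quality score < 0.6 (skipped
when no quality channel exists, as in simulated data) → observed
heterozygosity more than 3 SD from the panel mean → MAF < 0.01 →
Hardy-Weinberg $p < 10^{-15}$ (1-df chi-square, switching to the exact
conditional test when any expected genotype count is below 5). Each
removed SNP is attributed to the *first* rule it violates. The
heterozygosity rule uses observed (not expected) heterozygosity, computed
against the SNPs that survived the preceding rules; with a single extreme
outlier in a very small panel the rule's own mean and SD absorb the
outlier, which is why the planted-violation test panel carries a realistic
MAF spread. `filter_duplicate_samples()` removes the later-listed member
of any pair correlating at $r \ge 0.98$ over jointly non-missing calls
(transitive groups keep their first member); pairs sharing fewer than 100
SNPs are skipped with a logged warning. Sample call-rate filtering is
deliberately not implemented. Re-running QC on its own output is a no-op
on realistic panels (asserted in the tests); the heterozygosity rule is
the one rule for which idempotence is empirical rather than structural,
since its bounds are recomputed on the survivors.

## Validation

`accuracy()` reports, per group, the Pearson correlation between GBV and
progeny-test EBV, the standard error $\sqrt{(1-r^2)/(n-2)}$, and the OLS
slope of EBV on GBV (1 = no dispersion bias). An optional strain
adjustment removes group means from both variables before correlating —
implemented as fixed-effect residualization, the plainest reading of
"a strain effect was fitted" — so between-strain spread cannot inflate
within-breed accuracy. `classify_relatedness()` labels candidates *high*
when the mean of their `k_top = 30` largest genomic relationships to the
reference reaches 0.20, *low* when no relationship exceeds 0.10 (ties at
the k-th value are all included; if both rules could fire, high wins).
`stratified_comparison()` adds per-stratum panel differences with a paired
bootstrap (ids resampled jointly across panels; 1000 resamples by
default) — the bootstrap interval is this package's addition, since point
differences alone say nothing about their stability.

## The pipeline

`run_experiment()` chains simulate → phenotypes → progeny EBVs → per-panel
QC → GRM → REML → GBLUP (and optionally BayesR) → per-breed and
per-stratum validation, writing TSV report tables with an md5 manifest.
Stage results are cached under `output_dir/cache`, keyed by the md5 of the
serialized stage inputs, so re-running with an unchanged upstream stage
skips recomputation; reruns of an identical configuration are
byte-identical. Reference sets can be restricted with
`"purebred:<breed>"`, `"crossbred:<sire>x<dam>"` or `combined:` unions of
those, mirroring within- and across-breed prediction designs. The package
is a library: configuration files (YAML via `read_experiment_config()`)
plus these functions are the interface, and no shell executable is
installed.

## Known limitations

Single records per animal; homogeneous residual variance; no single-step
(H-matrix) machinery — every animal in these analyses is genotyped; no
multi-trait models; no blending of G with A (beyond the documented
diagnostics, matrices are used as constructed); dense linear algebra
throughout, appropriate up to a few thousand animals and not intended for
industrial scale.
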