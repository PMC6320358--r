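---
title: "Genomic, pedigree and reflectance-based yield prediction in stressed wheat trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic, pedigree and reflectance-based yield prediction in stressed wheat trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Elite wheat yield-trial nurseries evaluate on the order of a thousand
F6:F7 lines per year under managed drought and heat stress. Yield-testing
every line in every environment is expensive, so breeders want to predict
the grain yield (GY) of lines that were only genotyped, only pedigreed, or
only overflown with a reflectance camera. `stressgp` implements the full
analysis chain for that question: plot-model adjustment, relationship
matrices, univariate and multivariate kernel mixed models, an item-based
collaborative-filtering (IBCF) recommender driven by the green normalized
difference vegetation index (GNDVI), family-aware cross-validation
designs, and a breeding-population simulator that makes every stage
testable without any external data.

## From plots to line values

Field data arrive as plot records from an alpha-lattice layout: trials of
28 entries plus 2 checks, three replicates, six incomplete blocks per
replicate. `fit_plot_model()` fits, by REML (via lme4),

$$y_{ijkl} = \mu + g_i + t_j + r_{k(j)} + b_{l(jk)} + \varepsilon_{ijkl}$$

with genotype fixed and trial, replicate-within-trial and
block-within-replicate random; the genotype estimates are the line BLUEs
that every downstream model consumes. With genotype random instead, the
genetic and residual variance components give the line-mean heritability
on the square-root scale,

$$H = \sqrt{\sigma_g^2 / (\sigma_g^2 + \sigma_\varepsilon^2/\mathrm{nreps})},$$

which is the form in which heritabilities are reported for these trials
(so an "H of 0.75" is a line-mean repeatability of about 0.56). Grouping
factors with fewer than two levels are dropped, so a degenerate
single-trial dataset collapses to per-line means.

Before modelling, `huber_outlier_filter()` applies the robust rule used
for quality control of such trials: values more than `k_spreads`
(default 4) robust spreads from a robust center are set missing. The
center and spread are the joint Huber "Proposal 2" M-estimates with
tuning constant 1.345 (via `MASS::hubers`); any consistent robust pair
would do, and the zero-spread case (all values identical) deliberately
flags nothing. GNDVI itself is
$(R_{780} - R_{550})/(R_{780} + R_{550})$ from near-infrared and green
reflectance; `screen_dates()` drops measurement dates whose heritability
falls below `min_H` (default 0.5 — the cutoff is not standardized
anywhere, so it is exposed as a parameter) and labels survivors with
growth stages so that items can be matched across years by stage rather
than by calendar date.

## Relationship matrices

`vanraden_g()` builds the genomic relationship matrix (VanRaden method 1)
from dosages centered at twice the observed allele frequencies of the
analyzed set, $G = ZZ'/(2\sum_m p_m(1-p_m))$, after the standard marker
QC (`filter_markers()`: > 50% missing, < 5% minor-allele frequency,
> 5% heterozygosity; `filter_lines()`: > 50% missing;
`impute_mean()` for the remainder — a k-NN imputer would add little
because the centering absorbs the imputed means). A `jitter` of 1e-6 on
the diagonal keeps G safely positive definite for the solvers. For fully
inbred material the diagonal sits near 2, i.e. $1 + F$.

`pedigree_a()` builds the numerator relationship matrix by the recursive
tabular method from recorded parents only. Since the pedigree file
carries parents and cross but not per-line inbreeding, the F6:F7 selfing
is *not* reflected in A; A is the expected-relationship kernel at the
recorded depth, which is exactly its role in the comparisons below.

## Prediction engines

`reml_univariate()` fits $y_i = \mu + u_i + \varepsilon_i$ with
$\mathbf u \sim N(0, K\sigma_g^2)$ by restricted maximum likelihood,
profiling everything down to $\lambda = \sigma_g^2/\sigma_e^2$ through
the spectral decomposition of K and searching $\log\lambda \in [-10, 10]$
(tolerance 1e-8). The point-estimate-plus-BLUP rule $E[u \mid y]$ is the
deterministic counterpart of the Bayesian GBLUP samplers often used for
this model; with K = I and fixed $\lambda$ it reduces to ridge regression
toward the mean, which the tests exploit as an exact oracle.
`reml_two_kernel()` handles the combined G + A model by profiling a
mixing weight $\alpha$ over a 0.02-step grid with the 1-D search nested
inside — more robust at these problem sizes than a joint
two-component Newton scheme, and exactly equivalent at the grid optimum.

`reml_multivariate()` fits the t-trait model with genetic covariance
$V_G \otimes K$ and residual covariance $V_E \otimes I$ by an
expectation–maximization REML in the eigenbasis of K. Each iteration
additionally diagonalizes $(V_G, V_E)$ jointly, so the E- and M-steps are
elementwise over an n × t array and the restricted likelihood is monotone
by construction; convergence is declared at $|\Delta\ell| < 10^{-6}$
(capped at 1000 iterations, with a warning and the last iterate
returned), and both covariance matrices are clipped to the PSD cone at
1e-10 after every update. Genetic correlations are read off $V_G$.
Because the eigen-rotation that makes the EM fast requires complete
rows, (V_G, V_E) are estimated on the lines with complete traits;
`predict_trait_assisted()` then predicts the missing target (GY) for
validation lines as the *exact* joint-Gaussian conditional expectation
given every observed cell — relationships and the correlated GNDVI
records — at those estimates. In this workflow missingness is
whole-trait by design (validation lines lack GY), so the complete-case
restriction loses nothing material; lines without any secondary trait
still get a relationship-only prediction and are flagged.

`predict_ibcf()` implements the recommender rule
$P_{ij'} = \sum_j y_{ij} w_{jj'} / \sum_j |w_{jj'}|$ with cosine
similarities between items learned on the training set. Ratings are
z-scored per item — the rule averages items with incompatible units
(t/ha against unitless GNDVI), so some scaling convention is forced; the
per-item z-score is ours and is stored so predictions can be
back-transformed with the *training* target's mean and sd. Validation
GNDVI items are standardized by the validation set's own statistics,
weights may be negative (drought trials show negative GY–GNDVI
correlations), the absolute-value denominator is kept exactly as the
rule states, and all items serve as neighbors (item counts here are at
most about six; a top-k cut is available but pointless at that size).

## Cross-validation designs

`kfold_partition()` (5-fold by default), `one_progeny_subset()` (one
random line per cross — a population with no full sibs),
`fullsib_split()` (families with at least `min_family_size = 3` sibs,
split within family; the odd member alternates so the overall balance
holds), `dthd_subset()` (heading-date windows, either mean ± 1 sd or an
explicit closed interval), and `across_nursery_plan()` (all ordered
train→validation year pairs plus each year predicted from all others).
Published descriptions of the full-sib design conflict between a 50/50
sentence and 80/20-looking population counts; the package default is the
50/50 split with `train_fraction` configurable, and the acceptance
script uses 0.8 where it reproduces the printed numbers. Accuracy is
always the plain Pearson correlation between observed BLUEs and
predictions (`pearson_accuracy()`), never divided by the square root of
heritability; "±" summaries are the sd across folds
(`aggregate_grid()`).

## What the simulator emulates — and what it does not

`simulate_population()` builds the study system from the genome up:

* **Founders and families.** An older pool of `n_grandfounders = 30`
  inbred lines is crossed and selfed into `n_founders = 60` parent
  lines; each nursery then draws `n_families` crosses with 1–6 progeny
  each, gamete-dropped with Poisson(1) crossovers per one-Morgan
  chromosome and selfed `n_selfing_generations = 5` times (F6-like;
  residual heterozygosity halves per generation). Crucially, the
  delivered pedigree records the parent lines as unrelated founders, so
  the relatedness the older pool creates is visible to markers but not
  to A — the situation every real elite panel is in, and the mechanism
  that lets genomic prediction beat pedigree prediction across years.
* **Trait architecture.** Marker effects are standard normal, linearly
  rescaled so the realized breeding values hit `V_G` exactly. Effects
  are correlated `rg_across = 0.75` between nurseries: successive years
  share most but not all of the architecture (genotype-by-year), which
  caps across-year accuracy below the within-year level; the value was
  calibrated once so the simulated across-to-within accuracy ratio
  matches the reported averages (about 0.4). `within_family_selection =
  0.5` shrinks within-family genetic deviations toward the family mean,
  emulating the earlier-stage selection that leaves full sibs of
  selected-bulk material clustered tightly — without it, pedigree
  information would be strictly redundant with markers. `prop_scored =
  0.6` of the genome is delivered as the genotype panel while all
  markers remain causal, so G is a realistically noisy estimate of
  realized relatedness, as genotyping-by-sequencing panels are.
* **Field layout and noise.** Lines are randomized into 28-entry trials
  plus two shared checks, 3 replicates × 6 blocks; trial, replicate and
  block effects are drawn per trait as fractions (0.5 / 0.25 / 0.25) of
  that trait's residual variance, and plot residuals are multivariate
  normal over traits with `V_E`. Default heritabilities (square-root
  scale): GY 0.75, GNDVI 0.9, DTHD 0.95, height 0.9; default genetic
  correlations: GY–GNDVI 0.7 (the heat-stress regime), GNDVI–GNDVI 0.9;
  residual correlations of 0.3 couple repeated GNDVI dates and GNDVI
  with yield on the same plot, since observed phenotypic correlations
  attenuate less than the heritability product alone would allow.

Not emulated: spatial field trend beyond the block structure, dominance
and epistasis, explicit weather, selection *during* the simulated trials,
genotyping error, and drought-regime sign flips (a negative GY–GNDVI
correlation is obtained simply by setting the corresponding `V_G` entry
negative). Passing tests on this generator therefore demonstrate that
the estimators recover what they claim under the stated stochastic
model — not that any particular field dataset satisfies that model.

```{r}
library(stressgp)
cfg <- sim_config(n_nurseries = 2, n_families = 96, n_markers = 1200,
                  n_chromosomes = 21, seed = 11)
pop <- simulate_population(cfg)
nur <- pop$nurseries$EYT1
blues <- blues_matrix(filter_plot_outliers(nur$plot_table))
G <- vanraden_g(impute_mean(filter_markers(nur$genotypes)))
A <- pedigree_a(nur$pedigree)[nur$line_ids, nur$line_ids]
part <- kfold_partition(nur$line_ids, 5, seed = 1)
cv_kernel_models(setNames(blues[nur$line_ids, "GY"], nur$line_ids),
                 list(G = G, A = A), part)
```

## Numerical choices and problem sizes

Tolerances: 1e-8 for the univariate profile search, 1e-6 for both REML
engines' convergence, 1e-10 PSD clipping, 1e-6 kernel jitter. Variance
components are initialized at half the phenotypic (co)variance; all
optimizers are deterministic, so seeds only enter data generation and
fold assignment. Degenerate inputs are first-class: zero robust spread
keeps all values, constant matrices refuse rescaling, all-missing
markers refuse imputation, monomorphic panels refuse G, pedigree cycles
are detected, and zero-norm vectors refuse a cosine.

The test suite and `scripts/acceptance.R` run everything on scaled-down
populations chosen as the package's own working sizes: oracle checks on
≤ 50-plot designs and ≤ 40-line pedigrees, parameter-recovery at one
nursery of ~1000 lines × 240 markers, model-contrast sign tests on ten
replicate two-nursery populations of ~340 lines × 1200 markers, and the
acceptance pipeline on two nurseries of ~575 lines × 1200 markers on 21
chromosomes. The full four-nursery, 9285-marker default configuration
runs in minutes rather than seconds and is the recommended setting for
method exploration.

## Known limitations

A is built from recorded parents only, so inbreeding from selfing is
absent from its diagonal; the EM estimates (V_G, V_E) from
complete-trait lines; the two-kernel fit resolves the mixing weight only
to the 0.02 grid; within-nursery accuracies from a single k-fold run
carry fold noise of a few hundredths, which is why the reporting layer
aggregates folds (and optional repeats) with an sd. Exact numerical
agreement with Bayesian-sampler implementations of the same models is
not expected — agreement is statistical, at the level of variance
components, correlations and accuracies.
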