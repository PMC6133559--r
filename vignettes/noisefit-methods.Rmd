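---
title: "Methods: from single-cell expression noise to population fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell expression noise to population fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisefit)
```

# The scientific problem

Genetically identical cells growing in the same environment do not express a
gene at identical levels: stochastic transcription and translation create
cell-to-cell variability known as *expression noise*. Whether this noise
itself — as opposed to the average expression level — affects organismal
fitness is hard to measure, because promoter mutations that change noise
almost always change the mean as well. `noisefit` implements the full
quantitative machinery for such a study in budding yeast: quantifying median
expression and noise from flow cytometry of a fluorescent promoter reporter,
measuring competitive fitness to a precision of roughly 0.1%, separating the
fitness effect of noise from that of the mean with local-regression
residuals, and an individual-based model that explains the observed pattern
from first principles.

The central empirical quantity is a pair of residuals. With a panel of
promoter genotypes spanning a range of median activities, a LOESS regression
of noise on median expression defines **ΔNoise** (noise variation
independent of the mean), and a LOESS regression of fitness on median
expression defines **ΔFitness**. The headline analysis asks whether ΔNoise
and ΔFitness are correlated, separately for genotypes whose mean expression
is *far from* versus *close to* the expression optimum — the level at which
predicted fitness is maximal. Elevated noise is expected to help far below
the optimum (more cells land near the optimum by chance) and to hurt near it
(more cells land away from it).

# Expression quantification from cytometry events

`filter_events()` removes events that cannot be log-transformed, events
outside configurable quantile bounds on log FSC.A, log FSC.H and log FL1,
and non-single-cell events. For the latter we use a density gate on
(log FSC.A, log FSC.H): a robust Gaussian density is fitted by a
deterministic iteratively-trimmed covariance (three refinement passes on the
best 95% of squared Mahalanobis distances, with the truncated-chi-square
consistency correction) and events outside the `qchisq(0.9999, 2)` contour
are dropped. We chose this over a kernel-density threshold deliberately: a
doublet population carrying a few percent of the events forms its own mode
whose height is proportional to its mass, so no fixed fraction-of-mode KDE
cutoff can remove it while retaining 99% of singlets, whereas the robust
contour removes it entirely (the doublets sit many scatter SDs off the
singlet cloud). The trimmed estimator is also free of random subsampling, so
gating is bit-reproducible. Model-based mixture gating (as in flowClust) is
intentionally out of scope.

`size_normalize()` separates expression from cell size. A PCA of the
(log FSC.A, log FL1) cloud defines eigenvectors intersecting at the
centroid; with ν the vector from the origin to the centroid, the cloud is
rotated about the centroid by the angle between the first eigenvector and ν,
and rotated FL1 is divided by rotated FSC.A. Two conventions are ours
because the geometric construction does not fix them: the first eigenvector
is the larger-eigenvalue direction sign-fixed to a positive dot product with
ν, and the rotation maps it onto ν. The output is exactly FL1/FSC on data
already aligned with the centroid ray, and collapses pure size variation by
orders of magnitude.

`fluor_to_mrna()` applies the log-log calibration `log10 y = a log10 x + b`
mapping size-normalised fluorescence to relative mRNA level; the default
constants `a = 10.469`, `b = -9.586` come from joint
pyrosequencing/cytometry calibration measurements on the instrument this
design targets, and should be refitted for any other instrument.
`summarize_sample()` then records, per sample of at least 1000 cells
(configurable), the median `m`, SD `s`, and four noise metrics — noise
strength `s²/m` (a Fano-factor analogue with a median denominator),
`s`, `cv = s/m` and `log10(cv)` — which are always recomputed from `(m, s)`
so they stay mutually consistent through later corrections.

Batch correction (`correct_batch()`) removes the dominant technical factor,
run-to-run drift of detector sensitivity, using control replicates of the
reference strain present on every plate. Because the correction must act on
a scale linear in fluorescence rather than mRNA, the models are fitted to
`u = log10(m)` and to `v = s/(m ln 10)` — the first-order (delta-method)
approximation of the SD of log10 expression, using `σ²(f(x)) ≈ σ² f'(x)²`
with `f = log` — with fixed effects for flow run and plate row; fitted
deviations (centred on the control mean) are subtracted from every sample
and `(m, s)` are back-transformed. Autofluorescence is then subtracted as
the mean `(m, s)` of a non-fluorescent strain. Replicates are screened by a
raw MAD filter (`mad_filter()`, no consistency constant): values further
than `k` MADs from the replicate median are dropped, with `k = 4` for
expression and `k = 5` for fitness; when the MAD is zero only values
strictly different from the median are dropped. Genotype summaries are
percentages of the reference-strain mean with Student-t 95% CIs, reported
when at least four replicates survive.

# Competitive fitness

Indirect assays compete each genotype (YFP-marked) against a common
GFP-marked reference and track genotype frequencies by two-colour cytometry.
`classify_two_color()` performs a PCA on the two log fluorescence channels
and splits the colour component — identified as the component correlating
most with the channel contrast, which is the second component when size
variation dominates — at the kernel-density minima between the three
largest modes: GFP (high score), YFP (low score) and mixed YFP–GFP doublets
(intermediate). Same-colour doublets are invisible, so `doublet_correct()`
reconstructs them from the mixed count under random pairing: the mixed
class relates to the hidden classes like the heterozygote of a
Hardy–Weinberg ratio, `DYG = 2√(DY·DG)`, and random pairing forces equal
doublet proportions, `DY/TY = DG/TG`. The unique solution
`DY = (DYG/2)√(TY/TG)`, `DG = (DYG/2)√(TG/TY)` gives cell numbers
`NY = TY + DY + DYG`, `NG = TG + DG + DYG`, conserving
`NY + NG = TY + TG + DY + DG + 2 DYG`.

Generations are counted from the density/dilution log
(`generations_from_densities()`: `g = log2(D_end · f / D_start)` per cycle,
plate-level value the median across wells) and competitive fitness is
`w = exp(slope)` of the OLS regression of `ln(NY/NG)` on cumulative
generations (`fitness_from_series()`). We fit an unweighted slope with a
free intercept, including the starting timepoint when counts exist there;
the source protocol does not state weights or an intercept constraint.
Per-genotype fitness is the replicate mean relative to the wild-type
reference strain after a 5-MAD screen, with a t-based CI
(`relative_fitness()`). Direct pairwise assays replace counts with
pyrosequencing allele frequencies: `direct_fitness()` regresses
`ln(fH/fL)` (with `fH + fL = 1`) on generations, excluding series whose
mean pyrogram peak height is below 5 (weak PCR). `doubling_time()` inverts
the slope of `log2(density)` on time during log phase.

# Pyrosequencing quantification

Allele frequencies come from pyrogram peak heights with the standard 0.86
multiplicative correction applied to A peaks (`freq_from_peaks()`); we
multiply the A-peak height by 0.86, the reading of "applied to A peaks"
consistent with the chemistry's A over-call (the alternative, division,
is the same correction in the opposite direction and is documented here so
a user with differently calibrated chemistry can pass `1/0.86`). Residual
locus-specific PCR bias is removed either by the fixed printed line
`y = x(0.5/0.45) − 0.111` (`linear_bias_correct()`, calibrated on a control
strain whose true frequency 0.5 reads as 0.55), with outputs clipped to
[0, 1] since the line leaves the unit interval at its ends, or by a
calibration map fitted to gDNA controls of known composition
(`spline_bias_correct()`). With four or more distinct truth levels the map
is an isotonic-projected cubic smoothing spline; with the usual three
levels (0, 0.5, 1) a free spline is under-determined between the widely
spaced clusters, so the map interpolates the per-level replicate means
monotonically — exact for an affine bias.

Relative expression of two alleles follows from their gDNA frequency `G`
and cDNA frequency `C` as `A = (1−G)C/((1−C)G)` (`expression_ratio()`, the
inverse of `C = AG/(AG + 1 − G)`), and promoter copy numbers follow from
the expected marked-allele frequencies `n/(n+1)`: 0.5, 2/3, 0.75 for one,
two, three marked copies against the native copy (`expected_copy_freq()`).
`infer_copies()` assigns the nearest expectation and flags strains whose
replicate frequencies significantly exceed the claimed copy number
(one-sided t-test), the screen used to exclude strains with unintended
extra integrations.

# The residual analysis

`loess_fit()` is a from-scratch local polynomial smoother: tricube weights
over the `floor(span·n)` nearest neighbours (ties broken by input order),
local quadratic by default, evaluated exactly at every point ("direct"
surface; for spans above 1 the bandwidth is the maximum distance inflated
by √span). A frozen oracle table generated once by an independent reference
smoother pins the implementation to 1e-6.

`delta_metrics()` excludes genotypes above 125% median expression (too few
high-expression genotypes for residuals to be meaningful there), fits the
two LOESS regressions at span 2/3, and attaches the optimum classification:
`optimum_split()` evaluates the fitness fit on a 2001-point grid over the
observed expression range, finds the maximal predicted fitness, and places
the threshold where the prediction on the low-expression side crosses the
maximum minus `fitness_drop` (default 0.005), interpolating linearly
between grid points. Genotypes below the threshold are "far" from the
optimum. Correlations between ΔNoise and ΔFitness are tested per class
with the t distribution (`pearson_test()`) and by permutation
(`permutation_cor_test()`).

`permutation_median_test()` compares a statistic (median by default; mean
or SD for single-cell doubling-time comparisons) between two groups by
random shuffling. The p-value counts shuffles whose absolute difference is
**at least** the observed one — the non-strict inequality, under which the
identity assignment always counts, the Monte-Carlo value converges to the
exhaustive enumeration (`exact = TRUE`), and the p-value is valid in the
standard permutation-test sense; a strict inequality would report p = 0 on
small instances with ties. When no random shuffle reaches the observed
difference the proportion is reported along with the `1/n_perm` upper
bound. `robustness_grid()` repeats the class-wise correlations over all
100 combinations of five noise spans, five fitness spans
(2/6, 3/6, 4/6, 5/6, 1) and four fitness drops (0.0025–0.01).

# The individual-based growth model

`simulate_population()` links the single-cell expression distribution to
population growth. Expression is normal with mean `μ_E ∈ [0, 2]` and a
noise value `ν_E ∈ [0, 3]` specified as SD, CV or Fano factor
(`sigma_from_noise()`); draws are truncated at zero by redrawing, since
negative expression is meaningless and breaks the linear doubling-time map.
Each draw sets the cell's doubling time through one of two regimes
(`dt_function()`): the linear map `DT = −40E + 160` (directional
selection) or the inverted Gaussian `DT = −160·exp(−(E−1)²/0.18) + 240`
(stabilising selection, fastest division of 80 min at `E = 1`). Doubling
times are clamped at a configurable 1-minute floor: under the linear map,
truncation still admits `E > 4`, and without a floor such cells would
divide in non-positive time. Populations exceeding a hard cap (default
5×10⁷ cells) raise an error rather than silently subsampling.

A run desynchronises first: founder cells drawn from the expression
distribution have their first doubling time scaled by a uniform random
value, the population grows for the full duration `T`, and the main run's
founders are then drawn from the end of this seed experiment, inheriting
their expression state and residual time to next division (a second
rescaling would discard the phase structure the seed run exists to
produce). During growth, any cell whose next division fits inside the
remaining time divides, and mother and daughter independently redraw
expression and doubling time — deliberately ignoring mother-daughter
inheritance of expression, a conservative choice for detecting
noise-mediated fitness effects. Fitness compares final counts against a
reference genotype (`μ = 1`, `σ = 0.1`, same DT regime unless overridden)
as `exp(ln(N_i/N_ref)/T)` (`competitive_fitness_sim()`); because the
exponent is per minute these values sit very close to 1, so
`fitness_per_generation()` rescales to the reference's 80-minute doubling
time as a convenience. `sweep_fitness()` runs replicate grids with paired
seeds (focal and reference replicate share a seed stream) and t-based 95%
CIs.

The model's two signature patterns are assertable at reduced scale (600
minutes, 200 founders, 30 paired replicates — the sizes used throughout the
test suite, which keep a full sweep under a few seconds while leaving the
contrasts far larger than the replicate CIs): under the Gaussian regime
noise raises fitness at `μ = 0.5` and lowers it at `μ = 1`, with high
noise flattening the fitness-versus-mean relationship; under the linear
regime noise never hurts.

# Assay power analysis

`simulate_assay()` models one serial-dilution competition assay:
deterministic enrichment of the focal genotype by `e^s` per generation,
binomial drift at each bottleneck, binomial counting at each of
`n_cycles + 1` assessments, and the same log-odds-slope estimator the
fitness module uses (empirical-logit continuity correction keeps lost
lineages estimable). The bottleneck follows from the design: cultures grow
to `final_pop` cells (default 2.5×10⁶, i.e. 5×10⁶ cells/ml in a 0.5 ml
well) and are diluted `2^g`-fold, so `bottleneck = final_pop/2^g`.
Binomial rather than hypergeometric sampling models the dilution, an
excellent approximation at these dilution ratios. `sd_selection()` repeats
the simulation (default 5000 times) to estimate the estimator's SD and
`min_detectable()` inverts the two-sample noncentral-t power function
(via `power.t.test`) for the minimum detectable selection difference at a
given replication, significance level and power.

A consequential design property reproduced here: with the number of
dilution cycles fixed (four, as in the real design), precision is
maximised at an *intermediate* number of generations per cycle, because
few generations shrink the regression baseline (counting noise dominates)
while many generations shrink the bottleneck as `2^g` (drift dominates).
Note the interior optimum arises when cycles are held fixed and the total
generation count varies with `g`; holding total generations fixed instead
couples the two knobs and pushes the optimum to the boundary. The full
factorial design grid is supported through `power_sweep()`; the bundled
demonstrations use a 5-point sweep at 2000 simulations per point.

# The synthetic-data generators

Every pipeline input can be generated with known ground truth
(`gen_flow_events()`, `gen_two_color_events()`,
`gen_competition_series()`, `gen_pyrogram()`, `gen_study_panel()`), so the
whole analysis chain is testable end to end without instrument data. All
generators are bit-reproducible from one global seed with per-dataset
sub-seeds (`derive_seed()`).

Design choices worth knowing:

* **Single-cell expression is log-normal**, parameterised to match the
  requested arithmetic mean and SD. The real single-cell distribution
  family is not established; log-normal provides positive support and
  realistic right skew, but recovery tests on these draws cannot validate
  behaviour under other distribution shapes.
* **Cytometry forward model**: per-event log fluorescence is the
  calibrated fluorescence-per-size value times log scatter, plus additive
  autofluorescence, so the size-normalisation inverts it exactly in the
  noise-free limit. Doublets form by random pairing (summed areas and
  fluorescence, near-saturated height), which both makes the gate's task
  realistic and guarantees the doublet-correction assumptions hold in
  expectation.
* **Study panel truth**: mean expression spans 0–125% of wild type with a
  deletion and a wild-type genotype always present; fitness follows a
  plateau `1 − 0.061(1−μ)^1.8` below the wild-type level (calibrated so a
  deletion costs 6.1% and a 14.6% expression drop costs 0.19%) with a mild
  quadratic overexpression cost; noise follows a declining trend in the
  mean plus independent genotype perturbations (SD 30% of wild type); and
  the planted effect adds `noise_effect` (default 1e-4 fitness per noise
  percentage point, the order of magnitude implied by a ±1.5% ΔFitness
  range over a ±150% ΔNoise range) times the perturbation, ramped to zero
  as the mean approaches the optimum region. Measurement error on the
  panel (1.5% expression, 5% noise, 0.001 fitness) reflects
  replicate-averaged assay precision, where the competition assays resolve
  about 0.2% at 95% confidence.
* The emulated data are idealised in ways real data are not: no
  compensation/spillover between channels, no plate-position gradients
  beyond the modelled run and row effects, no autocorrelated drift within
  a flow run, and no mother-daughter expression inheritance. Passing
  recovery tests therefore demonstrates correctness of the estimators
  under the stated model, not robustness to every instrument artifact.

# Numerical choices and degenerate inputs

* LOESS neighbourhoods break distance ties by input order; spans below
  `(degree+1)/n` are refused.
* `optimum_split()` uses a 2001-point grid (resolution ≈ 0.06% expression
  for a 0–125% panel); a fitness drop of zero puts the threshold at the
  argmax, and a curve that never drops classifies everything "close" with
  a warning.
* `mad_filter()` with zero MAD drops only strict deviations from the
  median, so constant replicate sets are never emptied.
* `doublet_correct()` refuses mixed doublets alongside an empty colour
  class (the random-pairing assumption cannot hold).
* Corrected allele frequencies are clipped to [0, 1].
* `doubling_time()` treats slopes below 1e-10 per minute as degenerate.
* Permutation p-values of 0 are accompanied by the `1/n_perm` bound.

# Limitations

The pipeline treats log-phase relative growth rate as the fitness proxy;
lag and stationary phases, frequency-dependent or non-transitive
competition are out of scope, as is re-analysis of deposited instrument
files (inputs are CSV event tables in this build). The growth model's
fitness values depend on the assumed DT functions; only the qualitative
contrasts between regimes, not absolute fitness magnitudes, should be
interpreted. ΔNoise and ΔFitness are regression residuals and therefore
depend on the genotype panel composition — the direct pairwise assay
support exists precisely to check conclusions without residuals.

# A worked example

```{r example, eval = FALSE}
library(noisefit)

# a synthetic 43-genotype study with a planted noise effect
sp <- gen_study_panel(43, noise_effect = 1e-4, seed = 11,
                      emit = character(0))
an <- analyze_noise_fitness(sp$panel,
                            analysis_config(n_permutations = 20000,
                                            seed = 11))
an
#> Noise-fitness analysis: 43 genotypes, optimum threshold 78.0%
#>   far from optimum (n=27): r = 0.779, p(t) = 1.69e-06, p(perm) = 0
#>   close from optimum (n=16): r = 0.206, p(t) = 0.444, p(perm) = 0.441
```

The far-from-optimum class shows the planted positive ΔNoise-ΔFitness
correlation; close to the optimum the correlation is within sampling noise
of zero.
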