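---
title: "How clocktol measures the tolerance of epigenetic clocks to calibration-age error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How clocktol measures the tolerance of epigenetic clocks to calibration-age error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

An epigenetic clock is a sparse linear model that predicts chronological
age from DNA methylation beta values at selected CpG sites. Building one
requires a calibration cohort of known-age individuals — and for most wild
species, "known" ages are estimates with error of their own. `clocktol`
implements a simulation experiment that answers a practical question: how
wrong can calibration ages be before the clock's predictions become
detectably worse?

The design: fix a cohort, split it once into 70% calibration / 30%
hold-out, fit a baseline clock on the exact calibration ages, then sweep an
error level x from low to high. At each level, calibration ages are
independently perturbed by up to ±x% (uniformly within the bound), the
clock is refit from scratch, and its per-sample errors on the *unperturbed*
hold-out set are compared with the baseline's. Three instruments detect
excess error: an unpaired t-test on absolute errors, one on relative
errors, and Cohen's d on absolute errors, summarised by a linear model of d
against x whose inversion at d = 0.2 gives the tolerance threshold.

## The clock model and its assumptions

`fit_clock()` fits `age = b0 + Σ w_j beta_j` by elastic net with mixing
parameter α = 0.5, the convention of the epigenetic-clock literature: the
equal L1/L2 mix selects a sparse site panel while tolerating the strong
inter-site correlation typical of methylation data. The penalty strength λ
is not stated by convention, so the package chooses it by internal 10-fold
cross-validation minimising mean squared prediction error (the most common
default; the one-standard-error rule is deliberately not used, as the goal
is best predictive performance, not maximal parsimony). Features are
standardised internally and coefficients reported on the beta scale.

Site selection is data-driven on every refit: a perturbed-age fit is free
to select a completely different panel than the baseline, mirroring the
real situation where a new species' clock sites are unknown in advance.
`selection_overlap()` and `count_selected_sites()` expose the two
signatures of degradation on the selection side — panels shrink and stop
overlapping the baseline as error grows.

Assumptions worth stating: the age–methylation relationship is modelled as
linear (no log-linear juvenile rescaling), predictions are unclamped (a
negative predicted age is reported with a warning rather than truncated,
so error metrics are not silently biased), and no covariates (sex, tissue,
population) enter the model.

## The error-injection model

`inject_age_error(ages, percent)` returns `age · (1 + u)`,
`u ~ Uniform(−percent/100, +percent/100)`, independent per sample. The
experimental statement being modelled is a *bound* — ages may be off by up
to x% either way — and within a stated bound the uniform law adds the least
additional structure; it is isolated in one function so a different noise
law can be swapped in. Error is applied to calibration ages only, never to
the hold-out; 100% is the admissible maximum (beyond it an age could go
negative); and noise is redrawn independently at every level and every
repetition — each level is its own experiment, not an accumulation
(`redraw_per_rep = FALSE` shares one draw across a level's repetitions for
the alternative reading).

## Repetitions, pooling, and the statistics

Each level is refit `repetitions` times (default 5; 10 in the full-scale
configuration). Per-sample hold-out errors from all repetitions of a level
are pooled, and the pooled vectors are compared against the baseline's
per-sample errors. Pooling is the default (rather than testing the
per-repetition means) because it uses the per-sample information the
hold-out set actually provides; both modes are available via the sweep
result's long error table.

The t-test defaults to Student's pooled-variance form rather than Welch:
the companion effect size is Cohen's d with a pooled SD, and the two should
make the same homogeneity assumption. Welch is a flag away
(`var_equal = FALSE`). Cohen's d is signed as (perturbed − baseline)/pooled
SD, so worse predictions give positive d. "Absolute error" and "relative
error" summaries are means of the per-sample vectors (medians behind the
`center` flag); relative error is normalised by each individual's true age,
not by the cohort's age range. No multiple-testing correction is applied
across levels — the sweep is read as a dose–response curve, and correcting
would change the meaning of the first-crossing threshold.

Thresholds are reported as the *first* level at which a criterion triggers.
On fine grids a single noisy level can trigger spuriously, so
`detect_thresholds(sustained = 3)` optionally requires three consecutive
triggering levels. The effect-size line is ordinary least squares on the
per-level d values; `solve_threshold()` inverts it at a target d and
reports both the real-valued crossing and the nearest integer percent.
`aggregate_datasets()` averages d curves across cohorts before the fit,
for multi-species summaries.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the known-age cohorts used
in published tolerance analyses, whose sizes and age ranges are built in
as presets: human whole blood (394 samples, 16–88 years), zebrafish fin
(96, 11.9–60.1 weeks), mouse multi-tissue (153, 1–31 weeks), turtle skin
(63, 1–43 years). Ages are drawn uniformly over the profile range — the
real cohorts' age distributions are not published, and the flat
distribution is the least-structured choice covering the printed ranges.

Sites come in two kinds. An informative site follows
`beta = b0 + s · z + ε`, with z the min–max-normalised age, slope
`s = ±slope_magnitude` (default 0.4 beta units across the age range; half
the sites increase with age and half decrease, matching the observation
that methylation drifts in both directions), intercept `b0` uniform in
`baseline_range`, and Gaussian noise `ε` (default SD 0.05); a noise site
omits the age term. All betas are clamped to [0, 1]. The default signal is
100 informative sites among 900 uninformative ones. Gaussian noise with
clamping was chosen over a beta-distributed noise model for transparent
variance control; the generator records ground truth (`site_info`) so tests
can verify that informative sites, and only they, correlate with age.

What the generator does *not* emulate matters for interpretation: no
array-platform artifacts, batch effects, probe biases, or sex/population
structure, and noise is homoscedastic. The synthetic signal is consequently
*cleaner* than real methylation data — baseline clocks reach r ≈ 0.998 and
mean errors near one year, versus r ≈ 0.97 and several-year errors for real
cohorts. Against such a tight baseline, degradation is detectable at lower
error levels, so synthetic tolerance thresholds sit well below the ≈22%
found on real data. Passing tests therefore demonstrate that the machinery
detects degradation correctly and that thresholds behave as claimed
(positive effect-size slope, stability under subsampling), not that the
synthetic threshold equals the real-data one.

## Numerical and engineering choices

- **Lambda path.** The candidate λ path has 60 log-spaced points (glmnet's
  default is 100). On age-clock data the CV-minimising λ lies well inside
  the path, and the extra 40 near-zero penalties only add dense, slow tail
  fits; at both lengths the selected model is the same.
- **Split rounding.** The calibration partition holds
  `round(n · 0.7)` samples, rounding half up (63 samples → 44/19); fixed
  so splits are reproducible across platforms.
- **Seed ladder.** A master seed spawns one child seed per purpose (split,
  baseline, each level × repetition cell) via a seeded draw, so any cell
  can be re-run in isolation and checkpointed sweeps are bit-identical to
  uninterrupted ones. Checkpoints are per-level JSON files.
- **Serialisation.** Beta matrices and ages are written at 17 significant
  digits and parsed with correctly-rounded conversion, so a write/read
  cycle is lossless; clocks serialise to JSON (intercept, site→weight map,
  α, λ, seeds) for audit.
- **Degenerate inputs.** Constant calibration ages are rejected; an
  all-constant beta matrix yields an intercept-only clock (mean age) with a
  warning; a single usable site reduces to OLS; t-tests on two constant
  samples return p = 1 (equal means) or p = 0 with a warning (unequal);
  zero pooled SD makes Cohen's d an error rather than an infinity.
- **Problem sizes.** The test suite runs cohorts of 60–200 samples with
  150–1000 sites for unit checks; the end-to-end checks use the
  study-scale cohort (150 samples, 1000 sites, 20 repetitions at level 0;
  2 levels × 5 repetitions × 10 seeds for the degradation ordering) and,
  for the subsampling experiment, the full 394-sample profile against its
  96-sample subsample on a 5–60% grid in steps of 5 with 5 repetitions
  across 10 seeds. These sizes were chosen so a complete run finishes in
  minutes on one core while leaving each check comfortably powered.

## Known limitations

Uniform, unbiased, homoscedastic age error is the model under study;
systematic bias (e.g. proxies that always under-age old animals) and
individual gross errors are different phenomena — the
`prune_outliers_and_refit()` screening loop addresses the latter only
partially. Thresholds are first-crossing statistics on a stochastic curve
and inherit its seed-to-seed variability; the sustained-crossing option
trades sensitivity for stability. And all quantitative results on
synthetic cohorts transfer to real data only qualitatively, for the
signal-cleanliness reason above.
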