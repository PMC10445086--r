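# clocktol

How much error in calibration ages can an epigenetic clock tolerate?

Epigenetic clocks predict the age of an animal from DNA methylation levels
(beta values in [0, 1]) at a sparse set of CpG sites, selected and weighted
by elastic-net regression on a cohort of known-age individuals. For most
wildlife species, exactly known ages are rare: calibration ages often come
from growth marks, length–age curves or other proxies that carry their own
error. `clocktol` quantifies the consequence. It injects controlled,
bounded relative error into the calibration ages, refits the clock at every
error level, and measures — on an untouched hold-out partition with exact
ages — when age prediction becomes detectably worse.

## The method

**Clock.** `age_i = b0 + Σ_j w_j · beta_ij`, fit by elastic net with mixing
parameter α = 0.5 (equal L1/L2 weight, which drives most `w_j` to zero and
selects a small site panel). The penalty strength λ is chosen by internal
10-fold cross-validation minimising mean squared prediction error. Cohorts
are split 70% calibration / 30% hold-out once per experiment; the hold-out
ages are never perturbed.

**Error injection.** At level `x` (percent), each calibration age becomes
`age · (1 + u)` with `u ~ Uniform(−x/100, +x/100)`, drawn independently per
sample: an age can be off by *up to* x% in either direction. Levels run
from 1% to 100% — beyond 100% a perturbed age could go negative.

**Detection.** At each level, the clock is refit several times with fresh
noise; the per-sample hold-out errors (absolute, in age units, and
relative, in % of true age) are pooled and compared with the baseline
clock's errors using

- an unpaired Student t-test (`p < 0.05`),
- Cohen's d with pooled SD (`d = 0.2 / 0.5 / 0.8` = small / medium / large),
- an ordinary-least-squares line `d(x) = a·x + b` fitted to the per-level
  effect sizes, whose inversion `x* = (0.2 − b)/a` gives the tolerance
  threshold in percent.

Published work applying this design to four vertebrate cohorts (human,
zebrafish, mouse, marine turtle) reports the cross-species line
`d(x) = (1.176 x − 5.493)/100`, which crosses d = 0.2 at **22%** calibration
error. The four cohorts' sizes and age ranges are built in as profiles
(`profile_presets()`), and a synthetic-data generator reproduces their
structure so the whole pipeline is testable without downloads.

## Worked example

```r
library(clocktol)

cohort <- generate_dataset(
  dataset_profile("demo", n_samples = 150, age_min = 16, age_max = 88),
  signal_spec(),   # 100 age-informative + 900 noise CpG sites
  seed = 1)

cfg   <- sweep_config(levels = c(1, 2, 5, 10, 20, 40), repetitions = 5, seed = 1)
sweep <- run_error_sweep(cohort, cfg)
sweep$baseline
#> <performance_summary> n_test = 45
#>   r = 0.998, mean abs error = 1.142, mean rel error = 2.69%, 74 CpG sites

report <- detect_thresholds(sweep)
report
#> <threshold_report>
#>   absolute-error t-test first p < 0.05 at: 10%
#>   relative-error t-test first p < 0.05 at: 20%
#>   Cohen's d first above 0.2 at:          5%
#> <effect_size_model> Cohen's d vs training-age error
#>   d(x) = (2.712 x + 10.091) / 100   (R^2 = 0.909)

tidy(report)
#> # A tibble: 6 × 7
#>   level t_abs    p_abs t_rel      p_rel      d classification
#>   <dbl> <dbl>    <dbl> <dbl>      <dbl>  <dbl> <chr>
#> 1     1 0.274 7.84e- 1 0.106 0.916      0.0447 negligible
#> 2     2 0.580 5.62e- 1 0.358 0.721      0.0948 negligible
#> 3     5 1.70  9.04e- 2 1.23  0.219      0.277  small
#> 4    10 2.14  3.30e- 2 1.78  0.0770     0.350  small
#> 5    20 5.40  1.47e- 7 3.80  0.000181   0.882  large
#> 6    40 6.56  2.69e-10 4.76  0.00000318 1.07   large
```

Reading the output: the baseline clock (no injected error) predicts
hold-out age with r = 0.998 and a mean miss of 1.1 years using 74 CpG
sites. As injected calibration error grows, hold-out errors inflate; here a
small effect (d > 0.2) is already detectable at 5% and the t-test on
absolute errors triggers at 10%. The synthetic cohort is *cleaner* than
real methylation cohorts (its baseline error is far below the several-year
misses typical of real clocks), so its tolerance threshold sits lower than
the published 22% — the degradation is easier to detect against a tight
baseline. Inverting the published cross-species line reproduces that
threshold:

```r
published <- effect_size_model(slope = 1.176 / 100, intercept = -5.493 / 100)
solve_threshold(published, d_target = 0.2)
#> # A tibble: 1 × 3
#>   d_target level_exact level_percent
#>      <dbl>       <dbl>         <int>
#> 1      0.2        21.7            22
```

`autoplot(sweep)` and `autoplot(report)` draw the degradation curve and the
effect-size line; `cmd_simulate()` / `cmd_sweep()` / `cmd_report()` run the
same pipeline against files on disk (a thin `inst/exec/clocktol` script
exposes them to the shell), writing TSV/JSON outputs plus a manifest with
seeds and input digests.

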