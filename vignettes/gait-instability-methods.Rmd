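---
title: "Measuring gait instability in growing dogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait instability in growing dogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitvar)
```

## The problem

Canine hip dysplasia (HD) is a polygenic developmental malformation of the
hip joint, usually confirmed radiographically only after the main growth
phase. The hypothesis behind this package is kinematic: dogs developing HD
walk with a more *unsteady* gait while growing, so that serial gait
measurements should show a larger scatter around each dog's own growth
trend than in healthy dogs. The package implements that serial analysis:
dogs are walked on a leash at regular intervals from roughly 12 weeks to
15 months of age, an inertial-measurement-unit (IMU) system extracts
scalar gait features per walking trial, and the per-dog *variability* of
each feature over the growth period — not its level — is the outcome.

## The instability score

For one dog and one feature, let $(t_k, y_k)$, $k = 1 \dots n$, be the
day-averaged feature values at ages $t_k$ (days). The package fits
ordinary least squares with intercept,

$$ y_k = a + b\,t_k + \varepsilon_k, $$

and scores instability as the mean squared residual

$$ \mathrm{MSE} = \frac{1}{n} \sum_{k=1}^{n} \mathrm{res}_k^2, \qquad
   \mathrm{res}_k = y_k - (\hat a + \hat b\, t_k). $$

The divisor is deliberately the visit count $n$, not the
degrees-of-freedom-corrected $n-2$; the reference analysis this package
reproduces averages the squared deviations directly. The corrected
variant is available through `mse_score(fit, df_correct = TRUE)`. Because
each dog is detrended against its own line, stable breed and
individual-size offsets cancel; only scatter around the individual trend
remains. A useful identity follows from OLS theory: for i.i.d. noise of
variance $\sigma^2$ around a true line,
$E[\mathrm{MSE}] = \sigma^2 (n-2)/n$, which the test suite verifies by
Monte Carlo and the simulator's `truth_report()` uses as its oracle.

Series with fewer than 3 points are refused (`fit_linear_trend()` errors):
a 2-point fit is exact, its MSE tautologically zero, and it would bias the
score downwards.

## Preprocessing

Three deterministic rules replace the reference study's interactive visual
screening:

1. **Plausibility bounds** (`flag_implausible()`): a value is implausible
   when it exceeds its category's upper bound or is at/below the lower
   bound — energies (0, 200], step lengths (0.1 m, 0.6 m], withers height
   (0.15 m, 0.6 m] — or when the dog is older than 450 d. Bound
   orientation is exactly "> upper" / "≤ lower". Features without a bound
   category are only age-checked.
2. **Whole-day exclusion** (`drop_flagged_days()`): one flagged value
   voids the dog's *entire* day, all features and runs. The anomalies
   these bounds catch (e.g. 2 m step lengths) originate in the upstream
   feature-extraction software — typically doubly recorded stride
   frequencies — so the whole session is suspect.
3. **Minimum measurement days** (`filter_min_days()`): after averaging
   the 1–3 runs of each day (`average_runs_per_day()`), dogs with fewer
   than 4 distinct surviving days are removed. The count is per dog, not
   per feature: a feature missing on some days merely shortens that
   feature's series.

Preprocessing satisfies a conservation identity (every input row is kept,
on an excluded day, or owned by a removed dog), is idempotent, and is
independent of input row order; all three are property-tested.

## Side alignment and mirroring

HD is usually asymmetric, so features are expressed relative to the
pathological limb. The catalogue gives each feature a laterality (`left`,
`right`, `axial`) and a mirrored counterpart (`symmetry_pair`): the
contralateral twin for lateralized features, the left/right-swapped pair
for symmetry features. For a dog whose pathological side differs from the
reference side (default `right`), every non-axial feature is swapped with
its counterpart; axial features never move. The mapping is an involution.
Healthy dogs have no pathological side; they adopt the configured
reference side, which makes them map identically under either convention
— the reference analysis never stated how healthy dogs were oriented, and
on symmetric cohorts the group results are side-invariant, so this is
exposed as configuration rather than guessed. The catalogue also carries
mirrored counterparts for symmetry features that the reference tables
print only once (e.g. `Extension Symmetry Femur R - Humerus L`), because
mirroring must be total for left-affected dogs to have somewhere to map
from.

One naming quirk is resolved in the catalogue: the reference tables label
the same feature "Peak vertical force" and "maximum ventral acceleration"
in different places; the catalogue uses one id (`ventral_acc_r`) with
"Ventral acceleration" as the display name.

## Group comparison

Per aligned feature, the healthy and HD groups of MSE scores are compared
with a two-sided **pooled-variance Student t-test**
(`two_sample_t()`, $df = n_a + n_b - 2$) at $\alpha = 0.05$. Pooled
rather than Welch is a deliberate choice: recomputing the test from the
reference study's printed extension summaries (means 2.03 vs 2.91, SDs
0.74 vs 1.10, n 30 vs 14) reproduces its printed p-value of
$3.1 \times 10^{-3}$ only in the pooled form (Welch gives
$1.4 \times 10^{-2}$). Welch remains available via `var_equal = FALSE`.
`t_from_summary()` computes the identical statistic from group summaries
alone, which is how printed tables are verified when raw data are
unavailable.

Shapiro–Wilk normality checks are reported per group but a failure does
*not* switch the test to a nonparametric alternative — the comparison
gains a warning note instead, mirroring the reference analysis, which
reports t-tests throughout. Likewise no multiple-testing correction is
applied by default across the 13 features; `p_adjust = "holm"` (or any
`stats::p.adjust` method) enables one, with the adjusted p-values then
driving the significance flag.

Box-whisker summaries use linear-interpolation quartiles
(`stats::quantile()` type 7, the common default — no convention was
stated) and whiskers at the most extreme points within 1.5 IQR.
Significance stars follow the usual thresholds (\*: p < 0.05,
\*\*: p < 0.01, \*\*\*: p < 0.001).

## The synthetic cohort

The raw study data were never deposited, so the package ships a simulator
(`simulate_cohort()`) that reproduces the *design*, making every pipeline
stage testable:

* **Cohort**: 44 dogs, 14 HD, breed weights 37:11:6 (Australian
  Shepherd : Golden Retriever : Rottweiler). Pathological sides are
  assigned left/right with equal probability.
* **Schedule**: deterministic visits at 84, 112, 140, 168, 196, 256, 316,
  376, 436 days — monthly from 12 to 28 weeks, bimonthly afterwards, all
  within the 450 d age bound; optional uniform jitter. The reference
  design states only the interval lengths, so the exact grid is the
  package's choice. Each dog-day draws 1–3 runs uniformly.
* **Signal model**: value = feature intercept + breed offset + dog offset
  + slope × age + visit noise + run noise, all Gaussian. For HD dogs the
  visit noise of pathological-side and axial features is inflated
  ($\sigma_{HD} > \sigma_{healthy}$); everything else draws healthy
  noise. Homoscedastic Gaussian noise is the simplest structure matching
  the t-test assumptions the analysis itself invokes; the reference study
  gives no distributional detail.
* **Calibration**: per-feature sigmas are inverted from the reference
  study's printed group MSE means via
  $E[\mathrm{MSE}] = (\sigma_v^2 + \sigma_{run}^2 E[1/m])\,(n-2)/n$ with
  $n = 9$ visits and $E[1/m] = 11/18$, with run noise fixed at 25 % of
  the target scale. These are calibration constants, not claims about the
  study's true parameters; trends (e.g. extension 18° + 0.02°/day) are
  plausible stand-ins, since per-feature trend magnitudes were never
  published. One deliberate exception: the step-length features use a
  dispersion ~30× smaller than their printed MSE implies (ratio between
  groups preserved), because the printed value corresponds to residuals
  of ~0.2 m that would constantly violate the (0.1 m, 0.6 m] plausibility
  band and make clean data indistinguishable from anomalies.
* **Anomalies**: with probability `implausible_rate`, a dog-day receives
  one canonical out-of-bounds value (step length 2 m, energy 400, withers
  1 m), recorded in a truth table so the filter can be audited
  (`truth_report()` also predicts which dogs the 4-day rule must then
  remove).
* **Determinism**: a single integer seed governs every draw; equal seeds
  give identical output.

What the simulator does **not** emulate: real gait waveforms, nonlinear
growth, per-dog slope heterogeneity, correlated noise across features,
missed visits, and measurement error that depends on age or handler. A
passing test suite therefore shows the *pipeline* is correct and
well-calibrated under the stated model — not that real dogs behave this
way.

## Numerical and design notes

* OLS is solved in closed form from centred sums; the suite checks it
  against an independent normal-equations solver to 1e-10 and residuals
  sum to zero to numerical tolerance. Degenerate designs (all ages equal)
  are refused rather than pseudo-inverted.
* CSV dialects are fixed (comma, UTF-8, header, "." decimal); ages are
  stored in integer days — the one unambiguous axis, since the study
  mixes weeks, months and days. Results round-trip to ~15 significant
  digits through `write_results()`/`read_results()`.
* Symmetry features are treated as opaque scalar values: their defining
  formula was never published, so the package makes no attempt to
  recompute them from limb pairs.
* Problem sizes in the checks are chosen to keep the whole suite
  comfortably interactive: 1000 random series for the OLS oracle, 10^4
  Monte-Carlo replicates for the MSE shrinkage identity, 2000 simulated
  null cohorts (single-feature design) for the whole-pipeline type-I
  check, and 300 replicate cohorts for the simulator-vs-oracle mean
  comparison.

## Known limitations

* The printed p-values of the reference study's *additional* feature
  table cannot be reproduced from its own printed summaries under any
  standard t-test (e.g. printed $4.4 \times 10^{-2}$ vs recomputed
  $1.7 \times 10^{-2}$), and two of its rows print identical numbers
  under different names; these rows are carried as data but not used as
  oracles. Only the extension row and the "all six limb features below
  0.01" / "HD mean higher on all 13" claims are asserted.
* With only ~9 visits per dog the MSE is a noisy statistic (its sampling
  SD is of the order of the group differences), so single simulated
  cohorts will not always flag every feature — only the group-level and
  repeated-seed behaviour is guaranteed.
* Raw IMU signal processing and feature extraction are out of scope; the
  pipeline starts at the feature table.
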