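# gaitvar

Longitudinal gait-instability analysis for growing dogs at risk of hip
dysplasia (HD).

Serial IMU-based gait analysis of puppies (roughly 12 weeks to 15 months
of age) yields scalar gait features — step length, acceleration and
gyroscope amplitudes, left/right symmetry indices — at each examination
day. The hypothesis this package operationalises is that dogs developing
HD walk *less steadily* while growing: not the level of a feature but its
scatter around the dog's own growth trend separates the groups. For dog
*i* and feature *f* with day-averaged values *y\_k* at ages *t\_k* (days,
*k* = 1…*n*), the package fits per-dog ordinary least squares

    y_k = a + b t_k + res_k

and scores instability as the mean squared residual

    MSE = (1/n) Σ res_k² ,

then compares healthy vs HD dogs per feature (features first aligned to
each dog's pathological side, mirroring symmetry features) with
Shapiro–Wilk normality checks and a two-sided pooled-variance Student
t-test at α = 0.05.

The pipeline stages are:

1. **Plausibility filter** — category bounds (energies (0, 200], step
   lengths (0.1 m, 0.6 m], withers (0.15 m, 0.6 m], age ≤ 450 d); one
   implausible value excludes the dog's whole examination day.
2. **Day averaging** — the 1–3 consecutive runs of a day are averaged.
3. **Cohort filter** — dogs with fewer than 4 measurement days are
   removed.
4. **Detrending** — per dog × feature OLS vs age; MSE instability score.
5. **Side alignment** — lateralized and symmetry features mirrored onto
   the pathological side (configurable reference side for healthy dogs).
6. **Group comparison** — per-feature summaries, t-tests, box-whisker
   data and an annotated figure.

Because the underlying clinical study deposited no raw data, the package
includes a synthetic-cohort simulator (`simulate_cohort()`) reproducing
the study design — 44 dogs (14 HD), monthly then bimonthly visits, up to
3 runs/day, linear growth trends, HD-inflated dispersion on the
pathological side, injected implausible values with a truth table — so
every stage is testable end to end.

## Worked example

```r
library(gaitvar)

cfg <- cohort_config(seed = 42)          # study-design defaults
sim <- simulate_cohort(cfg)
res <- run_gait_analysis(sim$runs, sim$dogs, sim$features)

res$counts
#>  rows_in rows_on_excluded_days rows_of_removed_dogs rows_kept day_records dogs_analysed
#>    17871                     0                    0     17871        9108            44

subset(res$comparisons, feature_id == "extension_r",
       c(n_healthy, n_hd, mean_healthy, mean_hd, t_stat, p_value))
#> # A tibble: 1 × 6
#>   n_healthy  n_hd mean_healthy mean_hd t_stat p_value
#> 1        30    14         2.36    2.56 -0.442   0.661
```

All 44 simulated dogs survive preprocessing (no anomalies were injected
at rate 0); the extension feature's mean MSE is higher in the 14 HD dogs
(2.56 vs 2.36 in units of squared degrees), though this single seed does
not reach significance — with ~9 visits per dog the MSE is a noisy
statistic, and group separation at the calibrated effect size emerges
over repeated cohorts, not in every draw.

Verifying a published group table from its printed summaries:

```r
t_from_summary(2.03, 0.74, 30, 2.91, 1.10, 14)
#> $t_stat   -3.133940
#> $p_value   0.003141936
#> $df       42
```

i.e. the printed extension p-value of 3.1 × 10⁻³ at 2 significant
figures.

The same workflow as a sequence of scripts (each writes its tables and a
manifest under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_instability.R
Rscript analysis/04_group_comparison.R
Rscript analysis/05_reference_checks.R
```

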