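# emodyn

Emotion dynamics from intensive longitudinal assessments.

## The problem

Intensive longitudinal assessment (ILA) designs measure positive affect
(PA) and negative affect (NA) repeatedly: **EMA** (ecological momentary
assessment) prompts ~6 in-the-moment ratings per day, **EOD** diaries
collect one end-of-day summary, and the **DRM** (day reconstruction
method) has respondents divide one day into self-defined episodes and
rate each. Researchers derive person-level *emotion dynamics* from any
of these streams and often treat the methods as interchangeable. This
package implements the full measurement battery and the cross-method
comparability analysis needed to test that assumption, for
methodologists and ILA study teams.

## What it computes

Eleven per-person measures, identical for every method, from each
person's PA/NA series (episode ratings rescaled by
`100 (raw + 0.5) / 7` and timestamped at episode midpoints):

| Measure | Definition |
|---|---|
| Mean level (PA, NA) | mean of ratings |
| Variability (PA, NA) | within-person SD |
| Instability (PA, NA) | RMSSD, `sqrt(mean((x_{t+1} - x_t)^2))` over retained adjacent pairs |
| Inertia (PA, NA) | person-specific AR(1) slope (empirical-Bayes, multilevel) |
| Network density | `sum(abs(.))` of the 2 autoregressive + 2 cross-lagged person VAR parameters |
| Mixed emotions | MIN index, mean of `(PA + NA) - abs(PA - NA) = 2 min(PA, NA)` |
| Dialecticism | within-person cor(PA, NA) |

Adjacency-based measures first apply gap rules: EMA drops overnight and
>10 h pairs; DRM drops episode-midpoint gaps >10 h; EOD keeps only
consecutive diary days. Inertia and density are estimated with
two-level random-slope models (REML, lme4) and returned as
empirical-Bayes person coefficients — per-person estimates shrunk
toward the population value.

The comparison layer reproduces the three analysis steps of a
cross-method study: repeated-measures ANOVA with Bonferroni pairwise
tests; dependent-correlation Wald tests on Fisher-z scale
(Olkin–Siotani covariance, bootstrap fallback) with Cohen *q* effect
sizes; correlation networks with node-strength centrality; and
health-outcome correlations with incremental-validity regressions. A
calibrated synthetic-study generator (person-specific latent bivariate
VAR(1) sampled by all three methods) stands in for panel data that
cannot be redistributed; see `vignettes/emotion-dynamics-methods.Rmd`.

## Worked example

```r
library(emodyn)

cfg <- generator_config(n_persons = 90, seed = 42)
gen <- generate_study(cfg)                      # study + ground truth
study <- apply_inclusion_filter(gen$study)      # >= 4 obs per method
profiles <- compute_profiles(study)             # 11 measures x person x method
compare_methods(profiles)
```

```
         measure mean_EMA mean_EOD mean_DRM        F p_anova r_EMA_EOD r_EMA_DRM r_EOD_DRM wald_chisq wald_p
         pa_mean   64.326   64.726   64.515    0.202   0.817     0.990     0.891     0.896    125.054  0.000
         na_mean   14.429   13.401   15.729   19.953   0.000     0.989     0.942     0.940     64.009  0.000
           pa_sd   12.568    7.635    8.848   81.166   0.000     0.842     0.361     0.184     83.840  0.000
        pa_rmssd   13.537   10.578    8.010   44.166   0.000     0.103     0.433     0.053      8.426  0.015
      pa_inertia    0.371   -0.131    0.570 1159.603   0.000    -0.069     0.243     0.331     13.695  0.001
 network_density    0.758    0.422    1.084  308.973   0.000     0.559     0.226     0.063     18.401  0.000
  mixed_emotions   28.113   26.450   30.877   19.707   0.000     0.988     0.939     0.935     62.829  0.000
    dialecticism   -0.343   -0.305   -0.314    0.692   0.503     0.387     0.111     0.116      3.499  0.174
 (... remaining measures elided)
```

Read it like the study's comparison tables: per-method means with the
repeated-measures ANOVA (`F`, df (2, 178) at n = 90), the three
cross-method correlations of each measure, and the Wald χ² (df 2)
testing whether those dependent correlations differ. The qualitative
pattern the package is built to exhibit is visible: mean levels and
mixed emotions correspond almost perfectly across methods (r ≥ 0.89),
variability moderately, and the lagged measures (inertia, density)
weakly — the synthetic EOD inertia is even negative, because hourly
latent dynamics leave almost no day-to-day dependence (see the
vignette's limitations section).

```r
correlation_network(profiles[profiles$method == "EMA", ])
```

```
network_summary (EMA, n=90, |r| threshold 0.21)
network_density           pa_sd      na_inertia      pa_inertia           na_sd
           3.87            3.34            3.16            3.14            2.93
   dialecticism        na_rmssd  mixed_emotions         na_mean        pa_rmssd
           2.28            2.16            2.14            2.10            1.71
        pa_mean
           1.71
```

Node strength is each measure's summed absolute correlation with the
other ten; 0.21 is the smallest correlation significant at P < .05 for
n = 90 (`critical_r(90)`).

### Command line

```sh
Rscript inst/cli/ila.R simulate --config cfg.json --seed 7 --out data/
Rscript inst/cli/ila.R dynamics --in data/
Rscript inst/cli/ila.R compare  --in data/ --rank
```

Stages communicate through CSV files (`observations.csv`,
`episodes.csv`, `health.csv` → `profiles.csv` → comparison outputs), so
real study exports can replace the simulator at the `observations.csv`
boundary. Every stage writes a JSON sidecar recording its seed and
flags.

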