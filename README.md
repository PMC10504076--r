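# hfpeftrial

Participant-level analysis pipeline for randomized weight-loss trials in the
obesity phenotype of heart failure with preserved ejection fraction (HFpEF),
analyzed by obesity class. It is written for trial statisticians and
methods researchers who want the full prespecified subgroup-analysis stack —
not just the headline model — as tested, reusable R functions:

* **Hierarchical-composite win ratio.** Every treated participant is
  compared with every control in the stratum through an ordered endpoint
  hierarchy (all-cause death over the pair's shared follow-up; heart-failure
  events; KCCQ-CSS improvement thresholds of 15/10/5 points; 6-minute walk
  distance improvement ≥ 30 m). The win ratio is `wins / losses`; ties fall
  through to the next level. CIs come from a within-arm participant
  bootstrap on the log scale (a U-statistic projection variance is available
  for large simulation studies), and equality of the stratum win ratios is
  tested with an inverse-variance Cochran's Q on log WR.
* **Multiply-imputed ANCOVA subgroup effects.** Week-52 changes are modelled
  as `change ~ arm * class + baseline`; missing week-52 outcomes are
  multiply imputed from the proper posterior predictive of that same model,
  per-class estimated treatment differences (ETDs) are pooled by Rubin's
  rules (`T = W + (1 + 1/m) B`), and the treatment-by-class interaction is
  pooled with the multivariate (D1) combination and reported as an F-test.
  CRP is analyzed on the log scale and reported as ratios. An on-treatment
  complete-case estimand is provided alongside the intention-to-treat one.
* **Baseline trend tests.** Jonckheere–Terpstra (continuous, tie-corrected,
  exact permutation for small n), Cochran–Armitage (binary) and a
  score-based Cochran–Mantel–Haenszel statistic (ordered multinomial) across
  obesity classes I/II/III.
* **Weight-loss dose–response.** Within the semaglutide arm, continuous
  regressions of endpoint change on percent weight change (reported per 10%
  weight *decrease*; CRP as a ratio), ordinal analyses over the five
  weight-loss categories (<5%, 5–<10%, 10–<15%, 15–<20%, ≥20%) with a
  single-df linearity F-test, and baseline per-BMI association regressions.
* **Synthetic trial generator.** A seeded generator reproduces the
  statistical structure these analyses assume — ~529 participants 1:1,
  roughly equal thirds in BMI classes I/II/III, baseline KCCQ-CSS/6MWD
  falling and CRP rising with BMI, configurable treatment effects and
  weight-loss mediation, MAR missingness at week 52, rare death/HF events —
  so the entire pipeline is testable without access to trial data.

## Worked example

```r
library(hfpeftrial)

df  <- generate_trial(trial_config(n_per_arm = 265, seed = 1))
imp <- impute_endpoint(df, "kccq", m = 20, seed = 2)
subgroup_etds_mi(imp, "kccq")
#> Treatment effect by obesity class - kccq endpoint (intention-to-treat (multiple imputation))
#>   class I   ETD     7.21  [2.86, 11.6]  p = 0.00117
#>   class II  ETD     6.66  [2.16, 11.2]  p = 0.00376
#>   class III ETD     7.58  [2.9, 12.3]  p = 0.0015
#>   interaction F = 0.039 on (2, 5139) df, p = 0.962
```

The generator's default total KCCQ-CSS treatment effect is 7.8 points; each
class recovers it (ETDs 6.7–7.6 points, all CIs excluding 0) and the
interaction F-test finds no heterogeneity, as expected under a homogeneous
configuration.

```r
win_ratio(df, stratum = "I", ci_method = "bootstrap", B = 1000, seed = 3)
#> Win ratio, stratum I (97 treated x 99 control pairs)
#>   wins 4066, losses 2634, ties 2903
#>   WR = 1.54, 95% CI [1.03, 2.32]  (bootstrap)
#>         level wins losses
#> 1       death   96    197
#> 2   hf_events   93    390
#> 3   kccq_ge15 2117    840
#> 4   kccq_ge10  448    441
#> 5    kccq_ge5  627    266
#> 6 sixmwd_ge30  685    500
```

Of the 97 × 99 = 9603 class-I pairs, most are decided at the KCCQ threshold
levels (deaths and HF events are rare, so the upper levels are mostly
ties), and treated participants win 1.54 times as often as they lose.

```r
fit_dose_response(df, "kccq", "model1")
#> kccq endpoint, model1: slope 4.37 [1.75, 7] per 10% weight decrease, p = 0.00118 (n = 246)
fit_dose_response(df, "crp", "model2")
#> crp endpoint, model2: ratio 0.748 [0.646, 0.867] per 10% weight decrease, p = 0.000133 (n = 246)
```

Each 10% of weight lost on semaglutide is associated with a ~4-point KCCQ
gain and a ~25% CRP reduction in this run (generative values: 6 points and
ratio 0.72; n = 246 gives CIs wide enough to cover both).

`run_full_analysis(analysis_config(...))` executes the whole pipeline —
baseline table, ITT and on-treatment subgroup ETDs, win ratios with
Cochran's Q, dose–response tables, event rates — and writes plain CSVs plus
a JSON manifest with every seed, so reruns are bit-identical.

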