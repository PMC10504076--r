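---
title: "Methods: obesity-class subgroup analysis of a weight-loss trial in HFpEF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: obesity-class subgroup analysis of a weight-loss trial in HFpEF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements: the estimands, the models behind each function, the default
parameter choices and why they were made, what the synthetic-trial generator
does and does not emulate, and the numerical conventions that matter when
results are compared across implementations.

## Setting and estimands

The package analyzes a 1:1 randomized, placebo-controlled trial of a
weight-loss drug (semaglutide) in patients with the obesity phenotype of
HFpEF: BMI ≥ 30 kg/m² and KCCQ-CSS < 90 points at baseline, with outcomes
measured at baseline and week 52 (day 364). Analyses are stratified by
obesity class — I = [30, 35), II = [35, 40), III = [40, ∞) kg/m², half-open
intervals so that a boundary BMI such as 35.0 is unambiguous.

Two estimands are carried through every continuous endpoint:

* **Intention-to-treat**: all randomized participants; missing week-52
  outcomes are multiply imputed.
* **On-treatment**: participants on randomized medication at week 52 with
  an observed outcome; complete-case.

Endpoints are analyzed as change from baseline with the baseline value as a
covariate (ANCOVA). CRP is log-transformed, so its treatment effects and
dose–response slopes are multiplicative ratios; body weight is analyzed as
percent change from baseline. The on-treatment analysis of a two-visit data
model is exactly the complete-case ANCOVA at week 52 — with only baseline
and week-52 measurements there is no repeated-measures structure for a
mixed model to exploit, so a visit-nested MMRM would collapse to the same
fit. That simplification is deliberate and is the main divergence from what
a multi-visit trial database would support.

## Multiple imputation and Rubin's rules

`impute_endpoint()` fits, among observed records, a normal-errors linear
model of the week-52 change on treatment, obesity class, their interaction
and the baseline value — the same model used for analysis, making the
imputation congenial. Each imputation draws the residual variance from its
scaled inverse-chi-square posterior, the coefficients from their normal
posterior given that variance, and the missing changes from the resulting
predictive distribution (proper imputation). Imputed CRP values are drawn
on the log scale and are therefore strictly positive. Death days and HF
events are never imputed; requesting them is an error. Whether treatment
arm belongs in the imputation model is not decidable from a published
analysis plan alone; including it (with the interaction) is the congenial,
conservative reading and is what the package does.

`rubin_pool()` combines per-imputation estimates `Q_1..Q_m` with variances
`U_1..U_m` as

* pooled estimate: mean of `Q_i`,
* total variance: `T = W + (1 + 1/m) B` with `W = mean(U_i)` and `B` the
  sample variance of `Q_i`,
* df: `(m − 1)(1 + W / ((1 + 1/m) B))²`, with `df = 10^6` (the normal
  limit) when `B = 0` exactly, avoiding a division by zero in the
  degenerate no-missing-data case.

The treatment-by-class interaction under MI pools the 2-dimensional
interaction-contrast vector with the multivariate combination (the D1
statistic): `F = Q̄' Ū⁻¹ Q̄ / (k (1 + r))` with
`r = (1 + 1/m) tr(B Ū⁻¹) / k`, and the Li–Raghunathan–Rubin denominator
df. This is the textbook small-m-valid way to get the "F-test for
interaction" under multiple imputation. `m` defaults to 100 in
`impute_endpoint()` (configurable up to 1000); Rubin's-rule contracts are
m-invariant, and the test suite uses m between 10 and 30 to keep runs at
desk scale.

## The hierarchical-composite win ratio

`win_ratio()` compares every treated participant with every control in the
stratum through an ordered hierarchy (`hierarchy_spec()`):

1. **All-cause death**, compared over the pair's *shared* follow-up window
   `min(obs_i, obs_j)` — the standard convention for unequal follow-up
   ("similar observation time"): a death inside the window loses against a
   survivor; two deaths inside the window are ordered by time (later death
   wins).
2. **HF events**: fewer events within the shared window wins; equal
   positive counts are broken by the later first event. A time-to-first
   -event-only rule is available (`hf_rule = "time_only"`).
3. **KCCQ-CSS improvement thresholds**, default 15, 10, 5 points: achieving
   at least the threshold when the opponent does not wins. The trial
   family's exact thresholds are defined in its primary-results protocol,
   not restated in the subgroup report; 15/10/5 are the clinically standard
   KCCQ bands and are fully configurable.
4. **6MWD improvement ≥ 30 m**, the conventional minimal clinically
   important difference for walk distance.

The first level producing a strict preference decides the pair; a missing
change score means that level cannot decide and falls through; a pair no
level decides is a tie. The win ratio is wins/losses. A custom
`continuous_change` level type compares raw change scores, under which a
one-level hierarchy reduces exactly to the Mann–Whitney win ratio
`U / (n₁n₂ − U)` — used as a cross-check in the tests against an
independent rank-based computation, alongside a brute-force pair-by-pair
enumeration oracle.

Because no variance estimator is canonical for stratified win ratios, the
package offers two: a within-arm participant bootstrap on the log scale
(default, B = 2000, seeded; resamples with zero wins or losses get a 0.5
continuity correction) and a large-sample U-statistic projection variance
(per-participant win/loss profiles, delta method on the log ratio). The two
agree on null simulations; the projection variance is used inside
500-replicate calibration studies where 2000 bootstrap resamples per
replicate would be wasteful. With zero losses the ratio is reported as
infinite with a one-sided interval, and `cochran_q_winratio()` refuses such
strata rather than silently applying a continuity correction — a silent
correction would make the Q statistic depend on an arbitrary constant.

Cochran's Q for equality of the per-class win ratios is the
inverse-variance-weighted sum of squared deviations of the log win ratios
from their weighted mean, against chi-square with K − 1 df. Under MI, only
KCCQ-CSS and 6MWD are imputed (events and deaths are observed data); the
per-imputation log win ratios and variances are pooled by Rubin's rules and
exponentiated.

## Baseline trend tests

Continuous baseline variables use the Jonckheere–Terpstra statistic
`U = Σ_{i<j} #{y > x} + ½#{y = x}` over ordered group pairs, with the
tie-corrected null mean and variance. The reported z folds in a continuity
correction of half a lattice step (`|U − μ| − 0.5`), keeping
`p = 2(1 − Φ(|z|))`; full-support enumeration shows this tracks the exact
permutation p to within about 0.015 for untied three-group splits of
N = 12, whereas the uncorrected normal misses by up to 0.06. For total
N ≤ 12 the exact permutation p (all group assignments enumerated) is used
by default. Binary variables use the Cochran–Armitage score test; ordered
multinomial variables (NYHA class) use the single-df nonzero-correlation
CMH statistic `(N − 1) r²` — the only CMH variant that tests an ordered
trend, which is why it was chosen where the analysis plan says only "CMH
test". Group scores default to 1..K (equally spaced); the JT test is
score-free by construction, while CA/CMH conclusions depend on the score
choice, which is documented and configurable.

## Dose–response analyses

Within the semaglutide arm, `fit_dose_response()` regresses the week-52
change (log scale for CRP) on percent weight change plus

* **Model 1**: baseline weight and the baseline endpoint;
* **Model 2**: Model 1 plus age, sex, atrial fibrillation, coronary artery
  disease, NYHA class (unordered factor over II/III/IV), log CRP and log
  NTproBNP.

The slope is reported per 10% weight *decrease* — internally the regressor
is percent change and the sign flip is applied at reporting, so a positive
slope always means "more loss, more improvement". The CRP slope is
exponentiated; `ratio_to_percent_decrease()` maps a ratio r (and its CI,
bounds swapped) to `100(1 − r)`. The ordinal analysis fits the same Model-1
covariates with the five weight-loss categories (<5%, 5–<10%, 10–<15%,
15–<20%, ≥20%; gains fall in "<5%", the top category is closed at ≥20%),
evaluates adjusted category means at the covariate sample means and tests
linearity with a single-df contrast over scores 1..5, reported as an
F-statistic. Empty categories are dropped with a warning and the contrast
uses the remaining scores. Under MI, category membership is recomputed per
imputation from the imputed weight; the headline observed-count table
(`weight_category_counts()`) uses recorded weights only. Whether such trial
tables use MI or observed cases is often ambiguous; both modes are
provided, with complete-case as the data-frame default.

Percentages in count tables are rounded to one decimal with the
largest-remainder method, so each percentage column sums to exactly 100.0 —
the convention under which published trial tables' percentage columns add
up, and the only convention that reproduces all of them from their counts.

## The synthetic-trial generator

`trial_config()`/`generate_trial()` emulate the structure the analyses
assume, not any specific dataset:

* ~530 participants 1:1; obesity classes drawn with probabilities
  0.34/0.32/0.34 and BMI from truncated log-normals within class (medians
  ≈ 32.5/37.2/43.5 kg/m²), so class proportions are exactly controllable.
* Baseline KCCQ-CSS (−0.8 points) and 6MWD (−6 m) fall and log CRP (+0.06)
  rises per unit BMI. Bounded scores use symmetric scaled-beta noise around
  an exactly linear conditional mean, which keeps KCCQ below the 90-point
  eligibility cut *without* truncation bias — a truncated normal would
  attenuate the very slope the baseline-association regressions are meant
  to recover. Demographics trend the same way as the baseline table
  (younger, more often female, higher NYHA, less coronary disease with
  higher class).
* Percent weight change is N(0, 3.5) in the placebo arm and
  N(−10.7, 6.5) under treatment. Endpoint changes are
  `direct arm effect + mediation × (weight loss/10%) + regression-to-mean
  + noise`, with mediation acting on realized individual weight change in
  both arms — so the within-arm dose–response is a real generative feature.
  `treatment_effects` are the *total* target ETDs (defaults: 7.8 KCCQ
  points, −10.7% weight, 20 m, log-CRP −0.3); the direct effect is derived
  by subtracting the expected mediated component. Mediation defaults (6.0
  points, 13 m, −0.33 log units per 10% loss) sit at the scale of the
  published dose–response estimates.
* Week-52 visits go missing with probability 0.07 under MAR (logistic in
  arm and baseline KCCQ only, intercept calibrated to the marginal rate);
  deaths (0.012/patient-year) and HF events (0.05/patient-year) are
  exponential/Poisson over a 420-day follow-up, independent of arm by
  default, so the upper hierarchy levels are mostly ties, as in a
  52-week HFpEF trial. Discontinuation (10%) is independent of outcome by
  default, making the two estimands agree up to noise.
* One seeded RNG stream drives the whole dataset; the same configuration
  (including seed) is byte-identical. Sub-streams per participant were
  considered and rejected — nothing in the package generates in parallel,
  and a single stream is the simpler determinism contract.

What the generator does **not** emulate: multi-visit trajectories,
treatment-dependent adverse events or discontinuation (available only by
explicit configuration), correlated baseline covariates beyond the
class-linked trends, and any attempt to match published medians or
quartiles beyond direction and scale. Passing tests therefore demonstrate
the estimators' statistical correctness under a faithful null/alternative
structure, not agreement with any real trial's numbers.

## Numerical conventions and edge cases

* Week 52 is day 364; weights kg, distances m, CRP mg/L, NTproBNP pg/mL.
* BMI consistency (weight/height²) is validated to 1e-6 relative.
* `fit_ancova()` errors on an empty arm-by-class cell, naming it; a
  single-class dataset collapses to two-group ANCOVA with no interaction.
* Imputed KCCQ/6MWD draws are not clamped to the physical score range:
  clamping the predictive draws would bias the pooled ANCOVA. Generated
  (observed) data do respect the ranges.
* CSVs are written with 17 significant digits so write-then-read
  round-trips are bit-exact; missing values are empty cells and
  `hf_event_days` is a semicolon-joined list.
* Test-suite and calibration problem sizes: type-I calibration uses 500
  replicates of a null generator at 150/arm (weight-change SD 10 in both
  arms so all five weight-loss categories are populated under the null);
  parameter recovery uses 200 replicates at 2000/arm; MI coverage uses 200
  MCAR replicates at 250/arm with m = 20. These sizes are the package's
  choices for stable Monte-Carlo estimates of 5%-level properties.

## Known limitations

* The on-treatment estimand is a complete-case ANCOVA, not an MMRM with
  unstructured covariance; with two visits these coincide, but the package
  cannot analyze interim visits at all.
* Only marginal (per-endpoint) imputation is provided, not joint chained
  equations across endpoints; the per-endpoint analyses make this
  congenial, but cross-endpoint summaries mix marginally-imputed values.
* The analytic win-ratio variance is a first-order projection; at very
  small strata (tens of pairs) the bootstrap is preferred.
* Cochran's Q refuses infinite win ratios instead of offering a corrected
  analysis; strata without losses need a hierarchy or sample-size change.
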