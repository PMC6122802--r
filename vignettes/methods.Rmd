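---
title: "Methods: augmenting breast cancer risk models with PRS, density and hormones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmenting breast cancer risk models with PRS, density and hormones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Gail and Rosner–Colditz models predict a woman's absolute risk of
invasive breast cancer from questionnaire factors (reproductive history,
benign breast disease, family history, and — in the Rosner–Colditz model —
BMI, height, alcohol and hormone-therapy use). Both are well calibrated but
only modestly discriminating. Three biological markers are well-confirmed
risk factors and only modestly correlated with each other: a polygenic risk
score (PRS) over common susceptibility variants, percent mammographic
density (MD, the dense area of the mammogram divided by the total area), and
circulating hormones — testosterone (T), estrone sulfate (E1S) and prolactin
(PRL). `bcriskaug` measures how much each marker, and their combinations,
adds to the base models: by change in age-adjusted AUC, by net
reclassification at a fixed absolute-risk threshold, and by the widening of
the population distribution of predicted 5-year risks.

Because individual-level cohort data of this kind are not public, the
package pairs the analysis machinery with a first-class synthetic data
generator that emulates a matched nested case–control study, so every stage
is testable end to end and statistical properties (parameter recovery,
confounding removal, over-fitting) can be verified against known truth.

## The synthetic nested case–control generator

`generate_population()` draws a source population of women aged 25–75 with:

* questionnaire factors at realistic marginals (age at menarche 12.5 ± 1.4;
  94% parous; first birth 25.5 ± 3.7; family history 11%; benign breast
  disease 42%; BMI 25.5 ± 4.5 kg/m²; alcohol zero-inflated log-normal with
  mean ≈ 4 g/day);
* genotypes at a 67-SNP panel simulated as independent binomial(2, risk
  allele frequency) counts — Hardy–Weinberg proportions, no linkage
  disequilibrium (the shipped panel is synthetic, with GWAS-scale per-allele
  odds ratios of 1.02–1.31);
* hormones as log-normal variables parameterised by the control median and
  10th percentile (E1S 562 [240]; T 0.66 [0.34]; PRL 9.7 [5.5]), a
  deliberately simple family for right-skewed positive biomarkers whose
  quantiles calibrate in closed form (p90 = median²/p10, hence E1S p90 ≈
  1,316 pmol/l);
* MD as a logit-normal variable mapped to the 0–100 percent scale
  (latent location −1.06, scale 0.9), giving a control mean of 28.7 percent
  and SD ≈ 16.4 while respecting the bounded support.

Case status is Bernoulli with logit equal to a baseline intercept plus a sum
of planted log odds ratios over the covariates: per SD on the analysis scale
for continuous covariates (PRS raw, MD percent, hormones log-transformed),
per unit for binary ones. The spec of the generating model on the *analysis*
scale makes the augmented logistic model correctly specified, so
parameter-recovery tests have an exact target. The default planted effects
are the separations implied by the case/control marginals of a large nursing
cohort: 0.34 SD for the PRS, 0.28 SD for MD (≈ 4.6 percentage points),
0.38/0.20/0.20 SD for log E1S/T/PRL, odds ratios 1.66 for family history and
1.38 for benign breast disease, and 0.075 SD for alcohol. The configured
biomarker marginals describe *controls*; because planted effects pull cases
upward, the generator pre-compensates the hormone and MD locations by
(expected case fraction) × (planted per-SD effect) so that control medians
land on the configured values.

`sample_nested_case_control()` mimics risk-set sampling: each case is
matched without replacement to controls of the same menopausal status and
hormone-therapy (HT) use within ±1 year of age — two controls for
postmenopausal cases not using HT, one otherwise. Matching on
blood-collection month, time of day and fasting is not simulated: none of
those variables enters any downstream computation. Cases in exhausted
matching cells are dropped with a warning and counted.

`apply_missingness()` masks biomarkers missing-completely-at-random by
default (rates ~30–35%, reflecting that density and hormone assays exist
only in subsets of real cohorts); an age-tilted missing-at-random variant is
available. The missingness mechanism of the motivating studies is not
characterised publicly, so MCAR is the default and the mechanism is a flag,
not a fixed assumption.

All randomness flows from one root seed through `stage_seed()` substreams:
identical configuration and seed reproduce identical datasets, fills, folds
and bootstrap draws.

**What the generator does not emulate:** linkage disequilibrium, cohort
attrition, questionnaire measurement error, secular trends in HT use,
ER-subtype etiologic heterogeneity (beyond a configurable ER+ fraction), and
real within-person correlation among PRS, MD and hormones — the literature
calls these "modestly correlated" without printing values, so the generator
draws them independently. Passing tests therefore demonstrate the
correctness and statistical behaviour of the *methods*, not the magnitudes
to expect in any particular cohort.

## Risk scores

* **PRS** (`compute_prs()`): sum over SNPs of risk-allele count × ln(odds
  ratio) — a multiplicative joint-effects model. Missing genotypes
  contribute their expected dosage `2 × frequency`. `standardize_prs()`
  rescales to mean 0, SD 1 over all participants (cases and controls
  pooled), with the population (n-denominator) SD — a declared, testable
  convention.
* **Modified Gail score** (`compute_gail_rr()`): categorical age at
  menarche, number of biopsies (interacting with age ≥ 50), age at first
  birth (interacting with family history), and binary family history;
  no atypical-hyperplasia term. The published category coefficients ship as
  a JSON configuration file (`gail_modified.json`) — coefficients are data,
  not code. The reference woman has relative risk exactly 1.
* **Simplified Rosner–Colditz-style score** (`compute_rc_score()`): a
  log-incidence linear predictor over menarche, birth index, family history,
  benign breast disease, premenopausal and postmenopausal durations, HT use,
  BMI (postmenopausal only), height and alcohol. The exact published
  functional forms live in prior literature; each term here is an explicit
  configurable transform, and the shipped coefficients are illustrative
  defaults meant to be replaced. The **birth index** is implemented as the
  cumulative woman-years since each birth, truncated at menopause —
  one concrete reading of "a combination of number of children and birth
  spacing", isolated in `birth_index()` so an alternative convention is a
  one-function change.
* **Quartile categories** (`quartile_categorize()`): cut points are the
  control-only 25/50/75th percentiles with type-7 (linear interpolation)
  quantiles; boundaries are left-closed (a value equal to a cut point falls
  in the lower category). Both conventions are arbitrary but must be fixed
  for reproducibility.

## Imputation

Missing MD and hormone values are filled by **single stochastic regression
imputation**: ordinary least squares of the transformed outcome on age, BMI,
menopausal status, HT use, case status, alcohol and parity (fitted on the
measured subset), plus a normal residual draw added to every prediction.
The added error matters: a deterministic fill would shrink the imputed
values onto the regression line and attenuate downstream odds ratios, and
the test suite asserts the variance identity var(imputed) ≈ var(fitted) +
residual variance. Hormones are imputed on the log scale; MD on
logit(percent/100) — a deviation from a blanket log transform, chosen so
imputed densities respect the 0–100 bound. Case status belongs among the
predictors so imputation preserves case–control differences. The predictor
set is configuration (the motivating analysis selected predictors from
prior data without publishing the list) and every fitted model is
serialised to JSON for audit. Multiple-imputation variance combining is out
of scope by design; a measured-data sensitivity comparison plays that role.

## Model augmentation and subgroup policy

`fit_augmented_model()` fits unconditional logistic regression of case
status on the base risk score, age, and the requested biomarkers. Age is
adjusted with the same 5-year bands used everywhere else (<40, 40–44, …,
65+), entered as indicators; matching factors enter as covariates rather
than via conditional logistic regression. Hormones enter log-transformed —
consistent with the imputation scale (whether raw or log concentrations
entered the motivating AUC models is unstated; the log scale is this
package's declared choice). Hormone terms obey the subgroup policy: T, E1S
and PRL among postmenopausal non-HT users (and the pooled analysis), PRL
only among postmenopausal HT users, none among premenopausal women, where
hormone–risk associations are weak. An ER-positive restriction drops
non-ER+ cases and keeps all controls.

`fit_relative_risks()` reports exposure odds ratios with Wald CIs, either
continuous (per control SD; binary exposures per unit) or as control-based
quartiles (Q2–Q4 vs Q1).

## Discrimination

* **AUC** (`auc_concordance()`): the Mann–Whitney concordance
  P(case score > control score) + ½ P(tie), with ties counting one half by
  declared convention. Stratum variance uses the Hanley–McNeil estimator by
  default (DeLong available); for perfectly separated strata the point
  estimate is clipped away from 0/1 *inside the variance formula only*, so
  meta-analysis weights stay finite.
* **Age-adjusted AUC** (`age_adjusted_auc()`): AUCs are computed within age
  bands and combined by fixed-effect inverse-variance weighting — the
  simplest reading of "a meta-analysis of age-specific AUCs"; a logit-scale
  option exists. Because the case–control design matches on age, the
  age-adjusted AUC deliberately excludes age's own (large) contribution to
  discrimination; absolute values are therefore lower than
  population-cohort AUCs.
* **ΔAUC** (`delta_auc()`): difference of age-adjusted AUCs of two scores on
  the same subjects. Inference is by stratified paired bootstrap (cases and
  controls resampled within age bands, both scores carried together,
  default 1,000 replicates, refuse fewer than 100): the motivating analysis
  does not state its test for correlated AUCs, so the bootstrap is a design
  decision, not an inference about anyone's code.
* **NRI** (`nri()`): two-category net reclassification at a single
  absolute-risk cutoff, 2.27% — twice the general-population average 5-year
  risk (shipped as the constant `threshold_twice_average_risk`). CI from
  the asymptotic variance of the case and non-case components.
* **Cross-validation** (`cross_validate()`): 10-fold, folds stratified on
  case status × age band; the base and augmented models are refitted per
  fold and ΔAUC is evaluated on both the training and held-out folds.
  Similar train/validation changes indicate little over-fitting.

## Absolute risk

`calibrate_baseline_hazard()` apportions age-specific composite incidence
into a baseline hazard by dividing each interval's rate by the mean relative
risk of the reference subjects (the controls) in that interval — the same
recalibration as the attributable-risk `1 − AR` formulation when AR is
computed from the same distribution, but with a directly testable identity:
mean RR × baseline hazard reproduces the composite rate exactly (asserted
at 10⁻⁶; on the *probability* scale Jensen's inequality introduces an
O((hτ)² · var RR) gap ≈ 10⁻⁵, which is why the identity is asserted on the
hazard/expected-incidence scale). Empty intervals borrow the nearest
populated interval's mean RR, with a message.

`project_absolute_risk()` evaluates the Gail-type projection
\[
P = \int_a^{a+\tau} r\,h_1^*(t)\,
    \exp\!\Big(-\int_a^{t} \big(r\,h_1^*(u) + h_2(u)\big)\,du\Big)\,dt
\]
in closed form over the piecewise-constant intervals; competing mortality
\(h_2\) is off by default (whether the motivating distributional analysis
included it is unstated; the table carries a mortality column and a flag
turns it on). The closed form is verified against an adaptive-quadrature
oracle to 10⁻⁸.

`risk_distribution()` projects every reference subject's 5-year risk at a
target age (default 50), returning the non-decreasing risk-percentile curve,
the 10th–90th percentile interval, and the fraction at or above the
threshold. The plot method can truncate the y-axis for display; the
underlying data are never truncated. The shipped incidence table
(`incidence_seer_like_synthetic.csv`) is a synthetic SEER-like set of rates
for white women constructed to place twice-average 5-year risk near 2.27%;
it is a labelled stand-in, not registry data.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains generate → score → impute → augment → evaluate →
project from one YAML configuration, writing plain CSV/JSON artifacts
(dataset, coefficient table per subgroup × model × term, a discrimination
report shaped subgroup × biomarker combination with AUC ×100 and ΔAUC with
CIs, NRI, a percentile-curve CSV) plus a log that narrates per-subgroup
counts and every default in effect. Identical configuration and seed give
byte-identical outputs. A thin command-line front end
(`inst/cli/bcriskaug.R`) exposes the stages as subcommands.

Default problem sizes were chosen so a complete demo run takes a few
seconds and the full verification suite a few minutes on one CPU: demo
population 12,000 (≈1,400 matched cases); parameter-recovery checks at
3,000 cases / 6,000 controls × 50 replicates; directional checks at ≈1,000
cases / 2,000 controls × 50 replicates; bootstrap 200 replicates in the
demo and 1,000 by default in `delta_auc()`. These sizes are statements
about the precision needed by each check, not about the method's limits.

## Known limitations

* Independence of PRS, MD and hormones in the generator overstates their
  joint information slightly relative to modestly correlated real markers.
* The simplified Rosner–Colditz score is a structural stand-in: correct
  functional skeleton, illustrative coefficients.
* Calibration assessment (Hosmer–Lemeshow, expected/observed ratios) and
  external validation are explicitly out of scope, as is any claim of
  transportability across racial/ethnic groups.
* Absolute-risk projection uses the control exposure distribution as the
  population distribution; with many risk factors this approximation
  degrades, which is why the projection is exercised with the simpler Gail
  base model only.
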