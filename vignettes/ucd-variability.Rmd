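---
title: "Within-person variability and determinants of urinary cadmium: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-person variability and determinants of urinary cadmium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdvar)
```

## The scientific problem

Urinary cadmium (U-Cd) from a 24-hr collection is the standard biomarker
of long-term cadmium body burden, but repeat collections from the same
woman taken months apart disagree substantially. That disagreement has two
consequences this package quantifies. First, a reliability question: how
much of the variance in ln U-Cd is stable between-person signal versus
within-person noise? Second, an epidemiological one: if a case–control
study characterises exposure with a single measurement, how far is its
odds ratio attenuated toward the null?

The package also fits determinants models: which characteristics —
urinary creatinine, age, smoking dose, parity, alcohol, body size, diet
and neighbourhood sources — predict U-Cd, and how much of its variance do
they explain?

## The variance-components model

For participant $i$ and collection $j$,

$$\ln \mathrm{UCd}_{ij} = \mu + b_i + e_{ij}, \qquad
b_i \sim N(0, \sigma^2_b),\; e_{ij} \sim N(0, \sigma^2_w),$$

estimated by REML through `fit_variance_components()`. The intraclass
correlation $\mathrm{ICC} = \sigma^2_b/(\sigma^2_b + \sigma^2_w)$ is the
proportion of variance that reflects stable exposure; the variance ratio
$\lambda = \sigma^2_w/\sigma^2_b$ drives measurement-error attenuation.
REML rather than ML because it is unbiased for the components at modest
numbers of repeat pairs and coincides with the one-way ANOVA
method-of-moments estimator on balanced data with interior estimates —
which is exactly the independent oracle the test suite uses. Negative
component estimates are truncated at zero by the optimizer's boundary,
so $\lambda$ is infinite when no between-person variance remains.
Participants with a single collection are retained in the fit; they
inform the total variance, while pairs identify the split.

With the exposure measured as the mean of $n$ replicates, the expected
log odds ratio in a logistic model is

$$\beta_E = \frac{\beta_T}{1 + \lambda/n}, \qquad
\text{\% bias} = \frac{\beta_E - \beta_T}{\beta_T} \times 100
= -\frac{100\,\lambda}{n + \lambda}.$$

`attenuation()` evaluates this closed form; `simulate_case_control()` is
its Monte-Carlo twin, drawing a standardized true exposure, assigning
case status from a logistic model with slope $\ln(\mathrm{OR})$ per SD,
adding within-person noise, and refitting. For reporting, $\lambda$ is
rounded to one decimal before the multi-sample table is computed: the
reliability analysis quotes its variance ratio at that precision, and
a ratio of 1.0 yields the familiar 50/33/20% rows for 1/2/4 samples
(an unrounded ratio of 1.023 would print 34% at $n = 2$).

One numerical subtlety, visible in the tests: the closed form is the
linear regression-dilution limit. A logistic model marginalized over
residual exposure noise shrinks slightly further (non-collapsibility),
about 2% of the slope at $\lambda = 1$, $n = 1$. The simulation
therefore sits a hair below $\exp(\beta_T/2) = 1.414$ — near 1.39 — and
both agree with the reference value 1.4 at its printed one-decimal
precision.

## The synthetic cohort

No individual-level data ship with the package; `generate_cohort()` and
friends build a synthetic study with the statistical structure the
analysis assumes, and every acceptance-style check runs against it.

* **Size and design.** 296 women, of whom `round(296 × 141/296) = 141`
  provide a second 24-hr collection 3, 6 or 9 months later (uniform over
  the three intervals; reliability is assumed stable over this span, with
  a configurable drift term available).
* **Biomarker.** ln U-Cd is the two-component Gaussian model above with
  $\sigma^2_b = 0.216$, $\sigma^2_w = 0.221$ and
  $\mu = \ln 0.27$, i.e. GM 0.27 µg/L, GSD
  $\exp\sqrt{0.437} \approx 1.9$, ICC ≈ 0.49. Log-normality is assumed
  as the family consistent with GM/GSD reporting of a skewed biomarker.
* **Covariate effects inside the components.** Default slopes
  (`default_covariate_effects()`) make creatinine explain roughly a
  quarter of total variance and age/smoking/parity/alcohol a further
  sixth, echoing the cumulative $R^2$ pattern of determinants models in
  this population. Person-level signal variance is subtracted from the
  between-person intercept variance, and the occasion-level creatinine
  signal from the within-person noise, so the *marginal* components a
  variance-components model sees stay at the configured values whatever
  effects are switched on. With `covariate_effects = list()` the
  generator is exactly the unconditional two-component model.
* **Covariates.** Age is truncated normal (55, 12) on [31, 84]; BMI
  truncated normal (27, 5.9); parity, smoking status, alcohol category
  and hormone-use indicators are categorical draws matching the cohort's
  marginal percentages; passive-smoke intensity-years for never smokers
  follow a gamma with mean 30 and SD ≈ 35. Only the marginals matter
  downstream, so no covariate correlation structure is generated.
* **Geography.** A 40 × 40 km planar region in km coordinates — at
  buffer radii of 0.3–5 km the planar approximation is exact for all
  practical purposes and keeps the module dependency-light. Roads
  cluster so about a third of residences see no major road within 300 m;
  facilities are sparse and heavy-tailed (most residences have zero
  emitters within 5 km); tract air concentrations lie in 0.05–0.65
  ng/m³.
* **Diet.** Each woman's target cadmium intake is gamma with mean 11 and
  SD 4.2 µg/day (quartiles ≈ 8 and 13.5). Item frequencies are
  constructed to hit both that target and her energy intake exactly, by
  blending energy-rich and cadmium-rich item weights in closed form, so
  the downstream scored intake reproduces the configured distribution
  while implied energy stays plausible. Small configured fractions
  return no FFQ or mis-scale their reporting into the implausible-energy
  exclusion zone.
* **LOD.** Generation uses the assay's 0.1 µg/L limit; values below it
  are flagged, not altered. Because the log-normal tail is heavier than
  the assay's real floor, the generator produces a few percent
  non-detects — more than the handful seen in practice — which the
  substitution step then compresses onto a single value. For
  parameter-recovery simulations of the ICC the fits therefore use the
  uncensored log values; censoring treatment is a preprocessing concern,
  not part of the estimator under study.

What the generator does **not** emulate: assay drift or batch effects,
real street networks, correlated covariates, iron status or renal
function (both known to influence U-Cd but absent here), or seasonal
structure in the repeat interval. Passing tests show the estimators recover the
generating model; they cannot certify behaviour under violations the
generator never produces.

## Biomarker preprocessing conventions

* Non-detects are substituted by LOD/√2 = 0.0707 µg/L. Values exactly at
  the LOD count as detects: substitution applies strictly below.
  Substitution is idempotent. Multiple imputation or censored-likelihood
  approaches are deliberately out of scope.
* Creatinine adjustment divides µg/L by g/L; daily output multiplies by
  24-hr volume. Both are exact, so the geometric-mean identities
  GM(x/y) = GM(x)/GM(y) and GM(xy) = GM(x)·GM(y) hold to machine
  precision and are tested as properties.
* GSD uses the sample (n−1) standard deviation of natural logs, the
  conventional choice for biomarker tables.

## Exposure metrics

* **Traffic density**: for each segment, AADT × the exact length of its
  intersection with the 300-m disc (line–circle clipping via the
  quadratic, not all-or-nothing inclusion), summed and divided by
  $\pi r^2 = 0.2827$ km². The metric is invariant under rigid motions
  and linear in every AADT — both tested.
* **Industrial emissions**: annual kg summed over all facilities within
  5 km (Euclidean). Summation over facilities, rather than
  nearest-facility-only, is the implemented convention; the alternative
  changes only the categorical displays.
* **Ambient air**: exact tract lookup; no dispersion modelling.
* **Diet**: frequency × portion weight × cadmium per medium serving,
  with portion weights small/medium/large = 0.5/1/1.5 of the medium
  serving — a symmetric convention, configurable, since the instrument
  defines none. The kcal analogue of the same weighted sum screens
  implausible reporting (< 600 or > 5,000 kcal/day → missing, with the
  reason recorded).
* **Body surface area**: the Du Bois form
  $0.007184\, w^{0.425} h^{0.725}$. A height exponent of 0.275
  circulates in the applied literature but yields BSA ≈ 0.2 m² for a
  typical adult, an order of magnitude off; the exponent is an argument
  (`height_exp`) defaulting to 0.725, which reproduces the expected
  ≈ 1.7–1.8 m², and the discrepancy is surfaced rather than silently
  resolved.

## Determinants models

`fit_mixed()` fits ln U-Cd on ordered fixed effects with a random
intercept per participant. Creatinine enters as a covariate (per
0.1 g/L) with *unadjusted* ln U-Cd as the outcome, rather than dividing
it out, so other effects are interpretable net of urine dilution.
Coefficients are reported as percent change per unit,
$(e^\beta - 1) \times 100$, with Wald 95% intervals transformed the same
way; the inverse identity $\ln(1 + \mathrm{pct}/100) = \beta$ is tested
to 1e−12. Fixed-effect p-values are Wald normal approximations — at
hundreds of samples the difference from a degrees-of-freedom-corrected
test is negligible and the backward-elimination threshold of 0.1 is not
sharp. When no participant has a repeat, the fit degrades to OLS with
zero between-person variance (tested against `lm`).

Screening mirrors the two-stage practice: Kruskal–Wallis across
categories of the raw (skewed) biomarker, then an age-adjusted linear
trend on ln U-Cd for continuous/ordinal predictors (age's own trend is
unadjusted, and unordered binary variables get no trend test). Candidate
terms passing either screen at p < 0.2 feed backward elimination, which
removes the worst non-forced term per iteration until all removable
p < 0.1; the dietary and environmental exposure estimates are forced —
retained regardless of p — and ties break toward the later term in the
specified order. Elimination terminates in at most one iteration per
removable term.

$R^2$ for a mixed model has no single definition; the package reports
the proportional reduction in total residual variance
$(\sigma^2_b + \sigma^2_w)$ against the intercept-only model,
cumulatively as each term enters in its specified order, with the
squared observed–fitted correlation alongside for transparency. Under
REML the cumulative sequence can dip by O(1/n) when a null term enters
(the df correction); monotonicity is asserted within that allowance.
Ordinal alcohol (0, 1, 2 for none, < 20, ≥ 20 g/day) enters as a single
slope. Traffic and industrial emissions enter per 10-fold change —
log₁₀ with zeros mapped to half the smallest positive value
(configurable; the scale is undefined at zero and any choice is a
convention); air enters per 0.1 ng/m³. Age is rescaled so the youngest
participant is zero, which provably moves only the intercept — tested
by refitting under both codings.

Cross-validation is 10-fold over *participants*, never samples, so a
woman's two collections share a fold; per-fold refits report coefficient
stability and the $R^2$ range. `quit_decay()` adds the questionnaire
offset (+3 years, since smoking history predates collection by three
years) before regressing ln U-Cd on years since cessation among former
smokers.

## Problem sizes and seeds

Package simulations run at the scale of the design they emulate: 296
women, 141 repeat pairs, 20-item FFQ. Parameter-recovery tests use 200
replicates (ICC and case–control attenuation; Monte-Carlo SEs ≈ 0.005),
method-of-moments oracles run at 3,000–50,000 cheap replicates, and the
moment-recovery check uses 5,000 balanced pairs. All randomness descends
from one root seed through fixed per-stage offsets, so every stage is
independently reproducible and two runs with one seed are identical to
the byte.

## Known limitations

The generator's marginals are independent across covariates, so
collinearity-driven elimination behaviour is milder than in real data.
The creatinine effect is linear on the natural scale while creatinine
itself is log-normal; the implied creatinine-adjusted ICC comes out
*higher* than the unadjusted one, whereas real repeat-sample studies
typically find creatinine adjustment lowers the ICC. Attenuation formulas assume classical, nondifferential
error on the log scale. None of the geographic layers carry time:
exposure metrics describe the residence at collection, not history.
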