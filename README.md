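# cdvar — within-person variability and determinants of urinary cadmium

Urinary cadmium (U-Cd) measured in a 24-hr collection is the workhorse
biomarker of long-term cadmium body burden in environmental
epidemiology. Repeat collections from the same person months apart,
however, disagree enough that a single measurement misclassifies
exposure — and misclassification attenuates health-effect estimates
toward the null. `cdvar` is an R package for epidemiologists and
exposure scientists who want to quantify that problem end to end:

* **Reliability.** A REML random-intercept model on ln U-Cd splits the
  variance into between-person (σ²_b) and within-person (σ²_w)
  components and reports the intraclass correlation
  ICC = σ²_b/(σ²_b + σ²_w) and variance ratio λ = σ²_w/σ²_b.
* **Attenuation.** With exposure measured as the mean of *n* replicates,
  the expected logistic coefficient is β_E = β_T/(1 + λ/n), and the
  percent attenuation bias is −100·λ/(n + λ). Both the closed form
  (`attenuation()`) and a full case–control simulation twin
  (`simulate_case_control()`) are provided.
* **Determinants.** Kruskal–Wallis and age-adjusted trend screening,
  random-intercept mixed models with percent-change reporting
  ((e^β − 1) × 100), backward elimination with forced dietary and
  environmental terms, cumulative R², participant-level 10-fold
  cross-validation, and the post-cessation decay of U-Cd among former
  smokers.
* **Exposure metrics.** Traffic density by exact line–circle clipping of
  road segments against a 300-m residential buffer (area 0.28 km²),
  industrial cadmium emissions within 5 km, tract-linked ambient air,
  FFQ-scored dietary cadmium with energy-plausibility exclusions, and
  derived covariates (BSA, BMI, pack-years, intensity-years).
* **A synthetic cohort generator**, so everything above is testable and
  reproducible without any individual-level data: 296 women, 141 with a
  repeat 24-hr sample 3–9 months later, log-normal U-Cd with
  σ²_b = 0.216 and σ²_w = 0.221, and planar geographic layers.

## Worked example

```r
library(cdvar)

cfg       <- cohort_config(seed = 1)
cohort    <- generate_cohort(cfg)
samples   <- generate_samples(cohort, cfg)
processed <- process_samples(samples, lod = cfg$lod)

gm_gsd(processed$cadmium_sub[processed$occasion == 1])
#> GM 0.28 ug/L (GSD 1.9)

(vc <- fit_variance_components(processed))
#> Within/between-person variance components (REML)
#>   outcome: log_cd;  437 samples from 296 participants (141 with repeats)
#>   sigma2_between = 0.202
#>   sigma2_within  = 0.226
#>   ICC            = 0.472
#>   lambda (w/b)   = 1.117

attenuation(round(vc$lambda, 1), c(1, 2, 4))
#> Expected attenuation of a case-control odds ratio
#>  n true_OR expected_OR attenuation_pct
#>  1       2        1.39              52
#>  2       2        1.56              35
#>  4       2        1.72              22
```

Read: in this synthetic realization, less than half of the variance in
ln U-Cd is stable between-person signal (ICC 0.47), so a case–control
study using one 24-hr sample would expect to observe an odds ratio of
about 1.4 where the true odds ratio is 2.0; averaging two or four
samples per person only partly repairs the bias. The determinants side
runs the same way from one configuration:

```r
res <- run_pipeline(run_config(seed = 7), "run7")
writeLines(res$report)   # ICC, lambda, attenuation, model R2, CV summary
```

which also writes every intermediate artifact (`participants.csv`,
`samples.csv`, `roads.geojson`, `reliability.json`, `model_fit.json`,
`screening.csv`, `cv.json`, `report.txt`, …) into `run7/`. A thin CLI
wrapper with `run`, `simulate` and `reliability` subcommands is
installed at `inst/scripts/cdvar`.

## Design notes

The methods vignette (`vignettes/ucd-variability.Rmd`) documents the
models and their assumptions, what the synthetic generator does and does
not emulate, numerical conventions (LOD substitution at LOD/√2, the
Du Bois BSA exponent, log₁₀ scaling of zero-inflated exposure metrics,
REML vs the ANOVA oracle, non-collapsibility in the logistic
simulation), and known limitations.
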