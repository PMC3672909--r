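# shared fixtures and independent oracles

# one-way ANOVA method-of-moments variance components on balanced pairs;
# independent of the REML path under test
mom_vc_pairs <- function(x1, x2) {
  k <- length(x1)
  x <- cbind(x1, x2)
  m <- rowMeans(x)
  msw <- sum((x - m)^2) / k
  msb <- 2 * sum((m - mean(m))^2) / (k - 1)
  list(s2w = msw, s2b = max((msb - msw) / 2, 0))
}

# expected mean of the ICC estimator at k balanced pairs, by brute-force
# method-of-moments simulation (the oracle never touches lme4)
mom_icc_mean <- function(k, s2b, s2w, reps, seed) {
  set.seed(seed)
  icc <- numeric(reps)
  for (r in seq_len(reps)) {
    b <- rnorm(k, 0, sqrt(s2b))
    x1 <- b + rnorm(k, 0, sqrt(s2w))
    x2 <- b + rnorm(k, 0, sqrt(s2w))
    vc <- mom_vc_pairs(x1, x2)
    icc[r] <- vc$s2b / (vc$s2b + vc$s2w)
  }
  list(mean = mean(icc), se = sd(icc) / sqrt(reps))
}

# default synthetic study, built once and reused across test files
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(seed = 7)
      cohort <- generate_cohort(cfg)
      samples <- generate_samples(cohort, cfg)
      geo <- generate_geography(cfg)
      ffq <- generate_ffq(cohort, contaminant_table(), cfg)
      processed <- process_samples(samples, cfg$lod)
      exposures <- build_exposures(cohort, geo, ffq, contaminant_table())
      cache <<- list(cfg = cfg, cohort = cohort, samples = samples,
                     geo = geo, ffq = ffq, processed = processed,
                     exposures = exposures,
                     model_data = prepare_model_data(processed, cohort,
                                                     exposures))
    }
    cache
  }
})

# long data with known fixed effects for determinants tests:
# log_cd = mu + b_creat*(creatinine - 0.71) + slopes %*% covariates
#          + person intercept + noise
make_determinants_data <- function(n = 400, repeat_fraction = 1,
                                   b_creat = 1.0,
                                   slopes = c(age0 = 0.014),
                                   s2b = 0.05, s2w = 0.05, seed = 1) {
  set.seed(seed)
  n2 <- round(n * repeat_fraction)
  idx <- c(seq_len(n), seq_len(n2))
  covs <- data.frame(age0 = runif(n, 0, 50),
                     pack_years = rexp(n, 1 / 4),
                     parity = sample(0:4, n, TRUE),
                     noise_cov = rnorm(n))
  creat <- rlnorm(length(idx), log(0.71), 0.4)
  eta <- rep(0, n)
  for (v in names(slopes)) eta <- eta + slopes[[v]] * covs[[v]]
  b <- rnorm(n, 0, sqrt(s2b))
  y <- -1.3 + eta[idx] + b_creat * (creat - 0.71) + b[idx] +
    rnorm(length(idx), 0, sqrt(s2w))
  d <- data.frame(participant_id = sprintf("P%04d", idx),
                  occasion = c(rep(1L, n), rep(2L, n2)),
                  log_cd = y, creatinine = creat,
                  creatinine_01 = creat / 0.1)
  cbind(d, covs[idx, , drop = FALSE])
}
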