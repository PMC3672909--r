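test_that("Kruskal-Wallis wrapper matches the rank-sum formula", {
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1), no ties
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7)
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1)
  expect_identical(kruskal_wallis(rep(4, 6), rep(c("a", "b"), 3))$H, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two non-empty")
})

test_that("null labels give uniform Kruskal-Wallis p-values", {
  set.seed(51)
  y <- rlnorm(60, -1.3, 0.6)
  p <- replicate(300, kruskal_wallis(y, sample(rep(1:3, 20)))$p)
  expect_true(abs(mean(p < 0.05) - 0.05) < 0.04)
  expect_true(abs(mean(p) - 0.5) < 0.06)
})

test_that("age-adjusted trend test is calibrated and recovers slopes", {
  set.seed(52)
  # type-I error at the nominal level under a zero predictor effect
  rej <- 0; reps <- 500
  for (r in seq_len(reps)) {
    age <- runif(150, 31, 84)
    x <- rnorm(150)
    y <- -1.3 + 0.014 * age + rnorm(150, 0, 0.5)
    rej <- rej + (trend_test(y, x, age)$p < 0.05)
  }
  expect_true(rej / reps > 0.025 && rej / reps < 0.08)
  # slope recovery: true effect inside the 95% CI in >= 90% of reps
  cover <- 0; reps2 <- 200
  for (r in seq_len(reps2)) {
    age <- runif(296, 31, 84)
    x <- rnorm(296, 0, 10)
    y <- -1.3 + 0.014 * age + 0.01 * x + rnorm(296, 0, 0.5)
    tt <- trend_test(y, x, age)
    cover <- cover + (abs(tt$slope - 0.01) < 1.96 * tt$se)
  }
  expect_true(cover / reps2 >= 0.9)
  expect_error(trend_test(rnorm(10), rep(1, 10), runif(10)), "distinct")
  age <- runif(50, 31, 84)
  expect_error(trend_test(rnorm(50), age, age), "collinear")
})

test_that("mixed model recovers a known creatinine effect as ~15% per 0.1 g/L", {
  cfg <- cohort_config(n_participants = 3000, repeat_fraction = 1,
                       sigma2_within = 0.4,
                       covariate_effects = list(creatinine = 1.398),
                       seed = 61)
  co <- generate_cohort(cfg)
  pr <- process_samples(generate_samples(co, cfg))
  pr$creatinine_01 <- pr$creatinine / 0.1
  fit <- fit_mixed(pr, "creatinine_01", compute_r2 = FALSE)
  row <- fit$coefficients[fit$coefficients$term == "creatinine_01", ]
  expect_equal(row$beta, 0.1398, tolerance = 0.05)
  expect_equal(row$pct_change, 15, tolerance = 0.05)
  expect_true(row$pct_lo < 15 && row$pct_hi > 15)
})

test_that("percent changes invert exactly and Wald CIs transform with them", {
  d <- make_determinants_data(n = 150, seed = 62)
  fit <- fit_mixed(d, c("creatinine_01", "age0"), compute_r2 = FALSE)
  cf <- fit$coefficients
  expect_equal(log(1 + cf$pct_change / 100), cf$beta, tolerance = 1e-12)
  expect_equal(log(1 + cf$pct_lo / 100), cf$beta - 1.96 * cf$se,
               tolerance = 1e-12)
})

test_that("all-singleton data reduce the mixed fit to least squares", {
  d <- make_determinants_data(n = 120, repeat_fraction = 0, seed = 63)
  fit <- fit_mixed(d, c("creatinine_01", "age0"), compute_r2 = FALSE)
  expect_false(fit$mixed)
  expect_identical(fit$sigma2_between, 0)
  ols <- lm(log_cd ~ creatinine_01 + age0, data = d)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the term named", {
  d <- make_determinants_data(n = 80, seed = 64)
  d$age_copy <- d$age0
  expect_error(fit_mixed(d, c("age0", "age_copy")), "age_copy")
  expect_error(fit_mixed(d, "absent_col"), "lack columns")
})

test_that("backward elimination keeps forced terms and strong effects", {
  d <- make_determinants_data(
    n = 500, b_creat = 1.0,
    slopes = c(age0 = 0.02, pack_years = 0.03), seed = 65)
  d$dietary_cd <- rnorm(nrow(d), 11, 4)     # zero-effect forced exposure
  final <- backward_eliminate(d, c("creatinine_01", "age0", "pack_years",
                                   "dietary_cd", "noise_cov"),
                              forced = "dietary_cd")
  expect_true("dietary_cd" %in% final$terms)
  expect_true(all(c("creatinine_01", "age0", "pack_years") %in%
                    final$terms))
  expect_false("noise_cov" %in% final$terms)
  expect_error(backward_eliminate(d, "age0", forced = "dietary_cd"),
               "subset")
})

test_that("a pure-noise covariate is eliminated at the expected rate", {
  # under the null its p-value is uniform, so removal happens with
  # probability 0.9 at the 0.1 threshold; demand >= 80% over 25 reps
  removed <- 0
  for (r in 1:25) {
    d <- make_determinants_data(n = 250, slopes = c(age0 = 0.02),
                                seed = 700 + r)
    fin <- backward_eliminate(d, c("creatinine_01", "age0", "noise_cov"),
                              forced = character(0))
    removed <- removed + !("noise_cov" %in% fin$terms)
  }
  expect_true(removed >= 20)
})

test_that("elimination threshold 1 keeps the full model", {
  d <- make_determinants_data(n = 150, seed = 66)
  fin <- backward_eliminate(d, c("creatinine_01", "age0", "noise_cov"),
                            threshold = 1)
  expect_identical(fin$terms, c("creatinine_01", "age0", "noise_cov"))
})

test_that("age rescaling changes only the intercept", {
  d <- make_determinants_data(n = 200, seed = 67)
  d$age <- d$age0 + 31
  f0 <- fit_mixed(d, c("creatinine_01", "age0"))
  f1 <- fit_mixed(d, c("creatinine_01", "age"))
  b0 <- coef(f0); b1 <- coef(f1)
  expect_equal(b0[["age0"]], b1[["age"]], tolerance = 1e-8)
  expect_equal(b0[["creatinine_01"]], b1[["creatinine_01"]],
               tolerance = 1e-8)
  expect_equal(f0$r2, f1$r2, tolerance = 1e-8)
  expect_equal(unname(f0$r2_cumulative), unname(f1$r2_cumulative),
               tolerance = 1e-8)
})

test_that("cumulative R2 starts at zero, never decreases, and nests", {
  d <- make_determinants_data(n = 300,
                              slopes = c(age0 = 0.02, pack_years = 0.02),
                              seed = 68)
  terms <- c("creatinine_01", "age0", "pack_years", "noise_cov")
  fit <- fit_mixed(d, terms)
  r2 <- cumulative_r2(fit)
  # REML's degrees-of-freedom correction can nudge the total variance up
  # by O(1/n) when a null term enters; monotone within that allowance
  expect_true(all(diff(c(0, r2)) > -2e-3))
  expect_equal(unname(r2[length(r2)]), fit$r2, tolerance = 1e-10)
  null_fit <- fit_mixed(d, character(0))
  expect_equal(unname(cumulative_r2(null_fit)), 0)
  seq_fits <- lapply(0:2, function(k)
    fit_mixed(d, terms[seq_len(k)], compute_r2 = FALSE))
  r2_seq <- cumulative_r2(seq_fits)
  expect_equal(r2_seq[1], 0, tolerance = 1e-10)
  expect_equal(r2_seq[-1], unname(r2[1:2]), tolerance = 1e-6)
  expect_error(cumulative_r2(list(seq_fits[[3]], seq_fits[[1]])),
               "not nested")
  # creatinine dominates: its share of explained variance is the largest
  expect_true(r2[1] > max(diff(r2)))
})

test_that("alcohol enters as a single ordinal slope", {
  s <- default_study()
  fit <- fit_mixed(s$model_data, c("creatinine_01", "alcohol_score"),
                   compute_r2 = FALSE)
  expect_identical(sum(grepl("alcohol", fit$coefficients$term)), 1L)
})

test_that("participant-level 10-fold cross-validation is stable on strong signal", {
  d <- make_determinants_data(n = 600, b_creat = 1.0,
                              slopes = c(age0 = 0.02), seed = 69)
  cv <- crossvalidate_10fold(d, c("creatinine_01", "age0"), seed = 5)
  expect_identical(nrow(cv$beta), 10L)
  # folds partition participants, never split a person's samples
  expect_identical(sort(unique(names(cv$fold))), sort(unique(d$participant_id)))
  expect_true(cv$max_rel_dev < 0.10)
  expect_true(diff(cv$r2_range) < 0.06)
  cv2 <- crossvalidate_10fold(d, c("creatinine_01", "age0"), seed = 5)
  expect_identical(cv$beta, cv2$beta)
  tiny <- d[d$participant_id %in% unique(d$participant_id)[1:5], ]
  expect_error(crossvalidate_10fold(tiny, "age0"), "fewer than")
})

test_that("quit-decay applies the questionnaire offset and recovers decay", {
  set.seed(71)
  n <- 70
  ysq <- runif(n, 1, 30)
  idx <- c(1:n, 1:28)
  y <- -1.2 + log(0.985) * (ysq[idx] + 3) +
    rnorm(n, 0, 0.2)[idx] + rnorm(length(idx), 0, 0.25)
  d <- data.frame(participant_id = sprintf("F%02d", idx),
                  log_cd = y, years_since_quit = ysq[idx])
  qd <- quit_decay(d, adjust = character(0))
  expect_equal(qd$n_participants, 70)
  expect_true(qd$ci[1] < -1.5 && qd$ci[2] > -1.5)
  expect_equal(qd$pct_per_year, -1.5, tolerance = 0.8)
  # offset rule: +3 years reproduces the manual fit on shifted data
  d2 <- d; d2$years_since_quit <- d2$years_since_quit + 3
  qd0 <- quit_decay(d2, adjust = character(0), offset_years = 0)
  expect_equal(qd$pct_per_year, qd0$pct_per_year, tolerance = 1e-10)
  # zero injected decay: CI covers 0
  d$log_cd <- -1.2 + rnorm(nrow(d), 0, 0.3)
  qd_null <- quit_decay(d, adjust = character(0))
  expect_true(qd_null$ci[1] < 0 && qd_null$ci[2] > 0)
  expect_error(quit_decay(d[0, ], adjust = character(0)), "no former")
})

test_that("screening table reports GMs and both p-values per variable", {
  s <- default_study()
  first <- s$model_data[s$model_data$occasion == 1, ]
  scr <- screen_predictors(first, "cadmium_sub",
                           list(age = NULL, alcohol_category = NULL,
                                oc_ever = NULL))
  expect_identical(scr$variable, c("age", "alcohol_category", "oc_ever"))
  expect_true(all(scr$kw_p >= 0 & scr$kw_p <= 1))
  expect_true(is.na(scr$trend_p[scr$variable == "oc_ever"]))
  expect_false(anyNA(scr$trend_p[scr$variable != "oc_ever"]))
})

test_that("log10 scaling maps zeros to half the smallest positive value", {
  x <- c(0, 10, 1000)
  expect_equal(scale_log10(x), log10(c(5, 10, 1000)))
  expect_equal(scale_log10(x, offset = 1), log10(c(1, 10, 1000)))
  expect_error(scale_log10(c(-1, 2)), "non-negative")
})
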