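#' Kruskal-Wallis comparison of a skewed biomarker across categories
#'
#' Rank-based one-way comparison with midrank tie handling and the
#' chi-square reference on k - 1 degrees of freedom, as appropriate for a
#' right-skewed biomarker like U-Cd.
#'
#' @param values numeric outcome.
#' @param groups category labels (>= 2 non-empty groups).
#' @return list with \code{H}, \code{p} and \code{df}.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (length(unique(values)) == 1)   # fully tied: no evidence against null
    return(list(H = 0, p = 1, df = nlevels(g) - 1))
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Age-adjusted linear trend test on log U-Cd
#'
#' Regresses ln U-Cd on a continuous or ordinal-scored predictor plus age
#' and returns the predictor's slope with its Wald p-value. Constant
#' predictors and predictors collinear with age are rejected (the fit
#' would be degenerate).
#'
#' @param log_cd ln-transformed biomarker.
#' @param predictor numeric predictor or ordinal score.
#' @param age age in years, adjusted for as a covariate.
#' @return list with \code{slope}, \code{se} and \code{p}.
#' @export
trend_test <- function(log_cd, predictor, age) {
  if (length(unique(predictor[!is.na(predictor)])) < 2)
    stop("predictor must take at least two distinct values", call. = FALSE)
  fit <- lm(log_cd ~ predictor + age)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)) || !"predictor" %in% rownames(cf))
    stop("degenerate fit: predictor is collinear with age", call. = FALSE)
  list(slope = cf["predictor", "Estimate"],
       se = cf["predictor", "Std. Error"],
       p = cf["predictor", "Pr(>|t|)"])
}

#' Screen candidate determinants of U-Cd
#'
#' For each candidate variable, reports geometric means of the biomarker
#' by category, the Kruskal-Wallis p-value across categories, and the
#' age-adjusted linear-trend p-value (on the continuous or ordinal form;
#' skipped for unordered binary variables). Intended for the first sample
#' of each participant.
#'
#' @param data one row per participant with the biomarker and candidates.
#' @param outcome name of the positive biomarker column (e.g.
#'   \code{"cadmium_sub"} or \code{"cd_per_creatinine"}).
#' @param variables named list: each element \code{NULL} (categorise a
#'   numeric variable at its quartiles; use it continuously for trend) or
#'   a list with optional \code{breaks} (cut points for display) and
#'   \code{trend} (\code{FALSE} to skip the trend test).
#' @param age_col age column used for trend adjustment.
#' @return data.frame: \code{variable}, \code{n}, \code{categories},
#'   \code{gm_by_category}, \code{kw_p}, \code{trend_p}.
#' @export
screen_predictors <- function(data, outcome, variables, age_col = "age") {
  rows <- lapply(names(variables), function(v) {
    spec <- variables[[v]]
    x <- data[[v]]
    y <- data[[outcome]]
    ok <- !is.na(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]; age <- data[[age_col]][ok]
    if (is.numeric(x)) {
      brk <- if (!is.null(spec$breaks)) spec$breaks else
        unique(quantile(x, c(0, 0.25, 0.5, 0.75, 1)))
      cats <- cut(x, breaks = brk, include.lowest = TRUE)
      trend_x <- x
    } else {
      cats <- factor(x)
      trend_x <- as.numeric(cats) - 1
    }
    cats <- droplevels(cats)
    gm <- vapply(split(y, cats), function(s) gm_gsd(s)$gm, numeric(1))
    kw <- if (nlevels(cats) >= 2) kruskal_wallis(y, cats)
    else list(p = NA_real_)   # degenerate split (e.g. all zeros)
    do_trend <- !isFALSE(spec$trend) &&
      !(is.logical(data[[v]]) || (!is.numeric(data[[v]]) &&
                                    nlevels(cats) == 2))
    tp <- if (!do_trend) NA_real_
    else if (v == age_col) {       # age's own trend needs no age adjustment
      s <- summary(lm(log(y) ~ trend_x))$coefficients
      s["trend_x", "Pr(>|t|)"]
    } else {
      tryCatch(trend_test(log(y), trend_x, age)$p,
               error = function(e) NA_real_)
    }
    data.frame(variable = v, n = length(y),
               categories = paste(levels(cats), collapse = "; "),
               gm_by_category = paste(sprintf("%.2f", gm), collapse = "; "),
               kw_p = kw$p, trend_p = tp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# total residual variance (between + within) of a nested term set,
# plus the fitted model; falls back to OLS when nobody has a repeat
fit_terms <- function(data, terms, outcome, id) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  g <- factor(data[[id]])
  has_repeats <- any(table(g) >= 2)
  if (has_repeats) {
    f <- as.formula(paste(outcome, "~", rhs, "+ (1 |", id, ")"))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(f, data = data, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.nRE = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == id]
    s2w <- vc$vcov[vc$grp == "Residual"]
  } else {
    f <- as.formula(paste(outcome, "~", rhs))
    fit <- lm(f, data = data)
    s2b <- 0
    s2w <- summary(fit)$sigma^2
  }
  list(fit = fit, s2b = s2b, s2w = s2w, mixed = has_repeats)
}

#' Random-intercept mixed model for determinants of log U-Cd
#'
#' Fits ln U-Cd on an ordered set of fixed-effect terms with a random
#' intercept per participant (REML), so that the correlation between
#' repeat samples from the same woman is respected. Creatinine belongs
#' among the covariates -- modelling unadjusted ln U-Cd with creatinine
#' as a predictor rather than dividing it out keeps the other effects
#' interpretable net of urine dilution. Coefficients are reported as
#' percent change per unit, (exp(beta) - 1) x 100, with Wald 95\%
#' intervals transformed the same way; the cumulative R-squared column
#' gives, for each term added in order, the proportional reduction in
#' total residual variance (between + within) relative to the
#' intercept-only model. When no participant has a repeat sample the
#' model degenerates gracefully to ordinary least squares with zero
#' between-person variance.
#'
#' @param data long data.frame: one row per sample, person-level
#'   covariates repeated across rows.
#' @param terms character vector of fixed-effect column names, in the
#'   order they should enter (used for the cumulative R-squared).
#' @param outcome log-scale outcome column; default \code{"log_cd"}.
#' @param id participant identifier column.
#' @param compute_r2 compute the cumulative R-squared sequence (refits
#'   one nested model per term).
#' @return object of class \code{cd_mixed}; see
#'   \code{\link{print.cd_mixed}}, \code{coef}, \code{predict},
#'   \code{residuals}.
#' @export
fit_mixed <- function(data, terms, outcome = "log_cd",
                      id = "participant_id", compute_r2 = TRUE) {
  stopifnot(length(terms) >= 0)
  cols <- c(outcome, id, terms)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  data <- data[complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  if (!nrow(data)) stop("no complete cases", call. = FALSE)

  if (length(terms)) {
    X <- model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))),
                      data)
    q <- qr(X)
    if (q$rank < ncol(X)) {
      bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
      stop("rank-deficient design; offending term(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  full <- fit_terms(data, terms, outcome, id)
  cf <- if (full$mixed) {
    s <- summary(full$fit)$coefficients
    data.frame(term = rownames(s), beta = s[, "Estimate"],
               se = s[, "Std. Error"], stringsAsFactors = FALSE)
  } else {
    s <- summary(full$fit)$coefficients
    data.frame(term = rownames(s), beta = s[, "Estimate"],
               se = s[, "Std. Error"], stringsAsFactors = FALSE)
  }
  cf$z <- cf$beta / cf$se
  cf$p <- 2 * pnorm(-abs(cf$z))
  cf$pct_change <- (exp(cf$beta) - 1) * 100
  cf$pct_lo <- (exp(cf$beta - 1.96 * cf$se) - 1) * 100
  cf$pct_hi <- (exp(cf$beta + 1.96 * cf$se) - 1) * 100
  rownames(cf) <- NULL

  null_fit <- fit_terms(data, character(0), outcome, id)
  total_null <- null_fit$s2b + null_fit$s2w
  r2_cum <- NULL
  if (compute_r2 && length(terms)) {
    r2_cum <- vapply(seq_along(terms), function(k) {
      m <- fit_terms(data, terms[seq_len(k)], outcome, id)
      1 - (m$s2b + m$s2w) / total_null
    }, numeric(1))
    names(r2_cum) <- terms
  }
  y <- data[[outcome]]
  fit_vals <- fitted(full$fit)
  out <- list(terms = terms,
              coefficients = cf,
              sigma2_between = full$s2b,
              sigma2_within = full$s2w,
              total_var_null = total_null,
              r2 = 1 - (full$s2b + full$s2w) / total_null,
              r2_cumulative = r2_cum,
              r2_corr = if (sd(fit_vals) > 0) cor(y, fit_vals)^2 else 0,
              n_samples = nrow(data),
              n_participants = length(unique(data[[id]])),
              outcome = outcome, id = id,
              mixed = full$mixed,
              fit = full$fit,
              data = data)
  class(out) <- "cd_mixed"
  out
}

#' Print a determinants model fit
#' @param x a \code{cd_mixed} object.
#' @param digits significant digits.
#' @param ... unused.
#' @export
print.cd_mixed <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept model of %s: %d samples / %d participants\n",
              x$outcome, x$n_samples, x$n_participants))
  if (!x$mixed) cat("  (no repeat samples: ordinary least squares)\n")
  tab <- x$coefficients
  disp <- data.frame(term = tab$term,
                     beta = signif(tab$beta, digits),
                     se = signif(tab$se, digits),
                     p = signif(tab$p, 2),
                     pct_change = sprintf("%.1f (%.1f, %.1f)",
                                          tab$pct_change, tab$pct_lo,
                                          tab$pct_hi))
  if (!is.null(x$r2_cumulative))
    disp$R2_cum <- c(NA, round(x$r2_cumulative, 2))[
      match(disp$term, c("(Intercept)", names(x$r2_cumulative)))]
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("sigma2_between = %.4f, sigma2_within = %.4f, R2 = %.3f\n",
              x$sigma2_between, x$sigma2_within, x$r2))
  invisible(x)
}

#' @export
summary.cd_mixed <- function(object, ...) {
  print(object)
  cat(sprintf("R2 (squared observed-fitted correlation) = %.3f\n",
              object$r2_corr))
  invisible(object)
}

#' @export
coef.cd_mixed <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
predict.cd_mixed <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  if (object$mixed)
    predict(object$fit, newdata = newdata, re.form = NA, ...)
  else predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.cd_mixed <- function(object, ...) residuals(object$fit)

#' @export
plot.cd_mixed <- function(x, ...) {
  graphics::plot(fitted(x$fit), residuals(x$fit),
                 xlab = "fitted ln U-Cd", ylab = "residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Backward elimination with forced terms
#'
#' Starting from the full term list, repeatedly refits the
#' random-intercept model and removes the non-forced term with the
#' largest Wald p-value until every removable term has p below the
#' threshold. Forced terms (here, the environmental and dietary exposure
#' estimates) are retained regardless of significance. Ties on p are
#' broken toward the term appearing later in the specified order. The
#' surviving terms keep their original order.
#'
#' @inheritParams fit_mixed
#' @param forced subset of \code{terms} never removed.
#' @param threshold retention p-value threshold; default 0.1.
#' @return the final \code{cd_mixed} fit, with an \code{eliminated}
#'   element recording each removed term and its p-value at removal.
#' @export
backward_eliminate <- function(data, terms, forced = character(),
                               threshold = 0.1, outcome = "log_cd",
                               id = "participant_id") {
  if (!all(forced %in% terms))
    stop("forced terms must be a subset of terms", call. = FALSE)
  current <- terms
  dropped <- list()
  repeat {
    fit <- fit_mixed(data, current, outcome, id, compute_r2 = FALSE)
    cf <- fit$coefficients
    cand <- cf[cf$term %in% setdiff(current, forced), , drop = FALSE]
    if (!nrow(cand)) break
    worst_p <- max(cand$p)
    if (worst_p < threshold) break
    at_max <- cand$term[cand$p == worst_p]
    worst <- at_max[which.max(match(at_max, current))]
    dropped[[length(dropped) + 1L]] <- list(term = worst, p = worst_p)
    current <- setdiff(current, worst)
  }
  final <- fit_mixed(data, current, outcome, id, compute_r2 = TRUE)
  final$eliminated <- dropped
  final$forced <- forced
  final
}

#' Cumulative R-squared over a nested model sequence
#'
#' For a fitted \code{cd_mixed} object, returns the stored cumulative
#' R-squared per term. For a list of fits, verifies the sequence is
#' nested (each fit's terms contain the previous fit's) and computes the
#' proportional reduction in total residual variance relative to the
#' first model's intercept-only baseline.
#'
#' @param fits a \code{cd_mixed} object or list of nested \code{cd_mixed}
#'   fits on the same data.
#' @return numeric vector of cumulative proportions.
#' @export
cumulative_r2 <- function(fits) {
  if (inherits(fits, "cd_mixed")) {
    if (is.null(fits$r2_cumulative) && length(fits$terms) == 0)
      return(c(`(Intercept)` = 0))
    return(fits$r2_cumulative)
  }
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1),
                                      "cd_mixed")))
  for (k in seq_along(fits)[-1]) {
    if (!all(fits[[k - 1]]$terms %in% fits[[k]]$terms))
      stop("model sequence is not nested", call. = FALSE)
  }
  base <- fits[[1]]$total_var_null
  vapply(fits, function(f)
    1 - (f$sigma2_between + f$sigma2_within) / base, numeric(1))
}

#' 10-fold cross-validation of a determinants model
#'
#' Partitions participants (never samples: both collections from a woman
#' stay in the same fold) into k folds, refits the model leaving each
#' fold out, and summarises the stability of the coefficients and of the
#' R-squared across refits.
#'
#' @inheritParams fit_mixed
#' @param seed integer seed for the fold assignment.
#' @param k number of folds; default 10.
#' @return object of class \code{cd_cv}: per-fold coefficient matrix and
#'   R-squared, the full-data fit, the maximum relative coefficient
#'   deviation from the full fit, and the R-squared range.
#' @export
crossvalidate_10fold <- function(data, terms, outcome = "log_cd",
                                 id = "participant_id", seed = 1L,
                                 k = 10) {
  ids <- unique(data[[id]])
  if (length(ids) < k)
    stop("fewer than ", k, " participants: cannot form folds",
         call. = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold) <- ids
  full <- fit_mixed(data, terms, outcome, id, compute_r2 = FALSE)
  full_beta <- coef(full)
  res <- lapply(seq_len(k), function(f) {
    train <- data[fold[data[[id]]] != f, , drop = FALSE]
    m <- fit_mixed(train, terms, outcome, id, compute_r2 = FALSE)
    list(beta = coef(m), r2 = m$r2)
  })
  beta_mat <- do.call(rbind, lapply(res, `[[`, "beta"))
  r2 <- vapply(res, `[[`, numeric(1), "r2")
  rel_dev <- abs(sweep(beta_mat, 2, full_beta) /
                   rep(full_beta, each = k))
  slope_cols <- setdiff(colnames(beta_mat), "(Intercept)")
  out <- list(beta = beta_mat, r2 = r2, fold = fold, full = full,
              max_rel_dev = max(rel_dev[, slope_cols, drop = FALSE]),
              r2_range = range(r2))
  class(out) <- "cd_cv"
  out
}

#' @export
print.cd_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d participants)\n",
              length(x$r2), length(x$fold)))
  cat(sprintf("  max relative slope deviation from full fit: %.1f%%\n",
              100 * x$max_rel_dev))
  cat(sprintf("  R2 across folds: %.3f-%.3f\n",
              x$r2_range[1], x$r2_range[2]))
  invisible(x)
}

#' Decay of U-Cd after smoking cessation
#'
#' Among former smokers, regresses ln U-Cd on years since quitting
#' (random-intercept model, adjusted for the supplied covariates) and
#' reports the percent change per year since cessation. Because the
#' smoking questionnaire predates the urine collection by three years, a
#' fixed offset (default 3 years) is added to the reported
#' years-since-quit before fitting.
#'
#' @param data long samples data for former smokers (or containing a
#'   \code{years_since_quit} column that is \code{NA} for others).
#' @param adjust covariate columns adjusted for.
#' @param offset_years years added to the reported quit duration.
#' @inheritParams fit_mixed
#' @return list: \code{pct_per_year}, \code{ci} (95\%), \code{p},
#'   \code{n_participants}, \code{n_samples}, and the underlying
#'   \code{cd_mixed} fit.
#' @export
quit_decay <- function(data, adjust = c("creatinine", "age"),
                       offset_years = 3, outcome = "log_cd",
                       id = "participant_id") {
  data <- data[!is.na(data$years_since_quit), , drop = FALSE]
  if (!nrow(data)) stop("no former smokers in data", call. = FALSE)
  data$years_since_quit_adj <- data$years_since_quit + offset_years
  fit <- fit_mixed(data, c(adjust, "years_since_quit_adj"), outcome, id,
                   compute_r2 = FALSE)
  cf <- fit$coefficients
  row <- cf[cf$term == "years_since_quit_adj", ]
  list(pct_per_year = row$pct_change,
       ci = c(row$pct_lo, row$pct_hi),
       p = row$p,
       n_participants = fit$n_participants,
       n_samples = fit$n_samples,
       fit = fit)
}

#' Log10 scaling with a zero offset for skewed exposure metrics
#'
#' Environmental metrics such as traffic density and facility emissions
#' span orders of magnitude and contain exact zeros; modelling them per
#' 10-fold change uses log10 after mapping zeros to a configurable
#' offset, by default half the smallest positive value.
#'
#' @param x non-negative metric.
#' @param offset value substituted for zeros; default half the minimum
#'   positive entry (or 1 when all entries are zero).
#' @return log10-scaled vector.
#' @export
scale_log10 <- function(x, offset = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop("x must be non-negative", call. = FALSE)
  if (is.null(offset)) {
    pos <- x[x > 0 & !is.na(x)]
    offset <- if (length(pos)) min(pos) / 2 else 1
  }
  log10(ifelse(x == 0, offset, x))
}

#' Assemble the modelling dataset
#'
#' Joins processed samples to participant covariates and exposure
#' metrics, and creates the model-scale versions of the predictors:
#' age rescaled so the youngest participant is zero, creatinine per
#' 0.1 g/L, ambient air per 0.1 ng/m^3, traffic and industrial emissions
#' per 10-fold change (\code{\link{scale_log10}}), and the ordinal
#' alcohol score.
#'
#' @param processed output of \code{\link{process_samples}}.
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param exposures output of \code{\link{build_exposures}}.
#' @return long data.frame, one row per sample, ready for
#'   \code{\link{fit_mixed}}. Model-scale columns: \code{creatinine_01}
#'   (0.1 g/L), \code{age0} (years above the cohort minimum),
#'   \code{air_01} (0.1 ng/m^3), \code{log10_traffic},
#'   \code{log10_industrial}.
#' @export
prepare_model_data <- function(processed, cohort, exposures) {
  d <- merge(processed, cohort, by.x = "participant_id", by.y = "id")
  d <- merge(d, exposures[, setdiff(names(exposures),
                                    c("pack_years",
                                      "passive_intensity_years"))],
             by = "participant_id")
  d$creatinine_01 <- d$creatinine / 0.1
  d$age0 <- d$age - min(d$age)
  d$air_01 <- d$air_cd / 0.1
  d$log10_traffic <- scale_log10(d$traffic_density)
  d$log10_industrial <- scale_log10(d$industrial_kg_5km)
  d[order(d$participant_id, d$occasion), , drop = FALSE]
}
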