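#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study into one validated list.
#' Defaults emulate a cohort of middle-aged, largely never-smoking women
#' providing 24-hr urine collections, with roughly half providing a second
#' collection 3--9 months later, and with log-normal U-Cd whose
#' between- and within-person log-scale variance components are 0.216 and
#' 0.221 (intraclass correlation about 0.5, variance ratio about 1).
#'
#' Covariate effects are log-scale slopes applied to centred covariates.
#' Person-level effects (age, pack-years, parity, ...) explain part of
#' \code{sigma2_between} and the occasion-level creatinine effect part of
#' \code{sigma2_within}: the residual random-intercept and noise variances
#' are reduced so that the marginal components seen by a variance-components
#' model stay at the configured values. With \code{covariate_effects =
#' list()} the generator reduces to the pure two-component log-normal model.
#'
#' @param n_participants number of women in the cohort.
#' @param repeat_fraction proportion providing a second 24-hr sample.
#' @param sigma2_between between-person variance of ln U-Cd.
#' @param sigma2_within within-person variance of ln U-Cd.
#' @param mu_log_cd mean of ln U-Cd in ln(ug/L); default ln(0.27).
#' @param covariate_effects named list of log-scale slopes per natural unit
#'   (see \code{\link{default_covariate_effects}}); \code{list()} disables.
#' @param lod assay limit of detection, ug/L.
#' @param interval_drift additive log-scale drift per month between
#'   collections (0 by default: reliability assumed stable over 3--9 months).
#' @param region_km side of the square planar study region, km.
#' @param tract_km side of the square census-tract grid cells, km.
#' @param n_road_clusters,segments_per_cluster road network size.
#' @param n_facilities number of industrial facilities.
#' @param ffq_missing_rate fraction of participants without FFQ responses.
#' @param ffq_implausible_rate fraction with deliberately mis-scaled
#'   reporting, producing implausible energy intakes.
#' @param seed integer seed; every generator draw descends from it.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_participants = 296,
                          repeat_fraction = 141 / 296,
                          sigma2_between = 0.216,
                          sigma2_within = 0.221,
                          mu_log_cd = log(0.27),
                          covariate_effects = default_covariate_effects(),
                          lod = 0.1,
                          interval_drift = 0,
                          region_km = 40,
                          tract_km = 5,
                          n_road_clusters = 60,
                          segments_per_cluster = 4,
                          n_facilities = 25,
                          ffq_missing_rate = 3 / 296,
                          ffq_implausible_rate = 6 / 296,
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              repeat_fraction = repeat_fraction,
              sigma2_between = sigma2_between,
              sigma2_within = sigma2_within,
              mu_log_cd = mu_log_cd,
              covariate_effects = covariate_effects,
              lod = lod,
              interval_drift = interval_drift,
              region_km = region_km,
              tract_km = tract_km,
              n_road_clusters = n_road_clusters,
              segments_per_cluster = segments_per_cluster,
              n_facilities = n_facilities,
              ffq_missing_rate = ffq_missing_rate,
              ffq_implausible_rate = ffq_implausible_rate,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_participants) || cfg$n_participants < 1)
    stop("n_participants must be a positive integer", call. = FALSE)
  if (cfg$sigma2_between < 0 || cfg$sigma2_within < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1)
    stop("repeat_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$lod <= 0) stop("lod must be positive", call. = FALSE)
  if (!is.list(cfg$covariate_effects))
    stop("covariate_effects must be a (possibly empty) named list",
         call. = FALSE)
  invisible(cfg)
}

#' Default covariate effects on ln U-Cd
#'
#' Log-scale slopes per natural unit, calibrated so that creatinine
#' explains roughly a quarter of the total ln U-Cd variance and the
#' person-level covariates together a further sixth, as observed in
#' determinants models of U-Cd in nonoccupationally exposed women:
#' U-Cd rises with urinary creatinine, age and smoking dose, and falls
#' with parity and alcohol intake. Passive-smoke intensity-years act only
#' on never smokers, where the covariate is defined.
#'
#' @return Named list of slopes: \code{creatinine} (per g/L, occasion
#'   level), \code{age} (per year), \code{pack_years} (per pack-year),
#'   \code{parity} (per pregnancy), \code{alcohol_score} (per ordinal
#'   category 0/1/2), \code{passive_intensity_years} (per intensity-year).
#' @export
default_covariate_effects <- function() {
  list(creatinine = 1.0,
       age = 0.014,
       pack_years = 0.0105,
       parity = -0.047,
       alcohol_score = -0.175,
       passive_intensity_years = 0.002)
}

# rejection-sampled truncated normal; bounds are in data units
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# derive a reproducible sub-seed per generator stage from the root seed
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, samples = 23L, geography = 37L, ffq = 41L,
               pipeline = 53L)
  (as.integer(seed) * 113L + offsets[[stage]]) %% 2147483629L
}

#' Generate a synthetic cohort of participants
#'
#' Draws participant covariates with marginal distributions emulating a
#' cohort of women aged 31--84 (mean about 55): body size, parity,
#' breastfeeding, active and passive smoking history, alcohol category,
#' contraceptive/hormone use, energy intake, and a planar residence with a
#' census-tract identifier. Deterministic for a fixed config and seed.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with one row per participant: \code{id}, \code{age},
#'   \code{height} (cm), \code{weight} (kg), \code{parity},
#'   \code{breastfeeding} (months), \code{smoking_status}
#'   (never/former/current), \code{pack_years},
#'   \code{passive_intensity_years} (never smokers, else \code{NA}),
#'   \code{years_since_quit} (former smokers, else \code{NA}),
#'   \code{alcohol_category} (none, "<20", ">=20" g/day),
#'   \code{alcohol_score} (0/1/2), \code{oc_ever}, \code{hrt_ever},
#'   \code{kcal_per_day}, \code{x_km}, \code{y_km}, \code{tract_id}.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "cohort"))
  n <- config$n_participants

  age <- rtnorm(n, 55, 12, 31, 84)
  height <- rtnorm(n, 163, 6.5, 140, 190)
  bmi <- rtnorm(n, 27, 5.9, 16, 61)
  weight <- bmi * (height / 100)^2

  parity <- sample(0:6, n, replace = TRUE,
                   prob = c(0.26, 0.22, 0.27, 0.15, 0.06, 0.03, 0.01))
  breastfeeding <- round(rtnorm(n, 3.2, 2.3, 0, 9), 1)

  smoking_status <- sample(c("never", "former", "current"), n,
                           replace = TRUE, prob = c(0.70, 0.27, 0.03))
  pack_years <- numeric(n)
  ever <- smoking_status != "never"
  pack_years[ever] <- pmin(rlnorm(sum(ever), meanlog = 1.8, sdlog = 1.4), 61)
  years_since_quit <- rep(NA_real_, n)
  former <- smoking_status == "former"
  years_since_quit[former] <- round(runif(sum(former), 1, 35), 1)

  passive_intensity_years <- rep(NA_real_, n)
  nev <- smoking_status == "never"
  passive_intensity_years[nev] <-
    pmin(rgamma(sum(nev), shape = 0.75, scale = 40), 203)

  alcohol_category <- sample(c("none", "<20", ">=20"), n, replace = TRUE,
                             prob = c(0.32, 0.59, 0.09))
  alcohol_score <- match(alcohol_category, c("none", "<20", ">=20")) - 1L

  oc_ever <- rbinom(n, 1, 0.72) == 1
  hrt_ever <- rbinom(n, 1, 0.48) == 1
  kcal_per_day <- rtnorm(n, 1800, 450, 700, 4200)

  x_km <- runif(n, 0, config$region_km)
  y_km <- runif(n, 0, config$region_km)
  tract_id <- tract_of(x_km, y_km, config)

  data.frame(id = sprintf("P%03d", seq_len(n)),
             age = age, height = height, weight = weight,
             parity = parity, breastfeeding = breastfeeding,
             smoking_status = smoking_status, pack_years = pack_years,
             passive_intensity_years = passive_intensity_years,
             years_since_quit = years_since_quit,
             alcohol_category = alcohol_category,
             alcohol_score = alcohol_score,
             oc_ever = oc_ever, hrt_ever = hrt_ever,
             kcal_per_day = kcal_per_day,
             x_km = x_km, y_km = y_km, tract_id = tract_id,
             stringsAsFactors = FALSE)
}

tract_of <- function(x, y, config) {
  per_side <- ceiling(config$region_km / config$tract_km)
  ix <- pmin(floor(x / config$tract_km), per_side - 1)
  iy <- pmin(floor(y / config$tract_km), per_side - 1)
  sprintf("T%03d", as.integer(iy * per_side + ix + 1))
}

# person-level covariate signal on the log scale, centred at cohort means
person_signal <- function(cohort, effects) {
  sig <- numeric(nrow(cohort))
  slope <- function(nm) if (is.null(effects[[nm]])) 0 else effects[[nm]]
  centred <- function(v) {
    v[is.na(v)] <- 0                     # effects apply where defined
    v - mean(v)
  }
  sig <- sig + slope("age") * centred(cohort$age)
  sig <- sig + slope("pack_years") * centred(cohort$pack_years)
  sig <- sig + slope("parity") * centred(cohort$parity)
  sig <- sig + slope("alcohol_score") * centred(cohort$alcohol_score)
  sig <- sig + slope("passive_intensity_years") *
    centred(cohort$passive_intensity_years)
  sig
}

#' Generate repeat 24-hr urine samples for a cohort
#'
#' Simulates ln U-Cd as mean + centred covariate effects + person random
#' intercept + occasion noise; a configured fraction of participants
#' (chosen at random, \code{round(n * repeat_fraction)} of them) provides a
#' second collection 3, 6 or 9 months after the first. Creatinine (g/L,
#' geometric mean about 0.7) and 24-hr urine volume (L/day, geometric mean
#' about 1.7) are drawn per collection; the occasion-level creatinine
#' effect, when configured, consumes part of the within-person variance so
#' that the marginal components stay at the configured
#' \code{sigma2_between}/\code{sigma2_within}. Values below the LOD are
#' flagged but stored unmodified; substitution happens in
#' \code{\link{process_samples}}.
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param config the same \code{\link{cohort_config}}.
#' @return data.frame of samples: \code{participant_id}, \code{occasion}
#'   (1/2), \code{interval_months} (0 for the first collection; 3, 6 or 9
#'   for the repeat), \code{cadmium} (ug/L), \code{below_lod},
#'   \code{creatinine} (g/L), \code{volume} (L/day).
#' @export
generate_samples <- function(cohort, config) {
  validate_config(config)
  if (nrow(cohort) < 1) stop("cohort is empty", call. = FALSE)
  set.seed(stage_seed(config$seed, "samples"))
  n <- nrow(cohort)
  eff <- config$covariate_effects

  sig_p <- person_signal(cohort, eff)
  var_p <- if (n > 1) var(sig_p) * (n - 1) / n else 0
  s2b_resid <- max(config$sigma2_between - var_p, 0)

  n_repeat <- round(n * config$repeat_fraction)
  repeaters <- sort(sample.int(n, n_repeat))
  idx <- c(seq_len(n), repeaters)
  occasion <- c(rep(1L, n), rep(2L, n_repeat))
  interval <- c(rep(0L, n),
                sample(c(3L, 6L, 9L), n_repeat, replace = TRUE))

  m <- length(idx)
  creatinine <- rlnorm(m, meanlog = log(0.71), sdlog = log(1.6))
  volume <- rlnorm(m, meanlog = log(1.7), sdlog = 0.25)

  b_cr <- if (is.null(eff$creatinine)) 0 else eff$creatinine
  sig_o <- b_cr * (creatinine - mean(creatinine))
  var_o <- if (m > 1) var(sig_o) * (m - 1) / m else 0
  s2w_resid <- max(config$sigma2_within - var_o, 0)

  intercepts <- rnorm(n, 0, sqrt(s2b_resid))
  log_cd <- config$mu_log_cd + sig_p[idx] + sig_o + intercepts[idx] +
    rnorm(m, 0, sqrt(s2w_resid)) + config$interval_drift * interval
  cadmium <- exp(log_cd)

  out <- data.frame(participant_id = cohort$id[idx],
                    occasion = occasion,
                    interval_months = interval,
                    cadmium = cadmium,
                    below_lod = cadmium < config$lod,
                    creatinine = creatinine,
                    volume = volume,
                    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$occasion), , drop = FALSE]
}

#' Generate planar geographic layers
#'
#' Builds a road network (clustered line segments with annual average
#' daily traffic, AADT), industrial facilities (points with annual cadmium
#' emissions in kg), and a census-tract ambient-air cadmium table
#' (ng/m^3, within 0.05--0.65). Coordinates are planar km: at buffer radii
#' of 0.3--5 km the error from ignoring geodesy is negligible. Roads
#' cluster around a subset of locations so that roughly a third of
#' residences see no major road within 300 m, and facilities are sparse so
#' that most residences have no emitter within 5 km, mirroring the skewed
#' exposure distributions typical of mixed urban/rural study regions.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{roads} (data.frame \code{x1,y1,x2,y2,aadt}),
#'   \code{facilities} (data.frame \code{x,y,emissions_kg}) and
#'   \code{air} (data.frame \code{tract_id, air_cd}).
#' @export
generate_geography <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "geography"))
  R <- config$region_km

  n_cl <- config$n_road_clusters
  centers <- cbind(runif(n_cl, 0, R), runif(n_cl, 0, R))
  segs <- lapply(seq_len(n_cl), function(i) {
    k <- sample.int(config$segments_per_cluster, 1)
    mx <- centers[i, 1] + rnorm(k, 0, 0.6)
    my <- centers[i, 2] + rnorm(k, 0, 0.6)
    theta <- runif(k, 0, pi)
    len <- runif(k, 0.3, 1.5)
    data.frame(x1 = mx - cos(theta) * len / 2,
               y1 = my - sin(theta) * len / 2,
               x2 = mx + cos(theta) * len / 2,
               y2 = my + sin(theta) * len / 2,
               aadt = pmin(rlnorm(k, meanlog = log(15000), sdlog = 1.1),
                           80000))
  })
  roads <- do.call(rbind, segs)

  nf <- config$n_facilities
  facilities <- if (nf > 0) {
    data.frame(x = runif(nf, 0, R), y = runif(nf, 0, R),
               emissions_kg = pmin(rlnorm(nf, meanlog = log(0.5),
                                          sdlog = 2.5), 1760))
  } else {
    data.frame(x = numeric(0), y = numeric(0), emissions_kg = numeric(0))
  }

  per_side <- ceiling(R / config$tract_km)
  ids <- sprintf("T%03d", seq_len(per_side^2))
  air_cd <- pmin(pmax(rgamma(length(ids), shape = 2.4, scale = 0.083),
                      0.05), 0.65)
  list(roads = roads, facilities = facilities,
       air = data.frame(tract_id = ids, air_cd = air_cd,
                        stringsAsFactors = FALSE))
}

#' Built-in synthetic food-item contaminant table
#'
#' A fixed table of 20 synthetic food items with cadmium content and
#' energy per medium serving, in the spirit of market-basket contaminant
#' surveys: leafy vegetables, grains, potatoes and organ meats carry the
#' most cadmium per serving. Entirely synthetic; item values are chosen so
#' that a typical diet delivers on the order of 10 ug Cd/day at roughly
#' 1,800 kcal/day.
#'
#' @return data.frame: \code{item_id}, \code{item},
#'   \code{cd_per_medium_serving} (ug), \code{kcal_per_medium_serving}.
#' @export
contaminant_table <- function() {
  items <- c("lettuce", "spinach", "potato", "whole grain bread", "rice",
             "pasta", "breakfast cereal", "peanuts", "sunflower seeds",
             "liver", "shellfish", "carrots", "tomatoes", "apples",
             "bananas", "milk", "cheese", "chicken", "beef", "chocolate")
  cd <- c(0.9, 1.6, 1.4, 0.8, 0.7, 0.5, 0.6, 1.1, 1.8,
          2.6, 2.1, 0.7, 0.4, 0.3, 0.3, 0.1, 0.2, 0.2, 0.3, 1.0)
  kcal <- c(15, 25, 160, 140, 200, 210, 150, 170, 175,
            180, 120, 35, 30, 95, 105, 120, 110, 190, 250, 230)
  data.frame(item_id = sprintf("f%02d", seq_along(items)),
             item = items,
             cd_per_medium_serving = cd,
             kcal_per_medium_serving = kcal,
             stringsAsFactors = FALSE)
}

#' Generate food-frequency questionnaire responses
#'
#' For each participant, draws a target dietary cadmium intake (gamma,
#' mean 11 and SD 4.2 ug/day) and constructs item frequencies whose
#' weighted sums reproduce both that target and the participant's energy
#' intake: random item weights are blended between an energy-rich and a
#' cadmium-rich basket so the implied kcal/Cd ratio matches
#' \code{kcal_per_day / target}, then scaled to the cadmium target. The
#' intake recovered downstream by \code{\link{dietary_cd_intake}}
#' therefore follows the configured distribution, and implied energy
#' stays plausible except for a configured fraction of participants who
#' mis-scale their reporting (and a configured fraction who return no
#' FFQ at all).
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param contaminants a contaminant table, see \code{\link{contaminant_table}}.
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame of responses: \code{participant_id}, \code{item_id},
#'   \code{frequency} (servings/day), \code{portion} (small/medium/large).
#' @export
generate_ffq <- function(cohort, contaminants, config) {
  validate_config(config)
  if (nrow(contaminants) < 1) stop("contaminant table is empty", call. = FALSE)
  set.seed(stage_seed(config$seed, "ffq"))
  n <- nrow(cohort)
  k <- nrow(contaminants)
  pw <- c(small = 0.5, medium = 1, large = 1.5)
  cd <- contaminants$cd_per_medium_serving
  kcal <- contaminants$kcal_per_medium_serving
  r <- kcal / cd                      # kcal per ug Cd, item by item

  missing_ffq <- runif(n) < config$ffq_missing_rate
  implausible <- !missing_ffq & runif(n) < config$ffq_implausible_rate

  target <- rgamma(n, shape = (11 / 4.2)^2, scale = 4.2^2 / 11)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    if (missing_ffq[i]) next
    base <- rgamma(k, shape = 0.8) + 0.05
    u_energy <- base * r; u_energy <- u_energy / sum(u_energy)
    u_cadmium <- base / r; u_cadmium <- u_cadmium / sum(u_cadmium)
    rho <- cohort$kcal_per_day[i] / target[i]
    # blend u = (1-t) u_energy + t u_cadmium so sum(u*kcal)/sum(u*cd) = rho
    A0 <- sum(u_energy * kcal); B0 <- sum(u_energy * cd)
    A1 <- sum(u_cadmium * kcal); B1 <- sum(u_cadmium * cd)
    denom <- (A1 - A0) - rho * (B1 - B0)
    t <- if (abs(denom) < 1e-12) 0.5 else (rho * B0 - A0) / denom
    t <- min(max(t, 0), 1)
    u <- (1 - t) * u_energy + t * u_cadmium
    dose <- target[i] * u / sum(u * cd)   # medium-serving equivalents/day
    portion <- sample(names(pw), k, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25))
    freq <- dose / pw[portion]
    if (implausible[i])
      freq <- freq * sample(c(0.04, 6), 1)
    res[[i]] <- data.frame(participant_id = cohort$id[i],
                           item_id = contaminants$item_id,
                           frequency = as.numeric(freq),
                           portion = portion,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
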