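#' Write road segments as GeoJSON
#'
#' LineString features in planar km coordinates with an \code{aadt}
#' property (vehicles/day).
#'
#' @param roads data.frame \code{x1,y1,x2,y2,aadt}.
#' @param path output file.
#' @export
write_roads_geojson <- function(roads, path) {
  features <- lapply(seq_len(nrow(roads)), function(i) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(roads$x1[i], roads$y1[i]),
                           c(roads$x2[i], roads$y2[i]))),
         properties = list(aadt = roads$aadt[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read road segments from GeoJSON
#' @param path GeoJSON file of LineString features with \code{aadt}.
#' @return data.frame \code{x1,y1,x2,y2,aadt}.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates
    data.frame(x1 = cc[[1]][[1]], y1 = cc[[1]][[2]],
               x2 = cc[[2]][[1]], y2 = cc[[2]][[2]],
               aadt = f$properties$aadt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write facilities as GeoJSON
#'
#' Point features in planar km coordinates with an \code{emissions_kg}
#' property (annual cadmium emissions).
#'
#' @param facilities data.frame \code{x,y,emissions_kg}.
#' @param path output file.
#' @export
write_facilities_geojson <- function(facilities, path) {
  features <- lapply(seq_len(nrow(facilities)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[i],
                                         facilities$y[i])),
         properties = list(emissions_kg = facilities$emissions_kg[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read facilities from GeoJSON
#' @param path GeoJSON file of Point features with \code{emissions_kg}.
#' @return data.frame \code{x,y,emissions_kg}.
#' @export
read_facilities_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates
    data.frame(x = cc[[1]], y = cc[[2]],
               emissions_kg = f$properties$emissions_kg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full-run configuration
#'
#' One declarative object driving the whole pipeline; all randomness
#' descends from the single \code{seed}.
#'
#' @param generator a \code{\link{cohort_config}} (its seed is overridden
#'   by \code{seed}).
#' @param lod assay limit of detection, ug/L.
#' @param buffer_km traffic buffer radius, km.
#' @param facility_km facility search radius, km.
#' @param portion_weights FFQ portion multipliers.
#' @param elimination_threshold retention p-value for backward
#'   elimination, in (0, 1].
#' @param forced_terms model terms retained regardless of significance
#'   (the environmental and dietary exposure estimates).
#' @param n_list numbers of measurements for the attenuation table.
#' @param true_or true odds ratio for the attenuation table.
#' @param height_exp BSA height exponent.
#' @param seed root integer seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(generator = cohort_config(seed = seed),
                       lod = 0.1,
                       buffer_km = 0.3,
                       facility_km = 5,
                       portion_weights = c(small = 0.5, medium = 1,
                                           large = 1.5),
                       elimination_threshold = 0.1,
                       forced_terms = c("air_01", "log10_industrial",
                                        "log10_traffic", "dietary_cd"),
                       n_list = c(1, 2, 4),
                       true_or = 2.0,
                       height_exp = 0.725,
                       seed = 1L) {
  if (elimination_threshold <= 0 || elimination_threshold > 1)
    stop("elimination_threshold must lie in (0, 1]", call. = FALSE)
  if (buffer_km <= 0 || facility_km <= 0)
    stop("radii must be positive", call. = FALSE)
  generator$seed <- as.integer(seed)
  generator$lod <- lod
  validate_config(generator)
  structure(list(generator = generator, lod = lod,
                 buffer_km = buffer_km, facility_km = facility_km,
                 portion_weights = portion_weights,
                 elimination_threshold = elimination_threshold,
                 forced_terms = forced_terms, n_list = n_list,
                 true_or = true_or, height_exp = height_exp,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; a
#' \code{generator} mapping holds \code{\link{cohort_config}} overrides.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  y$generator <- NULL
  if (!is.null(seed)) y$seed <- as.integer(seed)
  if (is.null(y$seed)) y$seed <- 1L
  gen <- do.call(cohort_config, c(gen_args, list(seed = y$seed)))
  if (!is.null(y$portion_weights))
    y$portion_weights <- unlist(y$portion_weights)
  if (!is.null(y$forced_terms)) y$forced_terms <- unlist(y$forced_terms)
  if (!is.null(y$n_list)) y$n_list <- unlist(y$n_list)
  do.call(run_config, c(list(generator = gen), y))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate -> prep -> exposures -> reliability -> determinants, from a
#' single configuration, writing every intermediate artifact (CSV,
#' GeoJSON, JSON) plus a plain-text summary report into \code{out_dir}.
#' Deterministic for a fixed config and seed. The report juxtaposes the
#' computed ICC, variance ratio and attenuation table with published
#' reference values for repeat 24-hr U-Cd sampling in women (ICC 0.50,
#' variance ratio 1.0, attenuation 50/33/20\% for 1/2/4 samples,
#' observed OR 1.4 for a true OR of 2.0).
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every major result: cohort, samples,
#'   processed samples, exposures, \code{cd_vc} fits, attenuation table,
#'   screening table, final models, cross-validation, quit-decay, and
#'   the report lines.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  gen <- config$generator

  sim <- run_stage("simulate", {
    cohort <- generate_cohort(gen)
    samples <- generate_samples(cohort, gen)
    geo <- generate_geography(gen)
    contaminants <- contaminant_table()
    ffq <- generate_ffq(cohort, contaminants, gen)
    write.csv(cohort, p("participants.csv"), row.names = FALSE)
    write.csv(samples, p("samples.csv"), row.names = FALSE)
    write.csv(ffq, p("ffq.csv"), row.names = FALSE)
    write.csv(contaminants, p("contaminants.csv"), row.names = FALSE)
    write.csv(geo$air, p("air_by_tract.csv"), row.names = FALSE)
    write_roads_geojson(geo$roads, p("roads.geojson"))
    write_facilities_geojson(geo$facilities, p("facilities.geojson"))
    list(cohort = cohort, samples = samples, geo = geo,
         contaminants = contaminants, ffq = ffq)
  })

  processed <- run_stage("prep", {
    pr <- process_samples(sim$samples, config$lod)
    write.csv(pr, p("processed_samples.csv"), row.names = FALSE)
    pr
  })

  exposures <- run_stage("exposures", {
    ex <- build_exposures(sim$cohort, sim$geo, sim$ffq,
                          sim$contaminants, config$buffer_km,
                          config$facility_km, config$height_exp,
                          config$portion_weights)
    write.csv(ex, p("exposures.csv"), row.names = FALSE)
    ex
  })

  rel <- run_stage("reliability", {
    vc <- fit_variance_components(processed, "log_cd")
    processed$log_cd_creat <- log(processed$cd_per_creatinine)
    vc_creat <- fit_variance_components(processed, "log_cd_creat")
    lam <- round(vc$lambda, 1)
    att <- attenuation(lam, config$n_list, log(config$true_or))
    by_int <- vc_by_interval(processed, "log_cd")
    jsonlite::write_json(
      list(unadjusted = as.list(coef(vc)),
           creatinine_adjusted = as.list(coef(vc_creat)),
           lambda_reporting = lam,
           attenuation = att[, c("n", "pct_bias", "or_true",
                                 "or_expected")],
           icc_by_interval = lapply(by_int, function(v) v$icc)),
      p("reliability.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    list(vc = vc, vc_creat = vc_creat, lambda = lam, attenuation = att,
         by_interval = by_int)
  })

  det <- run_stage("determinants", {
    d <- prepare_model_data(processed, sim$cohort, exposures)
    first <- d[d$occasion == 1, , drop = FALSE]
    screening <- screen_predictors(
      first, "cadmium_sub",
      list(age = NULL, pack_years = list(breaks = c(0, 0.1, 5, 20, Inf)),
           passive_intensity_years = NULL,
           alcohol_category = NULL, parity = list(breaks = c(0, 1, 3, Inf)),
           breastfeeding = NULL, oc_ever = NULL, hrt_ever = NULL,
           bmi = list(breaks = c(0, 25, 30, Inf)), bsa = NULL,
           dietary_cd = NULL, air_cd = list(breaks = c(0, 0.1, 0.3, Inf)),
           traffic_density = list(breaks = c(-1, 0, 7000, 70000, Inf)),
           industrial_kg_5km = list(breaks = c(-1, 0, 20, Inf))))
    write.csv(screening, p("screening.csv"), row.names = FALSE)

    terms1 <- c("creatinine_01", "age0", "pack_years", "parity",
                "alcohol_score", "bsa", "bmi", "breastfeeding",
                "oc_ever", "hrt_ever", config$forced_terms)
    model1 <- backward_eliminate(d, terms1, config$forced_terms,
                                 config$elimination_threshold)
    never <- d[d$smoking_status == "never", , drop = FALSE]
    terms2 <- c("creatinine_01", "age0", "passive_intensity_years",
                "parity", "alcohol_score", "bsa", "bmi", "breastfeeding",
                "oc_ever", "hrt_ever", config$forced_terms)
    model2 <- backward_eliminate(never, terms2, config$forced_terms,
                                 config$elimination_threshold)
    cv <- crossvalidate_10fold(d, model1$terms,
                               seed = stage_seed(config$seed, "pipeline"))
    qd <- tryCatch(quit_decay(d[d$smoking_status == "former", ,
                                drop = FALSE],
                              adjust = c("creatinine_01", "age0")),
                   error = function(e) NULL)
    model_json <- function(m)
      list(terms = m$terms, coefficients = m$coefficients,
           sigma2_between = m$sigma2_between,
           sigma2_within = m$sigma2_within,
           r2_cumulative = as.list(m$r2_cumulative), r2 = m$r2,
           eliminated = m$eliminated)
    jsonlite::write_json(list(model1 = model_json(model1),
                              model2 = model_json(model2)),
                         p("model_fit.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(list(r2 = cv$r2, r2_range = cv$r2_range,
                              max_rel_dev = cv$max_rel_dev),
                         p("cv.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(data = d, screening = screening, model1 = model1,
         model2 = model2, cv = cv, quit = qd)
  })

  report <- run_stage("report", {
    ref <- list(icc = 0.50, lambda = 1.0,
                att = c(`1` = 50, `2` = 33, `4` = 20), or_obs = 1.4)
    att <- rel$attenuation
    lines <- c(
      "U-Cd variability pipeline summary",
      sprintf("seed: %d; %d participants, %d samples",
              config$seed, nrow(sim$cohort), nrow(sim$samples)),
      "",
      sprintf("%-38s %10s %10s", "quantity", "computed", "reference"),
      sprintf("%-38s %10.3f %10.2f", "ICC (unadjusted ln U-Cd)",
              rel$vc$icc, ref$icc),
      sprintf("%-38s %10.3f %10s", "ICC (creatinine-adjusted)",
              rel$vc_creat$icc, ""),
      sprintf("%-38s %10.1f %10.1f", "variance ratio lambda (reporting)",
              rel$lambda, ref$lambda),
      vapply(seq_len(nrow(att)), function(i) {
        r <- as.character(att$n[i])
        sprintf("%-38s %10.0f %10s",
                sprintf("attenuation bias %% (n = %d)", att$n[i]),
                abs(att$pct_bias[i]),
                if (r %in% names(ref$att))
                  sprintf("%d", ref$att[[r]]) else "")
      }, character(1)),
      sprintf("%-38s %10.2f %10.1f",
              sprintf("expected observed OR (true %.1f, n = 1)",
                      config$true_or),
              att$or_expected[att$n == 1], ref$or_obs),
      "",
      sprintf("model 1 (all participants): R2 = %.2f over terms: %s",
              det$model1$r2, paste(det$model1$terms, collapse = ", ")),
      sprintf("model 2 (never smokers):    R2 = %.2f over terms: %s",
              det$model2$r2, paste(det$model2$terms, collapse = ", ")),
      sprintf("cross-validation: R2 %.2f-%.2f, max slope deviation %.0f%%",
              det$cv$r2_range[1], det$cv$r2_range[2],
              100 * det$cv$max_rel_dev))
    if (!is.null(det$quit))
      lines <- c(lines, sprintf(
        "former smokers: %.1f%% change per year since quitting (95%% CI %.1f, %.1f)",
        det$quit$pct_per_year, det$quit$ci[1], det$quit$ci[2]))
    writeLines(lines, p("report.txt"))
    lines
  })

  invisible(list(cohort = sim$cohort, samples = sim$samples,
                 geography = sim$geo, ffq = sim$ffq,
                 contaminants = sim$contaminants,
                 processed = processed, exposures = exposures,
                 reliability = rel, determinants = det,
                 report = report, out_dir = out_dir))
}
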