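#' Substitute values below the limit of detection
#'
#' Non-detects are replaced by LOD/sqrt(2), the standard single-value
#' substitution for left-censored assay data; with the 0.1 ug/L LOD of the
#' U-Cd assay this is 0.0707 ug/L (0.07 to assay precision). Values at or
#' above the LOD pass through unchanged: a value exactly at the LOD counts
#' as a detect. Idempotent, since the substitution value is itself below
#' the LOD only once.
#'
#' @param value numeric vector of concentrations, ug/L.
#' @param lod limit of detection, ug/L (> 0).
#' @param below_lod optional logical vector flagging non-detects; when
#'   supplied it overrides the \code{value < lod} comparison.
#' @return numeric vector with non-detects substituted.
#' @export
substitute_lod <- function(value, lod = 0.1, below_lod = NULL) {
  if (!is.numeric(lod) || length(lod) != 1 || is.na(lod) || lod <= 0)
    stop("lod must be a single positive number", call. = FALSE)
  nd <- if (is.null(below_lod)) value < lod else below_lod
  value[nd] <- lod / sqrt(2)
  value
}

#' Creatinine-adjust a urinary concentration
#'
#' Divides the analyte concentration (ug/L) by urinary creatinine (g/L) to
#' correct for urine dilution, giving ug per g creatinine.
#'
#' @param cadmium concentration, ug/L.
#' @param creatinine creatinine concentration, g/L (> 0).
#' @return adjusted concentration, ug/g.
#' @export
creatinine_adjust <- function(cadmium, creatinine) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be positive: invalid sample", call. = FALSE)
  cadmium / creatinine
}

#' Daily analyte output from a 24-hr collection
#'
#' Multiplies concentration (ug/L) by the total urine volume collected
#' over 24 hr (L/day), giving ug/day.
#'
#' @param cadmium concentration, ug/L.
#' @param volume 24-hr urine volume, L/day (> 0).
#' @return daily output, ug/day.
#' @export
daily_output <- function(cadmium, volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive", call. = FALSE)
  cadmium * volume
}

#' Geometric mean and geometric standard deviation
#'
#' GM = exp(mean(ln x)), GSD = exp(sd(ln x)) with the sample (n-1)
#' standard deviation of the logs -- the natural summaries of a log-normal
#' biomarker. The GSD of a single value, or of a constant vector, is 1.
#'
#' @param values positive numeric vector.
#' @return list with \code{gm} and \code{gsd}.
#' @export
gm_gsd <- function(values) {
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  lx <- log(values)
  list(gm = exp(mean(lx)),
       gsd = if (length(lx) > 1) exp(sd(lx)) else 1)
}

#' Preprocess urine samples into analysis-ready biomarker columns
#'
#' Applies LOD substitution, creatinine adjustment, daily-output
#' computation and the natural-log transform used throughout the
#' statistical analysis.
#'
#' @param samples data.frame as produced by \code{\link{generate_samples}}
#'   (columns \code{cadmium}, \code{creatinine}, \code{volume}, optionally
#'   \code{below_lod}).
#' @param lod limit of detection, ug/L.
#' @return the input with four derived columns: \code{cadmium_sub} (ug/L
#'   after substitution), \code{cd_per_creatinine} (ug/g),
#'   \code{cd_output} (ug/day), \code{log_cd} (ln ug/L).
#' @export
process_samples <- function(samples, lod = 0.1) {
  need <- c("cadmium", "creatinine", "volume")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  flag <- if ("below_lod" %in% names(samples)) samples$below_lod else NULL
  samples$cadmium_sub <- substitute_lod(samples$cadmium, lod, flag)
  samples$cd_per_creatinine <- creatinine_adjust(samples$cadmium_sub,
                                                 samples$creatinine)
  samples$cd_output <- daily_output(samples$cadmium_sub, samples$volume)
  samples$log_cd <- log(samples$cadmium_sub)
  samples
}
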