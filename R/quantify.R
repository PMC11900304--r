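#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of the trace inside the retention-time window,
#' above a baseline estimated as the median intensity outside the window
#' (robust to the peak itself; vendor-style baseline fitting is out of
#' scope). The result is truncated at zero.
#'
#' @param trace Data frame with columns `time_min` and `intensity`.
#' @param window `c(from, to)` retention-time interval (min), within the
#'   trace span and containing at least two sampled points.
#' @return Peak area (intensity x min), >= 0.
#' @export
integrate_peak <- function(trace, window) {
  stopifnot(is.data.frame(trace), all(c("time_min", "intensity") %in%
                                        names(trace)))
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("window must be an increasing interval c(from, to)", call. = FALSE)
  }
  t <- trace$time_min
  if (window[1L] < min(t) || window[2L] > max(t)) {
    stop("window lies outside the trace span", call. = FALSE)
  }
  inside <- t >= window[1L] & t <= window[2L]
  if (sum(inside) < 2L) stop("window contains fewer than two points",
                             call. = FALSE)
  baseline <- stats::median(trace$intensity[!inside])
  if (!is.finite(baseline)) baseline <- 0
  ti <- t[inside]
  yi <- trace$intensity[inside] - baseline
  area <- sum(diff(ti) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
  max(0, area)
}

#' Analyte / internal-standard response ratio
#'
#' The dimensionless quantity carried through calibration and
#' quantification. Invariant to any multiplicative loss shared by analyte
#' and IS -- the principle the homolog-IS design rests on.
#'
#' @param analyte_area,is_area Quantifier peak areas.
#' @return `analyte_area / is_area`, vectorized.
#' @export
response_ratio <- function(analyte_area, is_area) {
  if (any(!is.finite(is_area) | is_area <= 0)) {
    stop("internal-standard area must be > 0 (unusable sample)",
         call. = FALSE)
  }
  analyte_area / is_area
}

#' Fit an internal-standard calibration curve
#'
#' Weighted least squares of response ratio against nominal concentration,
#' `ratio = slope * conc + intercept`. The default `1/x^2` weighting is the
#' bioanalytical standard for curves spanning three orders of magnitude: it
#' equalises relative (rather than absolute) residuals, protecting
#' back-calculated accuracy at the low end.
#'
#' @param conc Nominal concentrations (ug/mL); at least 5 distinct levels.
#' @param ratio Response ratios (same length; replicates share a `conc`
#'   value).
#' @param weighting `"1/x^2"`, `"1/x"` or `"none"`.
#' @param protein Optional label carried into the result.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `weighting`, `protein`, `levels` (a data frame with per-level mean
#'   back-calculated accuracy %), and the underlying `fit`.
#' @export
fit_calibration <- function(conc, ratio, weighting = c("1/x^2", "1/x", "none"),
                            protein = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(conc) == length(ratio), all(conc > 0))
  if (length(unique(conc)) < 5L) {
    stop("at least 5 distinct calibration levels are required", call. = FALSE)
  }
  w <- switch(weighting, "1/x^2" = 1 / conc^2, "1/x" = 1 / conc, "none" = NULL)
  fit <- stats::lm(ratio ~ conc, weights = w)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration fit produced a non-positive slope", call. = FALSE)
  }
  back <- (ratio - intercept) / slope
  acc <- 100 * back / conc
  lev <- stats::aggregate(acc, list(conc = conc), mean)
  levels_df <- data.frame(conc_ug_ml = lev$conc, accuracy_pct = lev$x)
  structure(list(protein = protein, slope = slope, intercept = intercept,
                 weighting = weighting, levels = levels_df, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve%s: ratio = %.6g * conc %+.3g (weighting %s, %d levels)\n",
    if (is.na(x$protein)) "" else paste0(" [", x$protein, "]"),
    x$slope, x$intercept, x$weighting, nrow(x$levels)))
  print(x$levels, ...)
  invisible(x)
}

#' Back-calculate concentrations from response ratios
#'
#' Inverts the calibration line. Negative back-calculated values are clamped
#' to zero and flagged `"clamped"`; values above the top calibration level
#' are flagged `"extrapolated_high"` but returned.
#'
#' @param ratio Response ratio(s), >= 0.
#' @param curve A [fit_calibration()] result.
#' @param volume_ml Optional sample volume; adds an `amount_ug` column.
#' @return Data frame: `ratio`, `conc_ug_ml`, `flag` (and `amount_ug`).
#' @export
quantify <- function(ratio, curve, volume_ml = NULL) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a fitted calibration_curve", call. = FALSE)
  }
  stopifnot(all(ratio >= 0))
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  flag[conc < 0] <- "clamped"
  conc[conc < 0] <- 0
  top <- max(curve$levels$conc_ug_ml)
  flag[conc > top] <- "extrapolated_high"
  out <- data.frame(ratio = ratio, conc_ug_ml = conc, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(volume_ml)) out$amount_ug <- conc * volume_ml
  out
}

#' Estimate the wetted-length-to-volume conversion factor
#'
#' Least-squares slope through the origin of wetted length against deposited
#' volume (a dry strip has zero wetted length, so the line is anchored
#' there). The quoted SD is the scatter of the per-observation length/volume
#' ratios, matching how a "ratio +/- SD" is conventionally reported for this
#' measurement.
#'
#' @param volume_ul Deposited volumes (uL); at least 3 distinct values.
#' @param length_mm Measured wetted lengths (mm), same length.
#' @return A `conversion_factor`: list with `estimate` (mm/uL), `sd`,
#'   `volumes`, `n`.
#' @export
estimate_conversion_factor <- function(volume_ul, length_mm) {
  stopifnot(length(volume_ul) == length(length_mm), all(volume_ul > 0))
  if (length(unique(volume_ul)) < 3L) {
    stop("at least 3 distinct volumes are required", call. = FALSE)
  }
  est <- sum(volume_ul * length_mm) / sum(volume_ul^2)
  structure(list(estimate = est, sd = stats::sd(length_mm / volume_ul),
                 volumes = sort(unique(volume_ul)), n = length(volume_ul)),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Conversion factor: %.3f mm/uL (SD %.3f, n = %d over %d volumes)\n",
              x$estimate, x$sd, x$n, length(x$volumes)))
  invisible(x)
}

#' Convert a wetted length to the adsorbed volume
#'
#' @param length_mm Wetted length(s), >= 0.
#' @param factor A `conversion_factor` or a positive number (mm/uL).
#' @return Volume(s) in uL.
#' @export
strip_volume <- function(length_mm, factor) {
  f <- if (inherits(factor, "conversion_factor")) factor$estimate else factor
  stopifnot(is.numeric(f), f > 0, all(length_mm >= 0))
  length_mm / f
}
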