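#' Bioanalytical validation statistics
#'
#' Elementary validation quantities used throughout method validation:
#' recovery, matrix effect, accuracy (bias) and precision (CV).
#'
#' `recovery_percent()` is the extracted amount as a percentage of the
#' reference (deposited/spiked) amount. `matrix_effect_percent()` is the
#' absolute deviation of the spiked-matrix/neat response ratio from unity,
#' in percent: a negligible matrix effect reads as a small number (1-3%),
#' not as a ratio near 100%. `bias_percent()` is the signed relative error
#' of a measured value against its expected value, in percent.
#' `cv_percent()` is the sample standard deviation (n - 1) over the mean, in
#' percent.
#'
#' @param extracted,reference Amounts (same units), `reference > 0`.
#' @return A percentage (vectorized where meaningful).
#' @name validation_stats
NULL

#' @rdname validation_stats
#' @export
recovery_percent <- function(extracted, reference) {
  if (any(reference <= 0)) stop("reference amount must be > 0", call. = FALSE)
  100 * extracted / reference
}

#' @rdname validation_stats
#' @param spiked,neat Instrument responses in spiked extraction buffer and in
#'   neat standard solution, `neat > 0`.
#' @export
matrix_effect_percent <- function(spiked, neat) {
  if (any(neat <= 0)) stop("neat response must be > 0", call. = FALSE)
  100 * abs(spiked / neat - 1)
}

#' @rdname validation_stats
#' @param measured,expected Measured and expected values, `expected > 0`.
#' @export
bias_percent <- function(measured, expected) {
  if (any(expected <= 0)) stop("expected value must be > 0", call. = FALSE)
  100 * (measured - expected) / expected
}

#' @rdname validation_stats
#' @param values At least two replicate values with non-zero mean.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("at least 2 replicates are required",
                                call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Estimate LOD and LOQ from a step-wise dilution series
#'
#' Signal-to-noise convention: the limit of detection is the lowest tested
#' concentration whose mean response reaches 3 x the noise SD; the limit of
#' quantification additionally requires 10 x the noise SD and a replicate
#' CV no worse than `cv_gate` (default 20%). Concentrations may be supplied
#' in any unit; the result is reported in the same unit.
#'
#' @param conc Tested concentrations (one value per response row).
#' @param response Replicate responses, same length as `conc`.
#' @param noise_sd Blank/baseline noise SD (> 0), same response units.
#' @param cv_gate Maximum CV% allowed at the LOQ.
#' @return List with `lod`, `loq` (NA with `reached = FALSE` in the
#'   corresponding `lod_reached`/`loq_reached` fields when no level
#'   qualifies, alongside `lowest_tested`), guaranteed `loq >= lod` when both
#'   are reached.
#' @export
estimate_lod_loq <- function(conc, response, noise_sd, cv_gate = 20) {
  stopifnot(length(conc) == length(response))
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  levels <- sort(unique(conc))
  mean_resp <- vapply(levels, function(l) mean(response[conc == l]),
                      numeric(1L))
  cv_resp <- vapply(levels, function(l) {
    v <- response[conc == l]
    if (length(v) < 2L) 0 else 100 * stats::sd(v) / mean(v)
  }, numeric(1L))
  lod_ok <- mean_resp >= 3 * noise_sd
  loq_ok <- mean_resp >= 10 * noise_sd & cv_resp <= cv_gate
  lod <- if (any(lod_ok)) levels[which(lod_ok)[1L]] else NA_real_
  loq <- if (any(loq_ok)) levels[which(loq_ok)[1L]] else NA_real_
  # a quantifiable level is by construction detectable; enforce the ordering
  if (!is.na(lod) && !is.na(loq) && loq < lod) loq <- lod
  list(lod = lod, loq = loq, lod_reached = !is.na(lod),
       loq_reached = !is.na(loq), lowest_tested = levels[1L])
}

#' Compare direct and strip-extraction quantification
#'
#' Per-sample signed bias of the strip result against the direct result
#' (direct analysis is the reference), and a one-way ANOVA between the two
#' method groups per protein. With two groups the ANOVA is equivalent to an
#' unpaired two-sample t-test (F = t^2); it is deliberately the textbook
#' unpaired form.
#'
#' @param paired Data frame with columns `sample`, `protein`, `direct`,
#'   `strip` (quantified concentrations); at least 3 complete pairs per
#'   protein, no missing values.
#' @return A `method_comparison`: list with `per_sample` (adds `bias_pct`),
#'   `max_abs_bias_pct`, and `anova` (per protein: `F`, `p`, `n`).
#' @export
compare_methods <- function(paired) {
  needed <- c("sample", "protein", "direct", "strip")
  stopifnot(all(needed %in% names(paired)))
  if (anyNA(paired[, c("direct", "strip")])) {
    stop("unpaired or missing measurements in method comparison",
         call. = FALSE)
  }
  per_sample <- paired
  per_sample$bias_pct <- bias_percent(paired$strip, paired$direct)
  anova_rows <- lapply(split(paired, paired$protein), function(d) {
    if (nrow(d) < 3L) {
      stop(sprintf("fewer than 3 pairs for protein %s", d$protein[1L]),
           call. = FALSE)
    }
    values <- c(d$direct, d$strip)
    group <- factor(rep(c("direct", "strip"), each = nrow(d)))
    av <- stats::anova(stats::lm(values ~ group))
    data.frame(protein = d$protein[1L], F = av[["F value"]][1L],
               p = av[["Pr(>F)"]][1L], n = nrow(d),
               stringsAsFactors = FALSE)
  })
  anova_df <- do.call(rbind, anova_rows)
  rownames(anova_df) <- NULL
  structure(list(per_sample = per_sample,
                 max_abs_bias_pct = max(abs(per_sample$bias_pct)),
                 anova = anova_df),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Direct vs strip comparison over %d measurements\n",
              nrow(x$per_sample)))
  cat(sprintf("  max |Bias%%| = %.2f\n", x$max_abs_bias_pct))
  for (i in seq_len(nrow(x$anova))) {
    cat(sprintf("  %s: one-way ANOVA F = %.3g, p = %.3g (n = %d pairs)\n",
                x$anova$protein[i], x$anova$F[i], x$anova$p[i], x$anova$n[i]))
  }
  invisible(x)
}

#' Run the full validation battery on a synthetic study bundle
#'
#' Fits per-protein IS calibration curves from the bundle's calibration set,
#' back-calculates QC amounts and tear concentrations, and assembles the
#' method-validation report: Rec% (mean +/- SD) per protein and QC level,
#' ME% per protein and level, Bias% and CV% per protein and QC level,
#' LOD/LOQ per protein, the wetted-length conversion factor, and the
#' direct-vs-strip method comparison.
#'
#' @param bundle A study bundle from [generate_study()] (or read back with
#'   [read_study_bundle()]).
#' @param weighting Calibration weighting, see [fit_calibration()].
#' @return A `validation_report` list: `curves`, `recovery`, `matrix_effect`,
#'   `qc_accuracy` (Bias%/CV% per protein x level), `lod_loq`,
#'   `conversion_factor`, `comparison`, `tears` (per-sample quantifications).
#' @export
validate_study <- function(bundle, weighting = "1/x^2") {
  cfg <- bundle$config
  proteins <- unique(bundle$calibration$protein)

  curves <- lapply(stats::setNames(proteins, proteins), function(p) {
    d <- bundle$calibration[bundle$calibration$protein == p, ]
    fit_calibration(d$level_ug_ml, d$analyte_area / d$is_area,
                    weighting = weighting, protein = p)
  })

  # QC accuracy & precision: quantified extract amount vs nominal deposit
  qc <- bundle$qc
  qc$ratio <- qc$analyte_area / qc$is_area
  qc_rows <- list(); rec_rows <- list()
  for (p in proteins) {
    for (lev in unique(qc$level)) {
      d <- qc[qc$protein == p & qc$level == lev, ]
      q <- quantify(d$ratio, curves[[p]], volume_ml = cfg$extraction_volume_ml)
      nominal <- d$deposited_ug[1L]
      qc_rows[[paste(p, lev)]] <- data.frame(
        protein = p, level = lev, nominal_ug = nominal,
        mean_measured_ug = mean(q$amount_ug),
        bias_pct = bias_percent(mean(q$amount_ug), nominal),
        cv_pct = cv_percent(q$amount_ug), n = nrow(d),
        stringsAsFactors = FALSE
      )
      rec <- recovery_percent(d$extracted_ug, d$deposited_ug)
      rec_rows[[paste(p, lev)]] <- data.frame(
        protein = p, level = lev, mean_rec_pct = mean(rec),
        sd_rec_pct = stats::sd(rec), n = nrow(d), stringsAsFactors = FALSE
      )
    }
  }
  qc_accuracy <- do.call(rbind, qc_rows); rownames(qc_accuracy) <- NULL
  recovery <- do.call(rbind, rec_rows); rownames(recovery) <- NULL

  # matrix effect per protein x level from mean responses
  me <- bundle$matrix_effect
  me_rows <- lapply(split(me, list(me$protein, me$level), drop = TRUE),
                    function(d) {
    data.frame(protein = d$protein[1L], level = d$level[1L],
               me_pct = matrix_effect_percent(mean(d$matrix_area),
                                              mean(d$neat_area)),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  matrix_effect <- do.call(rbind, me_rows); rownames(matrix_effect) <- NULL

  # LOD / LOQ from the dilution series (responses in area units, conc ng/mL)
  noise_sd <- max(cfg$instrument$baseline_sd, .Machine$double.eps)
  lod_rows <- lapply(stats::setNames(proteins, proteins), function(p) {
    d <- bundle$dilution[bundle$dilution$protein == p, ]
    r <- estimate_lod_loq(d$conc_ng_ml, d$analyte_area, noise_sd = noise_sd)
    data.frame(protein = p, lod_ng_ml = r$lod, loq_ng_ml = r$loq,
               lod_reached = r$lod_reached, loq_reached = r$loq_reached,
               stringsAsFactors = FALSE)
  })
  lod_loq <- do.call(rbind, lod_rows); rownames(lod_loq) <- NULL

  cf <- estimate_conversion_factor(bundle$wetting$volume_ul,
                                   bundle$wetting$length_mm)

  # paired direct / strip quantification of the tear samples
  tears <- bundle$tears
  direct_q <- strip_q <- numeric(nrow(tears))
  for (i in seq_len(nrow(tears))) {
    p <- tears$protein[i]
    direct_q[i] <- quantify(tears$direct_analyte_area[i] /
                              tears$direct_is_area[i], curves[[p]])$conc_ug_ml
    amt <- quantify(tears$strip_analyte_area[i] / tears$strip_is_area[i],
                    curves[[p]],
                    volume_ml = cfg$extraction_volume_ml)$amount_ug
    strip_q[i] <- amt / (tears$volume_ul[i] / 1000)
  }
  tears$direct_conc <- direct_q
  tears$strip_conc <- strip_q
  comparison <- compare_methods(data.frame(
    sample = tears$sample, protein = tears$protein,
    direct = direct_q, strip = strip_q, stringsAsFactors = FALSE
  ))

  structure(list(curves = curves, recovery = recovery,
                 matrix_effect = matrix_effect, qc_accuracy = qc_accuracy,
                 lod_loq = lod_loq, conversion_factor = cf,
                 comparison = comparison, tears = tears),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Method validation report ==\n\n-- QC accuracy & precision --\n")
  print(x$qc_accuracy, digits = 4)
  cat("\n-- Recovery (mean +/- SD, %) --\n")
  print(x$recovery, digits = 4)
  cat("\n-- Matrix effect (%) --\n")
  print(x$matrix_effect, digits = 3)
  cat("\n-- LOD / LOQ --\n")
  print(x$lod_loq, digits = 3)
  cat("\n-- Strip conversion factor --\n")
  print(x$conversion_factor)
  cat("\n-- Direct vs strip --\n")
  print(x$comparison)
  invisible(x)
}
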