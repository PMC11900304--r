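#' Study design configuration
#'
#' Collects every design parameter of the synthetic tear-protein study. The
#' defaults reproduce the reference design: a seven-point calibration curve
#' (0.1, 0.5, 1, 5, 10, 50, 100 ug/mL) with IS fixed at 2 ug/mL, QC strips
#' at 0.2 / 2 / 20 ug per protein in 20 uL with 2 ug of each IS in 10 uL,
#' 20 paired direct/strip tear samples, a 2 x 0.5 mL extraction (pooled to
#' 1 mL), and a triplicate wetting series over 5-40 uL.
#'
#' Two IS conventions coexist in the reference design -- a fixed amount
#' (2 ug per strip) for QC and real samples, and a fixed concentration
#' (2 ug/mL) for calibration standards -- so both are separate fields here
#' (`is_amount_ug`, `is_curve_conc_ug_ml`) rather than reconciled.
#'
#' @param n_tears Number of paired tear samples.
#' @param tear_profile,tear_volume_range See [simulate_tear_samples()].
#' @param calibration_levels Nominal curve concentrations (ug/mL).
#' @param calibration_replicates Replicates per curve level.
#' @param is_curve_conc_ug_ml IS concentration in calibration standards.
#' @param qc_amounts_ug Named deposited amounts for the QC levels (ug).
#' @param qc_replicates QC replicates per level.
#' @param qc_volume_ul Deposition volume for QCs (uL).
#' @param is_amount_ug,is_volume_ul IS amount (ug) and volume (uL) added to
#'   each strip.
#' @param extraction_volume_ml Total pooled extract volume (2 x 0.5 mL).
#' @param wetting_volumes,wetting_replicates Conversion-factor design.
#' @param dilution_series_ng_ml,dilution_replicates LOD/LOQ dilution design.
#' @param me_levels_ug_ml,me_replicates Matrix-effect design.
#' @param strip,extraction,instrument Component models.
#' @param weighting Calibration weighting.
#' @return A `study_config` list.
#' @export
study_config <- function(
    n_tears = 20,
    tear_profile = NULL,
    tear_volume_range = c(10, 30),
    calibration_levels = c(0.1, 0.5, 1, 5, 10, 50, 100),
    calibration_replicates = 1,
    is_curve_conc_ug_ml = 2,
    qc_amounts_ug = c(low = 0.2, medium = 2, high = 20),
    qc_replicates = 3,
    qc_volume_ul = 20,
    is_amount_ug = 2,
    is_volume_ul = 10,
    extraction_volume_ml = 1,
    wetting_volumes = seq(5, 40, by = 5),
    wetting_replicates = 3,
    dilution_series_ng_ml = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10),
    dilution_replicates = 3,
    me_levels_ug_ml = c(0.2, 2, 20),
    me_replicates = 3,
    strip = strip_model(),
    extraction = extraction_model("Buffer B"),
    instrument = instrument_model(),
    weighting = "1/x^2") {
  errs <- character(0)
  if (n_tears < 1) errs <- c(errs, "n_tears: must be >= 1")
  if (length(calibration_levels) < 5) {
    errs <- c(errs, "calibration_levels: at least 5 levels required")
  }
  if (is.null(names(qc_amounts_ug)) || any(names(qc_amounts_ug) == "")) {
    errs <- c(errs, "qc_amounts_ug: must be a named vector")
  }
  if (qc_replicates < 2) errs <- c(errs, "qc_replicates: must be >= 2")
  if (extraction_volume_ml <= 0) {
    errs <- c(errs, "extraction_volume_ml: must be > 0")
  }
  if (!inherits(strip, "strip_model")) errs <- c(errs, "strip: not a strip_model")
  if (!inherits(extraction, "extraction_model")) {
    errs <- c(errs, "extraction: not an extraction_model")
  }
  if (!inherits(instrument, "instrument_model")) {
    errs <- c(errs, "instrument: not an instrument_model")
  }
  if (length(errs) > 0L) {
    stop("invalid study config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(
    n_tears = n_tears, tear_profile = tear_profile,
    tear_volume_range = tear_volume_range,
    calibration_levels = calibration_levels,
    calibration_replicates = calibration_replicates,
    is_curve_conc_ug_ml = is_curve_conc_ug_ml,
    qc_amounts_ug = qc_amounts_ug, qc_replicates = qc_replicates,
    qc_volume_ul = qc_volume_ul, is_amount_ug = is_amount_ug,
    is_volume_ul = is_volume_ul, extraction_volume_ml = extraction_volume_ml,
    wetting_volumes = wetting_volumes,
    wetting_replicates = wetting_replicates,
    dilution_series_ng_ml = dilution_series_ng_ml,
    dilution_replicates = dilution_replicates,
    me_levels_ug_ml = me_levels_ug_ml, me_replicates = me_replicates,
    strip = strip, extraction = extraction, instrument = instrument,
    weighting = weighting
  ), class = "study_config")
}

#' Generate a complete synthetic study bundle
#'
#' Simulates every dataset the downstream pipeline consumes: the calibration
#' set (neat standards + IS), QC strips at three levels (deposited ->
#' extracted -> measured, truths retained), paired direct/strip tear
#' samples, the conversion-factor wetting series, a dilution series for
#' LOD/LOQ, and spiked-buffer vs neat responses for the matrix effect. The
#' master seed fans out to fixed per-stage child seeds, so each stage is
#' individually reproducible.
#'
#' @param config A [study_config()].
#' @param seed Master RNG seed (integer).
#' @return A `tear_study` list: `config`, `seed`, and data frames
#'   `calibration`, `qc`, `tears`, `wetting`, `dilution`, `matrix_effect`.
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  analytes <- names(cfg$instrument$response)

  # stage 1: calibration standards (neat, direct workflow)
  .set_seed(.child_seed(seed, 1L))
  cal_rows <- list()
  for (r in seq_len(cfg$calibration_replicates)) {
    for (lev in cfg$calibration_levels) {
      m <- simulate_measurement(
        stats::setNames(rep(lev, length(analytes)), analytes),
        is_conc = cfg$is_curve_conc_ug_ml, instrument = cfg$instrument,
        workflow = "direct")
      m$level_ug_ml <- lev; m$replicate <- r
      cal_rows[[length(cal_rows) + 1L]] <- m
    }
  }
  calibration <- do.call(rbind, cal_rows)

  # stage 2: QC strips
  .set_seed(.child_seed(seed, 2L))
  qc_rows <- list()
  for (lev in names(cfg$qc_amounts_ug)) {
    for (r in seq_len(cfg$qc_replicates)) {
      dep <- stats::setNames(rep(cfg$qc_amounts_ug[[lev]], length(analytes)),
                             analytes)
      isd <- stats::setNames(rep(cfg$is_amount_ug, length(analytes)), analytes)
      ext <- simulate_extraction(dep, cfg$extraction, is_deposited = isd)
      m <- simulate_measurement(ext$analyte / cfg$extraction_volume_ml,
                                is_conc = ext$is / cfg$extraction_volume_ml,
                                instrument = cfg$instrument,
                                workflow = "strip")
      m$level <- lev; m$replicate <- r
      m$deposited_ug <- dep[m$protein]
      m$extracted_ug <- ext$analyte[m$protein]
      m$is_extracted_ug <- ext$is[m$protein]
      qc_rows[[length(qc_rows) + 1L]] <- m
    }
  }
  qc <- do.call(rbind, qc_rows)

  # stage 3: paired direct / strip tear samples
  .set_seed(.child_seed(seed, 3L))
  samples <- simulate_tear_samples(cfg$n_tears, cfg$tear_profile,
                                   cfg$tear_volume_range)
  tear_rows <- list()
  for (i in seq_len(nrow(samples))) {
    truth <- unlist(samples[i, analytes])
    direct <- simulate_measurement(truth, is_conc = cfg$is_curve_conc_ug_ml,
                                   instrument = cfg$instrument,
                                   workflow = "direct")
    vol <- samples$volume_ul[i]
    length_mm <- simulate_strip_wetting(vol, cfg$strip)
    dep <- truth * vol / 1000
    isd <- stats::setNames(rep(cfg$is_amount_ug, length(analytes)), analytes)
    ext <- simulate_extraction(dep, cfg$extraction, is_deposited = isd)
    strip <- simulate_measurement(ext$analyte / cfg$extraction_volume_ml,
                                  is_conc = ext$is / cfg$extraction_volume_ml,
                                  instrument = cfg$instrument,
                                  workflow = "strip")
    tear_rows[[i]] <- data.frame(
      sample = samples$sample[i], protein = direct$protein,
      true_conc_ug_ml = as.numeric(truth[direct$protein]),
      volume_ul = vol, length_mm = length_mm,
      direct_analyte_area = direct$analyte_area,
      direct_is_area = direct$is_area,
      strip_analyte_area = strip$analyte_area,
      strip_is_area = strip$is_area,
      stringsAsFactors = FALSE
    )
  }
  tears <- do.call(rbind, tear_rows)

  # stage 4: conversion-factor wetting series
  .set_seed(.child_seed(seed, 4L))
  wetting <- simulate_wetting_series(cfg$wetting_volumes,
                                     cfg$wetting_replicates, cfg$strip)

  # stage 5: LOD/LOQ dilution series (IS-free neat injections)
  .set_seed(.child_seed(seed, 5L))
  dil_rows <- list()
  for (r in seq_len(cfg$dilution_replicates)) {
    for (cng in cfg$dilution_series_ng_ml) {
      m <- simulate_measurement(
        stats::setNames(rep(cng / 1000, length(analytes)), analytes),
        is_conc = NULL, instrument = cfg$instrument, workflow = "direct")
      m$conc_ng_ml <- cng; m$replicate <- r
      dil_rows[[length(dil_rows) + 1L]] <- m
    }
  }
  dilution <- do.call(rbind, dil_rows)

  # stage 6: matrix effect (spiked extraction buffer vs neat standard)
  .set_seed(.child_seed(seed, 6L))
  me_rows <- list()
  for (r in seq_len(cfg$me_replicates)) {
    for (lev in cfg$me_levels_ug_ml) {
      conc <- stats::setNames(rep(lev, length(analytes)), analytes)
      neat <- simulate_measurement(conc, is_conc = NULL,
                                   instrument = cfg$instrument,
                                   workflow = "direct")
      mat <- simulate_measurement(conc, is_conc = NULL,
                                  instrument = cfg$instrument,
                                  workflow = "strip")
      me_rows[[length(me_rows) + 1L]] <- data.frame(
        protein = neat$protein, level = lev, replicate = r,
        neat_area = neat$analyte_area, matrix_area = mat$analyte_area,
        stringsAsFactors = FALSE
      )
    }
  }
  matrix_effect <- do.call(rbind, me_rows)

  for (d in c("calibration", "qc", "tears", "dilution", "matrix_effect")) {
    assign(d, { x <- get(d); rownames(x) <- NULL; x })
  }
  structure(list(config = cfg, seed = seed, calibration = calibration,
                 qc = qc, tears = tears, wetting = wetting,
                 dilution = dilution, matrix_effect = matrix_effect),
            class = "tear_study")
}

.BUNDLE_TABLES <- c("calibration", "qc", "tears", "wetting", "dilution",
                    "matrix_effect")

#' Write / read a study bundle as delimited tables plus a manifest
#'
#' Each component data frame is written as a CSV; `manifest.json` records
#' the seed, the file list and a snapshot of the configuration, which is
#' sufficient to regenerate the bundle byte-identically with
#' [generate_study()].
#'
#' @param bundle A `tear_study`.
#' @param dir Output directory (created if needed).
#' @return `write_study_bundle()` returns `dir` invisibly;
#'   [read_study_bundle()] returns a `tear_study` whose `config` is the
#'   manifest's plain-list snapshot.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tear_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tab in .BUNDLE_TABLES) {
    f <- file.path(dir, paste0(tab, ".csv"))
    utils::write.csv(bundle[[tab]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(seed = bundle$seed, files = files,
                   config = unclass(bundle$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list(config = manifest$config, seed = manifest$seed)
  for (tab in .BUNDLE_TABLES) {
    out[[tab]] <- utils::read.csv(file.path(dir, paste0(tab, ".csv")),
                                  stringsAsFactors = FALSE)
  }
  class(out) <- "tear_study"
  out
}
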