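test_that("tear samples: range containment, cohort size, determinism", {
  s1 <- simulate_tear_samples(seed = 1)
  expect_equal(nrow(s1), 20)
  for (p in c("Albumin", "Lactoferrin", "Lysozyme")) {
    expect_true(all(s1[[p]] >= 5 & s1[[p]] <= 50))
  }
  s2 <- simulate_tear_samples(seed = 1)
  expect_identical(s1, s2)
  expect_error(
    simulate_tear_samples(profile = list(Albumin = c(10, 5))), "range")
})

test_that("strip wetting: exact arithmetic, truncation at zero", {
  expect_equal(simulate_strip_wetting(10, strip_model(length_sd = 0)), 11.5)
  noisy <- simulate_strip_wetting(rep(0.001, 500),
                                  strip_model(length_sd = 5), seed = 2)
  expect_true(all(noisy >= 0))
  ser <- simulate_wetting_series(seed = 3)
  expect_equal(sort(unique(ser$volume_ul)), seq(5, 40, by = 5))
  expect_equal(nrow(ser), 24)
})

test_that("extraction: exact recovery arithmetic and identity", {
  m0 <- extraction_model("Buffer B",
                         cv = c(Albumin = 0, Lactoferrin = 0, Lysozyme = 0))
  ext <- simulate_extraction(c(Albumin = 2), m0)
  expect_equal(unname(ext$analyte), 1.9)
  ident <- extraction_model("Buffer B",
                            recovery = c(Albumin = 1), cv = c(Albumin = 0))
  expect_equal(unname(simulate_extraction(c(Albumin = 2), ident)$analyte), 2)
  expect_error(simulate_extraction(c(Transferrin = 1), m0), "Transferrin")
  expect_error(extraction_model("Buffer C"))
})

test_that("mean recovery converges to the model mean (law of large numbers)", {
  model <- extraction_model("Buffer B")
  set.seed(4)
  recs <- replicate(1000, {
    simulate_extraction(c(Albumin = 2, Lactoferrin = 2, Lysozyme = 2),
                        model)$analyte / 2
  })
  for (p in rownames(recs)) {
    se <- model$recovery[p] * model$cv[p] / sqrt(ncol(recs))
    expect_lt(abs(mean(recs[p, ]) - model$recovery[p]), 3 * se)
  }
})

test_that("IS tracking 1 means the IS shares the analyte recovery draw", {
  model <- extraction_model("Buffer B")
  set.seed(5)
  ext <- simulate_extraction(c(Albumin = 2), model, is_deposited = c(Albumin = 2))
  expect_equal(ext$analyte, ext$is, tolerance = 1e-12)
})

test_that("measurement model: baseline-only at zero, linearity, matrix shift", {
  inst <- instrument_model(area_cv = 0, digestion_cv = 0, baseline_sd = 1)
  zero <- simulate_measurement(c(Albumin = 0, Lysozyme = 0), instrument = inst,
                               seed = 6)
  expect_true(all(zero$analyte_area >= 0 & zero$analyte_area < 5))
  noiseless <- instrument_model(area_cv = 0, digestion_cv = 0, baseline_sd = 0)
  a1 <- simulate_measurement(c(Albumin = 1), instrument = noiseless)
  a2 <- simulate_measurement(c(Albumin = 2), instrument = noiseless)
  expect_equal(a2$analyte_area, 2 * a1$analyte_area, tolerance = 1e-12)
  # matrix factor 1.025 yields a +2.5% shift against the neat response
  inst2 <- instrument_model(area_cv = 0, digestion_cv = 0, baseline_sd = 0,
                            matrix_factor = c(Albumin = 1.025))
  neat <- simulate_measurement(c(Albumin = 10), instrument = inst2,
                               workflow = "direct")
  mat <- simulate_measurement(c(Albumin = 10), instrument = inst2,
                              workflow = "strip")
  expect_equal(mat$analyte_area / neat$analyte_area, 1.025, tolerance = 1e-12)
  expect_error(
    simulate_measurement(c(Albumin = 1), is_conc = c(Lysozyme = 2)),
    "Albumin")
})

test_that("chromatogram synthesis integrates back to the requested area", {
  tr <- simulate_chromatogram(1000, rt_min = 9.85,
                              instrument = instrument_model(baseline_sd = 0))
  expect_equal(nrow(tr), 600)
  expect_equal(integrate_peak(tr, c(9.35, 10.35)), 1000, tolerance = 0.01)
})

test_that("study bundles are byte-identical under a fixed (config, seed)", {
  cfg <- study_config(n_tears = 4, qc_replicates = 2,
                      dilution_replicates = 2, me_replicates = 2)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_study_bundle(generate_study(cfg, 99), d1)
  write_study_bundle(generate_study(cfg, 99), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes draws but not the design structure
  b3 <- generate_study(cfg, 100)
  b1 <- read_study_bundle(d1)
  expect_equal(dim(b3$calibration), dim(b1$calibration))
  expect_false(isTRUE(all.equal(b3$calibration$analyte_area,
                                b1$calibration$analyte_area)))
  expect_equal(sort(unique(b3$calibration$level_ug_ml)),
               c(0.1, 0.5, 1, 5, 10, 50, 100))
})

test_that("round-tripped bundles validate identically", {
  cfg <- study_config(n_tears = 4, qc_replicates = 2)
  b <- generate_study(cfg, 11)
  d <- file.path(tempdir(), "bundle_rt")
  write_study_bundle(b, d)
  r1 <- validate_study(b)
  r2 <- validate_study(read_study_bundle(d))
  expect_equal(r1$qc_accuracy, r2$qc_accuracy, tolerance = 1e-9)
  expect_equal(r1$comparison$max_abs_bias_pct, r2$comparison$max_abs_bias_pct,
               tolerance = 1e-9)
})

test_that("noiseless end-to-end identity: truths recovered exactly", {
  rep <- validate_study(generate_study(noiseless_config(), 1))
  expect_equal(rep$qc_accuracy$bias_pct, rep(0, 9), tolerance = 1e-9)
  expect_equal(rep$qc_accuracy$cv_pct, rep(0, 9), tolerance = 1e-9)
  expect_equal(rep$tears$direct_conc, rep$tears$true_conc_ug_ml,
               tolerance = 1e-9)
  expect_equal(rep$tears$strip_conc, rep$tears$true_conc_ug_ml,
               tolerance = 1e-9)
  expect_equal(rep$conversion_factor$estimate, 1.15, tolerance = 1e-12)
  # zero-noise limit: LOD = LOQ = lowest tested level
  expect_equal(rep$lod_loq$lod_ng_ml, rep(0.05, 3))
  expect_equal(rep$lod_loq$loq_ng_ml, rep(0.05, 3))
})
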