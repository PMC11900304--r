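# Independent oracles kept deliberately naive: they never share code with
# the implementation paths they check.

# brute-force tryptic digest: enumerate every substring, keep those whose
# boundaries are cleavage boundaries and count internal uncleaved sites
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- function(i) {
    i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  }
  out <- list()
  for (a in 1:n) {
    for (b in a:n) {
      left_ok <- a == 1 || is_site(a - 1)
      right_ok <- b == n || is_site(b)
      if (!left_ok || !right_ok) next
      internal <- if (b > a) sum(vapply(a:(b - 1), is_site, logical(1))) else 0
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(
          peptide = paste(res[a:b], collapse = ""),
          start = a, end = b, missed_cleavages = internal,
          stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$missed_cleavages), , drop = FALSE]
}

# random peptide with canonical residues, fixed alphabet
random_peptide <- function(len, exclude = character(0)) {
  ab <- setdiff(names(residue_masses()), exclude)
  paste(sample(ab, len, replace = TRUE), collapse = "")
}

# closed-form mass re-derivation used as the m/z oracle
oracle_peptide_mass <- function(sequence) {
  m <- residue_masses()
  sum(m[strsplit(sequence, "")[[1]]]) + MASS_WATER
}

# an all-noise-off study configuration (the identity world)
noiseless_config <- function(...) {
  study_config(
    strip = strip_model(length_sd = 0),
    extraction = extraction_model(
      "Buffer B",
      cv = c(Albumin = 0, Lactoferrin = 0, Lysozyme = 0)),
    instrument = instrument_model(area_cv = 0, digestion_cv = 0,
                                  baseline_sd = 0),
    ...
  )
}

# does a default-noise study meet the headline validation thresholds?
study_meets_thresholds <- function(seed) {
  rep <- validate_study(generate_study(study_config(), seed))
  all(abs(rep$qc_accuracy$bias_pct) < 5) &&
    all(rep$qc_accuracy$cv_pct < 5) &&
    rep$comparison$max_abs_bias_pct < 8 &&
    all(rep$comparison$anova$p > 0.05)
}
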