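#' Monoisotopic residue masses and mass-spectrometric constants
#'
#' Masses of the 20 canonical amino-acid residues (i.e. amino acids minus
#' water) in daltons, monoisotopic. Together with the proton and water
#' constants these are the only numerical inputs to the peptide and
#' fragment-ion m/z calculus. Monoisotopic (not average) masses are required
#' to reproduce triple-quadrupole MRM transition lists at one-decimal
#' precision. No fixed or variable modifications are applied anywhere in the
#' package: the bundled transition table is consistent only with unmodified
#' peptides (in particular, no carbamidomethylation of cysteine).
#'
#' @return Named numeric vector of 20 residue masses (Da), names are the
#'   one-letter residue symbols.
#' @examples
#' residue_masses()[["G"]] # 57.02146
#' @export
residue_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

#' @rdname residue_masses
#' @format NULL
#' @export
MASS_PROTON <- 1.00728

#' @rdname residue_masses
#' @format NULL
#' @export
MASS_WATER <- 18.01056

# internal: residue-mass lookup reused by every mass function
.RESMASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

# internal: validate a peptide/protein sequence, reporting the first bad
# position; returns the sequence split into single residues
.check_residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(sprintf("%s must be a non-empty character scalar", what),
         call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% names(.RESMASS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s contains non-canonical residue '%s' at position %d",
      what, res[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  res
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R),
#' suppressed when the following residue is proline (the standard trypsin
#' specificity). Peptides carrying up to `max_missed_cleavages` internal
#' uncleaved K/R sites are enumerated as well.
#'
#' @param sequence Protein sequence, canonical one-letter residues only.
#' @param max_missed_cleavages Maximum number of missed cleavage sites per
#'   reported peptide (>= 0).
#' @return A data frame with one row per peptide: `peptide`, `start`, `end`
#'   (1-based positions in `sequence`) and `missed_cleavages`, ordered by
#'   start position then missed-cleavage count. With
#'   `max_missed_cleavages = 0` the peptides partition the input:
#'   concatenating them in order reconstructs `sequence`.
#' @examples
#' digest("AKRPGKSTR", 0)$peptide    # "AK" "RPGK" "STR"
#' digest("KLVNEVTEFAKQ", 1)$peptide
#' @export
digest <- function(sequence, max_missed_cleavages = 0L) {
  res <- .check_residues(sequence)
  if (!is.numeric(max_missed_cleavages) || length(max_missed_cleavages) != 1L ||
      is.na(max_missed_cleavages) || max_missed_cleavages < 0) {
    stop("max_missed_cleavages must be a single number >= 0", call. = FALSE)
  }
  mmc <- as.integer(max_missed_cleavages)
  n <- length(res)
  # cleavage sites: after position i when res[i] in {K, R} and res[i+1] != P
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[pmin(sites + 1L, n)] != "P"]
  # fully cleaved segment boundaries
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  nseg <- length(starts)
  out <- vector("list", 0L)
  for (i in seq_len(nseg)) {
    for (k in 0:min(mmc, nseg - i)) {
      j <- i + k
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], missed_cleavages = k,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$missed_cleavages), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, in daltons. Additive:
#' `peptide_mass(paste0(a, b)) == peptide_mass(a) + peptide_mass(b) - MASS_WATER`.
#'
#' @param sequence Peptide sequence, canonical residues only.
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' peptide_mass("LVNEVTEFAK") # 1148.608
#' @export
peptide_mass <- function(sequence) {
  res <- .check_residues(sequence, "peptide")
  sum(.RESMASS[res]) + MASS_WATER
}

#' Precursor ion m/z
#'
#' m/z of the protonated peptide: `(M + z * MASS_PROTON) / z`.
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @return m/z in Da per unit charge.
#' @examples
#' round(precursor_mz("LVNEVTEFAK", 2), 1) # 575.3
#' @export
precursor_mz <- function(sequence, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1) {
    stop("charge must be a single integer >= 1", call. = FALSE)
  }
  charge <- as.integer(charge)
  (peptide_mass(sequence) + charge * MASS_PROTON) / charge
}

#' Fragment ion m/z (b and y series)
#'
#' b ions are the N-terminal fragments (residues plus a proton per charge);
#' y ions are C-terminal and retain the peptide's water. For singly charged
#' complements, `b(i) + y(n - i) == peptide_mass + MASS_WATER + 2 * MASS_PROTON`
#' minus one water already counted -- i.e. the complementarity identity
#' `mz_b(i, 1) + mz_y(n - i, 1) == peptide_mass + 2 * MASS_PROTON` holds to
#' numerical precision.
#'
#' @param sequence Peptide sequence.
#' @param series `"b"` or `"y"`.
#' @param index Fragment length, `1 <= index <= nchar(sequence)` (the
#'   full-length y ion equals the singly protonated peptide; indices up to
#'   length - 1 are the physically observable backbone fragments).
#' @param charge Positive integer charge state (default 1).
#' @return m/z in Da per unit charge.
#' @examples
#' round(fragment_mz("LVNEVTEFAK", "y", 5), 1) # 595.3
#' round(fragment_mz("STDYGIFQINSR", "b", 3), 1) # 304.1
#' @export
fragment_mz <- function(sequence, series, index, charge = 1L) {
  res <- .check_residues(sequence, "peptide")
  series <- match.arg(series, c("b", "y"))
  n <- length(res)
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 1 || index > n) {
    stop(sprintf("fragment index must be in 1..%d", n), call. = FALSE)
  }
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1) {
    stop("charge must be a single integer >= 1", call. = FALSE)
  }
  index <- as.integer(index)
  charge <- as.integer(charge)
  resmass <- if (series == "b") {
    sum(.RESMASS[res[seq_len(index)]])
  } else {
    sum(.RESMASS[res[(n - index + 1L):n]]) + MASS_WATER
  }
  (resmass + charge * MASS_PROTON) / charge
}
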