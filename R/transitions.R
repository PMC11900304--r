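#' Select signature peptides for a protein panel
#'
#' A signature peptide is a fully tryptic peptide (0 missed cleavages) that
#' identifies exactly one protein of the analysed panel. Candidates are
#' filtered by length, by excluded residues (by default cysteine and
#' methionine, whose variable modification state makes transitions
#' unreliable), and by uniqueness: a peptide whose sequence occurs in more
#' than one panel protein is discarded for all of them. Uniqueness is
#' assessed within the panel only, not proteome-wide.
#'
#' @param panel A `protein_panel` (see [read_panel()]) or any data frame with
#'   `accession`, `protein` and `sequence` columns.
#' @param length_range Inclusive peptide length bounds, default `c(7, 25)`.
#' @param exclude_residues Residues that disqualify a peptide, default C and M.
#' @return Data frame with columns `accession`, `protein`, `peptide`. Panel
#'   proteins for which no peptide qualifies are listed in the
#'   `"unrepresented"` attribute (a character vector of accessions) rather
#'   than raising an error.
#' @export
select_signature_peptides <- function(panel, length_range = c(7L, 25L),
                                      exclude_residues = c("C", "M")) {
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  cand <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    d <- digest(panel$sequence[i], 0L)
    data.frame(accession = panel$accession[i], protein = panel$protein[i],
               peptide = d$peptide, stringsAsFactors = FALSE)
  }))
  len <- nchar(cand$peptide)
  keep <- len >= length_range[1L] & len <= length_range[2L]
  if (length(exclude_residues) > 0L) {
    pat <- paste0("[", paste(exclude_residues, collapse = ""), "]")
    keep <- keep & !grepl(pat, cand$peptide)
  }
  cand <- cand[keep, , drop = FALSE]
  # panel-wide uniqueness: peptide must occur in exactly one panel sequence
  n_hits <- vapply(cand$peptide, function(p) {
    sum(vapply(panel$sequence, function(s) grepl(p, s, fixed = TRUE),
               logical(1L)))
  }, numeric(1L))
  cand <- cand[n_hits == 1L, , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "unrepresented") <- setdiff(panel$accession, cand$accession)
  cand
}

# internal: parse a fragment annotation like "y5" or "b7^2" into
# series/index/charge; returns NULL if unparseable
.parse_annotation <- function(ann) {
  m <- regmatches(ann, regexec("^([by])([0-9]+)(\\^([0-9]+))?$", ann))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(series = m[2L], index = as.integer(m[3L]),
       charge = if (m[5L] == "") 1L else as.integer(m[5L]))
}

.TRANSITION_COLS <- c(
  "protein", "peptide", "precursor_mz", "precursor_charge", "product_mz",
  "fragment_annotation", "collision_energy", "retention_time_min", "quantifier"
)

#' Build an MRM transition table for validated signature peptides
#'
#' For each peptide the precursor charge is the smallest state in 1..3 that
#' places the precursor m/z inside the precursor window (if none does, the
#' state closest to the window is used). The default precursor window of
#' 300-725 m/z keeps precursors in the lower half of the quadrupole range so
#' that singly charged product ions of higher m/z remain observable; with
#' this window the smallest-in-window rule reproduces the declared panel
#' method's charge states (2+ throughout, 3+ for the 13-residue lactoferrin
#' peptide). Singly charged b/y fragments are ranked: ions inside the
#' product window and above the precursor m/z first (product ions heavier
#' than the precursor are insensitive to low-mass chemical noise), y series
#' before b, and within a series the smallest qualifying index first;
#' non-qualifying ions follow under the same series/index ordering so that
#' short peptides still yield the requested number of transitions. The
#' first-ranked product is flagged as the quantifier.
#'
#' @param peptides Data frame with columns `protein` and `peptide` (as
#'   returned by [select_signature_peptides()]; an `accession` column is
#'   carried through if present).
#' @param fragments_per_peptide Number of product ions per peptide.
#' @param precursor_window Precursor m/z window, default 300-725.
#' @param product_window Product-ion m/z window, default 300-1250.
#' @param collision_energy,retention_time_min Declared per-peptide metadata
#'   (recycled); never computed.
#' @return A `transition_table` data frame (provenance `"designed"`) with
#'   columns `protein`, `peptide`, `precursor_mz`, `precursor_charge`,
#'   `product_mz`, `fragment_annotation`, `collision_energy`,
#'   `retention_time_min`, `quantifier`.
#' @export
build_transition_table <- function(peptides, fragments_per_peptide = 2L,
                                   precursor_window = c(300, 725),
                                   product_window = c(300, 1250),
                                   collision_energy = NA_real_,
                                   retention_time_min = NA_real_) {
  stopifnot(nrow(peptides) >= 1L)
  ce <- rep_len(collision_energy, nrow(peptides))
  rt <- rep_len(retention_time_min, nrow(peptides))
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    n <- nchar(pep)
    if (n < 2L) stop(sprintf("peptide '%s' too short for fragmentation", pep),
                     call. = FALSE)
    prec <- vapply(1:3, function(z) precursor_mz(pep, z), numeric(1L))
    in_win <- prec >= precursor_window[1L] & prec <= precursor_window[2L]
    z <- if (any(in_win)) {
      which(in_win)[1L]
    } else {
      which.min(pmax(precursor_window[1L] - prec, prec - precursor_window[2L],
                     0))
    }
    frag <- expand.grid(series = c("y", "b"), index = seq_len(n - 1L),
                        stringsAsFactors = FALSE)
    frag$mz <- mapply(function(s, k) fragment_mz(pep, s, k, 1L),
                      frag$series, frag$index)
    frag$qualifies <- frag$mz >= product_window[1L] &
      frag$mz <= product_window[2L] & frag$mz > prec[z]
    frag <- frag[order(-frag$qualifies, frag$series == "b", frag$index), ,
                 drop = FALSE]
    frag <- utils::head(frag, fragments_per_peptide)
    rows[[i]] <- data.frame(
      protein = peptides$protein[i], peptide = pep,
      precursor_mz = prec[z], precursor_charge = z,
      product_mz = frag$mz,
      fragment_annotation = paste0(frag$series, frag$index),
      collision_energy = ce[i], retention_time_min = rt[i],
      quantifier = seq_len(nrow(frag)) == 1L,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  as_transition_table(tab, provenance = "designed")
}

#' Coerce a data frame to a transition table
#'
#' Validates the column set, uniqueness of (precursor, product) pairs and of
#' peptides per protein, and the one-quantifier-per-peptide rule.
#'
#' @param x Data frame with the transition-table columns.
#' @param provenance `"designed"` (built by [build_transition_table()]) or
#'   `"declared"` (taken from an instrument method or a publication).
#' @return A `transition_table`.
#' @export
as_transition_table <- function(x, provenance = c("declared", "designed")) {
  provenance <- match.arg(provenance)
  missing <- setdiff(.TRANSITION_COLS, names(x))
  if (length(missing) > 0L) {
    stop("transition table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[, .TRANSITION_COLS]
  if (anyDuplicated(x[, c("precursor_mz", "product_mz")])) {
    stop("duplicate (precursor, product) pair in transition table",
         call. = FALSE)
  }
  pp <- unique(x[, c("protein", "peptide")])
  if (anyDuplicated(pp$protein)) {
    stop("more than one peptide per protein in transition table",
         call. = FALSE)
  }
  nq <- tapply(x$quantifier, x$peptide, sum)
  if (any(nq != 1L)) {
    stop("each peptide must have exactly one quantifier transition",
         call. = FALSE)
  }
  class(x) <- c("transition_table", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

#' Verify declared m/z values against the mass calculus
#'
#' Recomputes every precursor and product m/z from the peptide sequence and
#' fragment annotation and compares with the declared values. Rows whose
#' fragment annotation cannot be parsed are flagged unverifiable (and count
#' as failures), never silently passed.
#'
#' @param table A `transition_table`.
#' @param tolerance Maximum allowed |declared - recomputed| in m/z. The
#'   default 0.1 matches tables printed at one-decimal precision.
#' @return A data frame of class `transition_verification`: one row per
#'   comparison with `protein`, `peptide`, `field` (`"precursor"` or the
#'   fragment annotation), `declared`, `recomputed`, `delta` (absolute),
#'   `pass`, and a `note` for unverifiable rows. The `"pass"` attribute gives
#'   the table-level verdict.
#' @export
verify_transition_table <- function(table, tolerance = 0.1) {
  out <- vector("list", 2L * nrow(table))
  for (i in seq_len(nrow(table))) {
    pep <- table$peptide[i]
    prec <- precursor_mz(pep, table$precursor_charge[i])
    out[[2L * i - 1L]] <- data.frame(
      protein = table$protein[i], peptide = pep, field = "precursor",
      declared = table$precursor_mz[i], recomputed = prec,
      delta = abs(table$precursor_mz[i] - prec),
      pass = abs(table$precursor_mz[i] - prec) <= tolerance,
      note = "", stringsAsFactors = FALSE
    )
    ann <- .parse_annotation(table$fragment_annotation[i])
    if (is.null(ann) || ann$index >= nchar(pep)) {
      out[[2L * i]] <- data.frame(
        protein = table$protein[i], peptide = pep,
        field = table$fragment_annotation[i],
        declared = table$product_mz[i], recomputed = NA_real_,
        delta = NA_real_, pass = FALSE,
        note = "unverifiable fragment annotation", stringsAsFactors = FALSE
      )
    } else {
      fmz <- fragment_mz(pep, ann$series, ann$index, ann$charge)
      out[[2L * i]] <- data.frame(
        protein = table$protein[i], peptide = pep,
        field = table$fragment_annotation[i],
        declared = table$product_mz[i], recomputed = fmz,
        delta = abs(table$product_mz[i] - fmz),
        pass = abs(table$product_mz[i] - fmz) <= tolerance,
        note = "", stringsAsFactors = FALSE
      )
    }
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("transition_verification", "data.frame")
  attr(rep, "tolerance") <- tolerance
  attr(rep, "pass") <- all(rep$pass)
  rep
}

#' Read / write a transition table (comma-delimited, UTF-8)
#'
#' One row per (precursor, product) pair; header-driven parsing, so column
#' order in the file is free. `write_transition_table()` followed by
#' [read_transition_table()] is the identity on all fields.
#'
#' @param path File path.
#' @param provenance Provenance tag to attach on read.
#' @return `read_transition_table()` returns a `transition_table`.
#' @export
read_transition_table <- function(path, provenance = "declared") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.TRANSITION_COLS, names(raw))
  if (length(missing) > 0L) {
    stop("transition file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("precursor_mz", "precursor_charge", "product_mz",
                "collision_energy", "retention_time_min")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop(sprintf("unparsable value '%s' in column '%s', row %d",
                   raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$precursor_charge <- as.integer(raw$precursor_charge)
  raw$quantifier <- as.logical(raw$quantifier)
  as_transition_table(raw, provenance = provenance)
}

#' @rdname read_transition_table
#' @param table A `transition_table`.
#' @export
write_transition_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, .TRANSITION_COLS], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled six-peptide MRM transition table
#'
#' The declared MRM method for the tear-protein panel: one signature peptide
#' per protein (human albumin, lactoferrin and lysozyme plus their non-human
#' internal standards), two transitions each, with collision energies and
#' retention times carried as declared metadata. The published method prints
#' the IS-albumin peptide with a typographical error (an 11-residue sequence
#' inconsistent with its own precursor and product m/z); the bundled table
#' uses the bovine albumin tryptic peptide LVNELTEFAK, the only sequence
#' consistent with the declared 582.3 / 708.4 / 837.4 values. All declared
#' values pass [verify_transition_table()] at tolerance 0.1; two IS entries
#' (precursor 659.3, product 804.3) differ from recomputation by 0.08-0.10,
#' i.e. they appear truncated rather than rounded.
#'
#' @return A `transition_table` with 12 rows.
#' @examples
#' tab <- tear_panel_transitions()
#' attr(verify_transition_table(tab, 0.1), "pass")
#' @export
tear_panel_transitions <- function() {
  read_transition_table(
    system.file("extdata", "tear_panel_transitions.csv", package = "tearmrm",
                mustWork = TRUE),
    provenance = "declared"
  )
}
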