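#' Read a protein panel (FASTA + manifest)
#'
#' A panel pairs each human analyte protein with a non-human homolog used as
#' its internal standard (IS). Sequences come from a FASTA file; roles and
#' analyte/IS pairing come from a comma-delimited manifest with columns
#' `accession`, `protein`, `species`, `role` (`analyte` or
#' `internal_standard`) and `partner` (the paired accession, empty for
#' analytes whose IS is declared on the IS row).
#'
#' @param fasta Path to a FASTA file. The first whitespace-delimited token of
#'   each description line is the accession label used to join against the
#'   manifest.
#' @param manifest Path to the manifest CSV.
#' @return A data frame of class `protein_panel`, one row per protein:
#'   `accession`, `protein`, `species`, `role`, `partner`, `sequence`.
#' @examples
#' panel <- read_panel(
#'   system.file("extdata", "panel_synthetic.fasta", package = "tearmrm"),
#'   system.file("extdata", "panel_manifest.csv", package = "tearmrm")
#' )
#' panel[, c("protein", "role", "partner")]
#' @export
read_panel <- function(fasta, manifest) {
  seqs <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("accession", "protein", "species", "role", "partner")
  missing <- setdiff(needed, names(man))
  if (length(missing) > 0L) {
    stop("panel manifest is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(man$accession, acc)
  if (length(absent) > 0L) {
    stop("no FASTA record for accession(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  man$sequence <- as.character(seqs)[match(man$accession, acc)]
  for (i in seq_len(nrow(man))) {
    .check_residues(man$sequence[i], paste0("sequence for ", man$accession[i]))
  }
  validate_panel(man)
}

#' Construct/validate a protein panel from a data frame
#'
#' @param entries Data frame with columns `accession`, `protein`, `species`,
#'   `role`, `partner`, `sequence`.
#' @return The validated `protein_panel`.
#' @export
validate_panel <- function(entries) {
  if (!all(entries$role %in% c("analyte", "internal_standard"))) {
    stop("role must be 'analyte' or 'internal_standard'", call. = FALSE)
  }
  is_rows <- entries[entries$role == "internal_standard", , drop = FALSE]
  for (i in seq_len(nrow(is_rows))) {
    p <- is_rows$partner[i]
    if (is.na(p) || p == "" || !p %in% entries$accession[entries$role == "analyte"]) {
      stop(sprintf("internal standard %s has no analyte partner",
                   is_rows$accession[i]), call. = FALSE)
    }
    mate <- entries$sequence[entries$accession == p][1L]
    if (identical(mate, is_rows$sequence[i])) {
      stop(sprintf("internal standard %s has the same sequence as its analyte",
                   is_rows$accession[i]), call. = FALSE)
    }
  }
  if (anyDuplicated(entries$accession)) {
    stop("duplicate accession in panel", call. = FALSE)
  }
  class(entries) <- c("protein_panel", "data.frame")
  entries
}
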