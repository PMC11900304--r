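panel_path <- function(f) system.file("extdata", f, package = "tearmrm")

test_that("panel FASTA + manifest reading and validation", {
  panel <- read_panel(panel_path("panel_synthetic.fasta"),
                      panel_path("panel_manifest.csv"))
  expect_s3_class(panel, "protein_panel")
  expect_equal(nrow(panel), 6)
  expect_setequal(panel$role, c("analyte", "internal_standard"))
  expect_true(grepl("LVNEVTEFAK", panel$sequence[panel$protein == "Albumin"]))
  bad <- panel
  bad$partner[bad$role == "internal_standard"][1] <- "NOPE"
  expect_error(validate_panel(bad), "partner")
})

test_that("signature-peptide selection: constraints and panel uniqueness", {
  panel <- read_panel(panel_path("panel_synthetic.fasta"),
                      panel_path("panel_manifest.csv"))
  sel <- select_signature_peptides(panel)
  # one signature peptide per protein; the shared GGSSGGSSK filler and the
  # M-containing N-terminal peptides are excluded
  expect_equal(nrow(sel), 6)
  expect_false("GGSSGGSSK" %in% sel$peptide)
  expect_equal(sel$peptide[sel$protein == "Albumin"], "LVNEVTEFAK")
  expect_equal(sel$peptide[sel$protein == "Lysozyme"], "STDYGIFQINSR")
  # residue exclusion
  fake <- data.frame(accession = "X1", protein = "X1",
                     sequence = "KMGGGGGGKR", stringsAsFactors = FALSE)
  expect_false("MGGGGGGK" %in% select_signature_peptides(fake)$peptide)
})

test_that("shared peptides are excluded from every carrier (property)", {
  set.seed(47)
  for (i in 1:10) {
    shared <- random_peptide(9, exclude = c("K", "R", "P", "C", "M"))
    shared <- paste0(shared, "K")
    mk <- function(acc) {
      own <- paste0(random_peptide(8, exclude = c("K", "R", "P", "C", "M")), "R")
      data.frame(accession = acc, protein = acc,
                 sequence = paste0("MK", shared, own),
                 stringsAsFactors = FALSE)
    }
    panel <- rbind(mk("A"), mk("B"))
    sel <- select_signature_peptides(panel)
    expect_false(shared %in% sel$peptide)
    expect_setequal(sel$accession, c("A", "B"))
  }
})

test_that("designed tables contain the expected products and verify", {
  peps <- data.frame(protein = "Albumin", peptide = "LVNEVTEFAK",
                     stringsAsFactors = FALSE)
  tab <- build_transition_table(peps, fragments_per_peptide = 2)
  expect_equal(round(sort(tab$product_mz), 1), c(595.3, 694.4))
  expect_true(all(grepl("^y", tab$fragment_annotation)))
  expect_equal(round(tab$precursor_mz[1], 1), 575.3)
  expect_equal(sum(tab$quantifier), 1)
  # minimal case: a 2-residue peptide still yields the requested transition
  gg <- build_transition_table(
    data.frame(protein = "X", peptide = "GG"), fragments_per_peptide = 1)
  expect_equal(nrow(gg), 1)
  # internal consistency: every emitted product equals recomputation
  v <- verify_transition_table(tab, tolerance = 0.001)
  expect_true(attr(v, "pass"))
})

test_that("bundled panel table passes verification at 0.1 (golden test)", {
  tab <- tear_panel_transitions()
  expect_equal(nrow(tab), 12)
  v <- verify_transition_table(tab, tolerance = 0.1)
  expect_true(attr(v, "pass"))
  expect_equal(nrow(v), 24)
  # printed values are rounded, so tolerance 0 must fail
  expect_false(attr(verify_transition_table(tab, tolerance = 0), "pass"))
})

test_that("verification flags injected errors and unknown annotations", {
  tab <- tear_panel_transitions()
  tab$precursor_mz[tab$protein == "Albumin"] <- 580.0
  v <- verify_transition_table(tab, tolerance = 0.1)
  bad <- v[v$protein == "Albumin" & v$field == "precursor", ]
  expect_true(all(!bad$pass))
  expect_equal(bad$delta[1], 4.7, tolerance = 0.05)

  tab2 <- tear_panel_transitions()
  tab2$fragment_annotation[1] <- "z9"
  v2 <- verify_transition_table(tab2, tolerance = 0.1)
  row <- v2[v2$field == "z9", ]
  expect_false(row$pass)
  expect_match(row$note, "unverifiable")
})

test_that("transition file round-trip and header-driven parsing", {
  tab <- tear_panel_transitions()
  f <- tempfile(fileext = ".csv")
  write_transition_table(tab, f)
  back <- read_transition_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-9)

  # swapped columns, same header names: still parsed correctly
  raw <- read.csv(f, stringsAsFactors = FALSE)
  raw <- raw[, rev(names(raw))]
  f2 <- tempfile(fileext = ".csv")
  write.csv(raw, f2, row.names = FALSE)
  expect_equal(as.data.frame(read_transition_table(f2)),
               as.data.frame(tab), tolerance = 1e-9)

  # missing column and unparsable number are reported by name/position
  raw2 <- read.csv(f, stringsAsFactors = FALSE)
  f3 <- tempfile(fileext = ".csv")
  write.csv(raw2[, -3], f3, row.names = FALSE)
  expect_error(read_transition_table(f3), "precursor_mz")
  raw2$product_mz[2] <- "oops"
  write.csv(raw2, f3, row.names = FALSE)
  expect_error(read_transition_table(f3), "row 2")
})

test_that("designed tables for random panels verify at 0.001 (idempotence)", {
  set.seed(48)
  for (i in 1:5) {
    pep <- paste0(random_peptide(sample(7:14, 1),
                                 exclude = c("K", "R", "P", "C", "M")), "K")
    tab <- build_transition_table(
      data.frame(protein = paste0("P", i), peptide = pep),
      fragments_per_peptide = 3)
    expect_true(attr(verify_transition_table(tab, 0.001), "pass"))
  }
})
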