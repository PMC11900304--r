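---
title: "Methods: models, assumptions and design choices in tearmrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and design choices in tearmrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tearmrm)
```

# The problem and the model

Tear fluid is sampled in the clinic with Schirmer strips; quantifying its
proteins afterwards requires extraction from the strip, tryptic digestion,
and targeted LC-MS/MS, each step losing an unknown fraction of the
protein. The workflow modelled here controls those losses with *homolog
internal standards*: a non-human counterpart of each target protein
(bovine serum albumin for human albumin, bovine lactoferrin, chicken
egg-white lysozyme) deposited on the strip together with the sample. The
measured quantity is then the response ratio

$$ r = \frac{A_{\text{analyte}}}{A_{\text{IS}}}, $$

where $A$ is the quantifier-transition peak area. Any multiplicative
factor shared by analyte and IS — extraction recovery, digestion
efficiency, injection volume, ionisation drift, matrix effect — cancels
in $r$. Calibration fits $r = a\,c + b$ against nominal concentration
$c$ on standards carrying the same fixed IS level, and unknowns are
back-calculated as $\hat c = (r-b)/a$. For a strip sample, the extract
amount $\hat c \times V_{\text{extract}}$ divided by the deposited tear
volume gives the tear concentration; the deposited volume itself is
recovered from the strip's wetted length through the conversion factor
(mm of wetting per µL).

The package's claim to correctness is structural, not empirical: with the
IS tracking its analyte perfectly and all noise at zero, the pipeline is
the identity on true concentrations (tested to 1e-9 relative), and each
statistic (Bias%, CV%, Rec%, ME%, LOD/LOQ, ANOVA) matches an independent
re-derivation.

# Mass calculus

Monoisotopic residue masses (5 decimal places), proton 1.00728 Da, water
18.01056 Da. These conventions are forced by the printed transition
table: average masses or fixed modifications (e.g. carbamidomethyl-C)
are inconsistent with every printed value, so the calculus applies *no*
modifications. Digestion is strict trypsin: cleave C-terminal to K or R
unless the next residue is P. Only b/y series, charges 1–3, are
supported — nothing else occurs in the modelled method.

The bundled panel table carries one acknowledged correction: the
published IS-albumin peptide is printed as an 11-mer ("LVNELTEAFAK")
whose own precursor and product m/z it cannot reproduce; the table uses
the bovine tryptic peptide LVNELTEFAK, which matches all three printed
values at one decimal. Two other printed entries (659.3, 804.3) differ
from recomputation by 0.08–0.10 — apparently truncated rather than
rounded — which is why the verification tolerance for printed tables is
0.1 m/z. Tables designed in-package verify at 0.001.

# Transition design rules

The source method states *which* transitions it used but not how they
were chosen, so the design operation is a reconstruction with two
deliberate choices:

* **Precursor charge**: smallest charge in 1–3 whose m/z falls in the
  precursor window, default 300–725. A wider window (e.g. the full quad
  range up to 1250) would admit singly protonated 10-mers (~1150 m/z),
  contradicting the declared method, which runs every peptide at 2+ and
  the 13-residue lactoferrin peptide at 3+. The 300–725 default is the
  window under which the smallest-charge rule reproduces exactly those
  states; methodologically it keeps precursors in the lower half of the
  range so that singly charged high-m/z products remain observable.
* **Fragment ranking**: candidate products are singly charged b/y ions
  inside the product window (300–1250) with m/z *above* the precursor
  (less low-mass chemical noise); y before b, smallest qualifying index
  first. For the albumin peptide this yields y5 then y6 — the declared
  quantifier and qualifier. When fewer candidates qualify than requested
  (very short peptides), non-qualifying ions follow in the same order, so
  the operation degrades gracefully instead of failing.

Signature-peptide selection uses: fully tryptic, length 7–25, no C or M,
unique within the analysed panel. Uniqueness is panel-wide substring
occurrence, not proteome-wide screening (which would require a proteome
download and is out of scope). Collision energy and retention time are
declared metadata, never predicted.

# The synthetic world

The generator reproduces the study design: a seven-point calibration
curve at 0.1, 0.5, 1, 5, 10, 50, 100 µg/mL with IS fixed at 2 µg/mL; QC
strips at 0.2, 2, 20 µg per protein (20 µL deposition) with 2 µg of each
IS in 10 µL; 20 paired direct/strip tear samples; a 2 × 0.5 mL extraction
pooled to 1 mL; and the conversion-factor design of 8 volumes (5–40 µL)
in triplicate. Two IS conventions coexist in the source protocol — an
amount per strip and a concentration in standards — and are kept as
separate configuration fields; with the 1 mL extract they coincide
numerically, which is what makes the strip extract directly quantifiable
against the standard curve.

Model components and their defaults:

| Parameter | Default | Basis |
|---|---|---|
| Strip conversion factor | 1.15 mm/µL | measured value in the modelled study |
| Wetted-length noise SD | 0.2 mm | ruler-reading scale; additive Gaussian, truncated at 0 |
| Buffer B recoveries | 95/92/84% (Alb/Lact/Lys), CV 3/5/4% | measured QC-medium recoveries |
| Buffer A recoveries | 92/85/76%, CV 4/6/4% | measured QC-medium recoveries |
| ABC recoveries | 70%, CV 8% (all) | **arbitrary placeholder** — no figures exist for plain ABC |
| IS tracking correlation | 1.0 | the homolog-IS premise; configurable to study IS failure |
| Matrix factors | 1.013 / 1.020 / 1.025 | inside the reported 1.3–2.5% ME band |
| Per-transition area noise CV | 1% | residual technical CV after shared-factor cancellation; chosen so the stated world reproduces the reported uniformly-below-5% triplicate CVs |
| Shared digestion factor CV | 5% | cancels in the ratio by construction |
| Baseline noise SD | 1 area unit | with response factors 1.2–2.5 × 10⁴ area/(µg/mL), places LOD/LOQ in the reported ng/mL decade |
| Tear profile | 5–50 µg/mL, 10–30 µL | **arbitrary**: mid-calibration-range concentrations and a plausible Schirmer wetting volume; real per-protein tear levels are not asserted |

Noise is multiplicative lognormal for areas and recoveries (positive
quantities whose natural error unit is a CV) and additive Gaussian for
wetted length. Areas receive a half-normal baseline term so a blank
injection produces baseline noise, not zero.

What the generator does *not* emulate: isotope envelopes, ion
suppression dynamics, retention-time drift, carryover, inter-day
effects, and real tear physiology (per-protein concentrations are
uniform draws, not mg/mL-scale clinical values). A green end-to-end test
therefore establishes that the *analysis* is correct under the stated
error model — not that the wet-lab method performs as reported.

# Quantification and validation choices

* **Calibration weighting** default 1/x²: over three orders of
  magnitude, unweighted least squares lets the top level dominate and
  destroys low-end back-calculation; 1/x² equalises *relative*
  residuals. A consequence worth knowing: a single gross outlier at the
  top level still shifts the fit by roughly its relative error divided
  by the number of points (the package's tests pin this at ~2.3
  percentage points of low-end accuracy for a +50% outlier over 7
  points) — weighted fitting is protection, not immunity.
* **Conversion factor** is regression through the origin (a dry strip
  has zero wetted length); its quoted SD is the scatter of
  length/volume ratios, matching how a ratio ± SD is conventionally
  reported.
* **Peak integration** baseline is the median intensity outside the
  window — robust and parameter-free; vendor-style baseline modelling is
  out of scope.
* **ME%** is reported as $100\,|r_{\text{spiked}}/r_{\text{neat}} - 1|$:
  the deviation-from-unity convention, since reported values of 1.3–2.5%
  cannot be a raw response ratio ×100 (which would sit near 100%).
* **LOD/LOQ**: lowest tested concentration with mean response ≥ 3σ of
  baseline noise (LOD) or ≥ 10σ with replicate CV ≤ 20% (LOQ); the
  source protocol says only "step-wise dilution", so the field's S/N
  convention is used. When no level qualifies the result is flagged
  not-reached rather than extrapolated. In the zero-noise limit both
  limits collapse to the lowest tested level.
* **Method comparison** uses the *unpaired* two-group one-way ANOVA per
  protein (equivalent to an unpaired t-test, F = t²), because the source
  analysis names ANOVA for a two-group comparison and does not state a
  paired design. On realistic paired tears (large between-sample spread,
  small technical noise) this test is conservative — p-values near 1 are
  expected, not suspicious. Its type-I error is calibrated in the regime
  where its assumptions hold exactly (independent noisy measurements of
  a common truth), and the test suite verifies the 5% rejection rate
  there.
* Negative back-calculated concentrations are clamped to 0 and flagged;
  values above the top calibration level are returned but flagged
  `extrapolated_high`. Strip-extract concentrations of dilute tear
  samples can fall *below* the lowest calibration level; they are
  back-calculated on the fitted line (intercept ≈ 0 makes this benign)
  and not flagged, mirroring common practice for within-linear-range
  extrapolation downwards.

# Reproducibility machinery

Every stochastic operation accepts a seed; `generate_study()` fans a
master seed out to per-stage child seeds by a fixed rule
(`(seed × 1009 + 97 × stage) mod 2147483587 + 1`), so the calibration,
QC, tear, wetting, dilution and matrix-effect stages are individually
reproducible. A study bundle written to disk with its manifest is
byte-identical across repeated runs of the same `(config, seed)`; the
run manifest lists every file the workflow writes.

# Known limitations

Single quantifier per peptide (no multi-transition consensus); linear
calibration only; no LLOQ-aware curve truncation; recovery for plain ABC
buffer is a placeholder; the direct-analysis arm models the tear
concentration as injected unchanged (shared dilution factors cancel into
the response factors); chromatogram synthesis is a single Gaussian per
transition and is off by default in study generation (areas are carried
directly). Real-tear concentration distributions and any
electrophoresis-based quantification are outside the package's scope.
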