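---
title: "ARMS-HRMA melt-curve scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ARMS-HRMA melt-curve scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armshrma)
```

## The assay and its readout

ARMS-HRMA couples two ideas. Allele-specific PCR (ARMS) places the
discriminating base at the forward primer's 3′ terminus: a template carrying
the target mutation primes perfectly and amplifies at high efficiency, while
any other allele suffers a 3′ mismatch and yields only residual product.
High-resolution melting analysis (HRMA) then quantifies the product in the
closed tube: fluorescence of a saturating dsDNA dye is recorded while
temperature ramps 45→95 °C in 0.2 °C steps, and the negative derivative
−dF/dT turns each dissociating product into a peak located at its melting
temperature (Tm) whose height tracks product amount.

Because both templates yield the *same* amplicon (the discriminating base
sits inside the primer), allele status is read from peak **intensity**, not
peak position: a mutated sample produces a tall peak at the assay's
characteristic Tm (≈ 80 °C for the G12V assay, ≈ 79.5 °C for G12D), a
wild-type sample only the residual-amplification stub. The G12D assay
additionally shows a genotype-independent by-product peak at ≈ 75.5 °C,
which scoring must ignore; the wild-type-allele control assay melts at
≈ 78.5 °C.

## The scoring rule

For one assay plate containing a wild-type cell-line control and a mutant
cell-line control, each well is processed as

1. Savitzky–Golay smoothing of the raw trace (window 11 points = 2.2 °C,
   cubic);
2. −dF/dT by central differences (one-sided at the two edges);
3. raw intensity `F` = maximum of −dF/dT inside the scoring window
   (scoring temperature ± 1 °C), clipped at 0;
4. normalization `score = (F − F_neg) / (F_pos − F_neg)` where `F_neg`,
   `F_pos` are the run means over wild-type-control and mutant-control
   replicates;
5. replicate scores averaged per sample; call **MUT** iff the mean exceeds
   the threshold 0.5.

Assumptions worth stating: controls and samples share one amplification/HRM
run (the normalization cancels run-level scale, so scoring is invariant to
multiplying every fluorescence value by any k > 0 — a tested property);
the mutant control must outshine the wild-type control (`F_pos > F_neg`),
otherwise the run is invalid and scoring refuses to proceed; replicate wells
are exchangeable.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| smoothing window | 11 points (2.2 °C) | points | preserves transitions ≥ 0.8 °C wide while attenuating noise; polynomial order 3 |
| scoring window | scoring temp ± 1.0 °C | °C | absorbs ± 0.5 °C inter-run Tm drift plus grid resolution; the G12V product (≈ 80 °C) still falls inside the 79.5-centred window |
| threshold | 0.5 | unitless | midpoint of the control anchors (controls self-score to 0 and 1); treated as a fixed configuration value, not re-fitted |
| peak prominence | 10 % of global max | fraction | suppresses noise ripples in peak *detection* (not used by scoring, which takes a windowed maximum) |
| readout mode | `window_max` | — | the windowed maximum is robust to Tm drift; `at_temp` reads the single grid point nearest the scoring temperature for instrument-style fixed readouts |

## Decisions made where the design was open

* **Normalization form.** The two-control linear rescaling
  `(F − F_neg)/(F_pos − F_neg)` is the natural reading of
  "normalized to the positive and negative controls"; it is exact for the
  controls themselves and keeps over-unity or negative scores visible
  (scores are *not* clipped — only raw intensities are clipped at zero
  before normalization).
* **Windowed maximum vs fixed 79.5 °C readout.** The assay's scoring
  temperature (79.5 °C) and the G12V product's Tm (≈ 80 °C) differ by more
  than a grid step; a windowed maximum absorbs this and inter-run drift.
  The fixed-point mode is retained as an option.
* **Tie at the threshold.** A mean score of exactly 0.5 is called NEG:
  a mutation call requires evidence strictly above the threshold.
* **Difference-plot orientation.** `sample − reference` (wild-type
  control as reference), so mutated samples show positive excursions;
  `invert = TRUE` gives the opposite convention.
* **Multiple controls** are averaged before normalization rather than
  paired per replicate; with ≥ 4 control wells this halves control noise in
  the anchors and keeps the rule well-defined for unequal replicate counts.
* **Missingness vocabulary.** `NA` (not assessed) and `UNREADABLE`
  (Sanger attempted, chromatogram failed) are distinct states because the
  two are counted separately when summarising how many plasma specimens
  could be sequenced (23 attempted) versus read (13 readable).
* **Concordance denominators.** The study-style comparison conditions on
  one method's positives co-assessed by the other (`positives_of_a`); the
  symmetric agreement rate over all co-assessed rows (`all`) is also
  provided. Rows missing either method never enter a denominator, so
  adding an all-`NA` row changes nothing (tested).
* **Repository shape.** The package is organised as an analysis workflow —
  computation in `R/`, narrative drivers under `analysis/` — because the
  deliverable is a sequence of analyses (fixture concordance, simulation
  studies) rather than a shell tool; the drivers are the command-line
  surface.

## What the simulator emulates

`simulation_config()` + `simulate_cohort()` generate plates with the
assay's statistical structure:

* **Amplification**: per-allele logistic-capped geometric growth,
  `n ← n + e·n·(1 − n/K)` per cycle, with matched efficiency 0.9 and
  mismatched efficiency 0.35 over 35 effective cycles (the wet protocol's
  10 low-stringency + 25 high-stringency cycles collapsed into one
  effective efficiency per allele). With 1000 template copies (≈ 4 ng
  genomic DNA) and plateau K = 10¹², a fully matched template saturates
  while template shares of 5–50 % land on the plateau shoulder — the regime
  in which normalized scores rise strictly with mutant fraction
  (≈ 0, 0.25, 0.75, 0.94, 1.00 at fractions 0, 0.05, 0.25, 0.5, 1) yet
  heterozygous carriers still score well above threshold.
* **Melting**: each product contributes a two-state transition
  `w/(1 + exp((T − Tm)/width))` with width 0.8 °C, so a transition of
  amplitude A has derivative peak height A/(4·width) — the closed form the
  signal-processing tests check. The G12D assay adds a fixed-amount
  (6×10¹¹ copies) by-product species at 75.5 °C for every well including
  non-template controls, sized so it forms a distinct peak rather than a
  shoulder even next to a full-strength specific transition.
* **Plate structure**: wild-type control (SW48-like, wt/wt), mutant
  control (SW480-like G12V/G12V, or LS174T-like wt/G12D — note the G12D
  positive control is heterozygous, as in the cell line), non-template
  controls, and 4 replicate wells per sample; a linear decreasing baseline
  (0.2 a.u. at 45 °C, −0.002 a.u./°C) and Gaussian noise (sd = 2 % of curve
  amplitude) exercise the smoothing and derivative code.

What it does **not** emulate: instrument-specific fluorescence magnitudes
and drift (the anchor 3.2×10⁻¹² a.u./copy is arbitrary; every result uses
normalized scores), annealing-temperature-dependent efficiency, competition
between alleles for reagents, melt-domain structure beyond two-state
transitions, and DNA-quality effects in FFPE or plasma extractions. Passing
recovery tests therefore demonstrate the *scoring logic* under the assay's
signal structure, not wet-lab analytical sensitivity. At heterozygous
fractions (≥ 25 % of template) recovery is complete across seeds; at
ctDNA-like fractions (≤ 0.1 %) scores fall to ≈ 0.005 and calls degrade to
NEG — expected, and deliberately not asserted as a detection claim.

## Numerical choices and degenerate inputs

* Temperature grids equal within 10⁻⁶ °C are treated as shared; anything
  else is an error — readers never resample.
* Central differences are exact for quadratics on the uniform grid; the
  logistic closed form A/(4w) is reproduced within 2 % at the 0.2 °C grid.
* Peak location is accurate to one grid step (0.2 °C) for transition widths
  ≥ 0.4 °C.
* Equal-height peak ties break toward lower temperature; plateaus report
  their first grid point.
* Mann–Whitney: exact enumeration for combined n ≤ 20 (the permutation
  distribution of U is symmetric about n₁n₂/2 even with ties, so the
  two-sided p is the tail mass of |U − n₁n₂/2|); larger samples use the
  normal approximation with midrank tie correction and 0.5 continuity
  correction (agrees with the exact branch within 0.01 at n = 10 vs 10).
  All pooled values identical → p = 1, flagged degenerate.
* Empty co-assessed sets yield a flagged report with `NA` concordance, not
  an error; an empty call table yields an empty report.

## Problem sizes

The test suite simulates 30-patient cohorts (two 130-well plates of
251-point curves) across 10 seeds for recovery, 5-point dose–response
ladders, and exhaustive Mann–Whitney enumeration up to combined n = 10
(and C(20,10) ≈ 1.8×10⁵ assignments in the largest exact case) — sizes
chosen to match the study's cohort while keeping the whole suite under a
minute on a laptop.

## Known limitations

Concordance analyses ingest the published call tables as ground truth; the
package does not process Sanger chromatograms or ddPCR droplet data. The
wild-type-allele assay is scored identically to the mutation assays but its
call (wt allele present/absent) is reported separately and never merged
into mutation calls. Three plasma specimens are described in the source
tables' notes as sequenced with only one primer; the tables do not identify
them, so the fixture cannot encode partial-primer status.
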