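---
title: "Per-cell confocal compartment quantification and colocalization: methods and design"
author: "colocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell confocal compartment quantification and colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Immunofluorescence studies of vesicular protein trafficking — here the
prototype is a cytokine that accumulates in LC3B-positive autophagic
vesicles before secretion — need per-cell numbers, not per-field numbers:
how much of a cell's signal sits in bright puncta rather than diffuse
cytoplasm, and how much of one marker's signal coincides with the other's.
The classic workflow is an ImageJ/Fiji macro: threshold the cytokine
channel low enough to capture whole cells, watershed the binary mask to
separate attached cells, take each label as one cell ROI, subtract a
per-image background estimated inside nuclei, and then measure integrated
densities and Manders coefficients per cell. `colocell` implements that
workflow as a reproducible library with every operator choice surfaced as
an explicit, logged parameter.

## Pipeline model and assumptions

**Segmentation** assumes cells are bright against background in the
cytokine channel and roughly convex. `cell_mask()` thresholds and fills
holes (nuclei are dim in the cytokine channel and would otherwise puncture
masks). `split_touching()` runs a watershed on the Euclidean distance
transform, seeded at distance maxima at least
`watershed_min_seed_distance_px` apart (default 10 px); separate connected
components are never merged, and a lone convex blob keeps one label.
`extract_rois()` drops labels below `min_cell_area_px` (default 200 px)
and, by default, labels touching the field border (partial cells bias
per-cell totals).

The default cell threshold, `"otsu_low"`, is half the Otsu threshold with
floor 1 — a deliberately permissive value matching the "low threshold that
includes the whole cell area" intent. One non-obvious numerical choice:
Otsu is computed on the **log-intensity histogram**. Puncta-bearing
channels have a third, very bright and very small intensity class
(vesicles); in the linear domain this class captures the Otsu split, which
then lands *above* the cytoplasm level and masks only the puncta. On the
log scale the split falls between background and cell, which is what a
whole-cell mask needs. Fixed numeric thresholds bypass all of this and are
the recommended route when an operator has calibrated the instrument.

`segmentation_params(smooth_sigma = ...)` optionally Gaussian-blurs the
image used to *build masks* (never the measured intensities). It is off by
default; it exists for images whose single-pixel read noise is comparable
to the cytoplasmic contrast, where pixelwise thresholding produces
percolating speckle rather than cells.

**Background.** One scalar per image per channel: the mean intensity over
the nuclear mask (`estimate_background()`), following the convention that
the nuclear interior carries no specific cytoplasmic/vesicular signal in
the measurement channels. With no nuclear channel a configured constant
(`background_fallback`) must be supplied. Subtraction clamps at zero;
clamping keeps integrated densities non-negative and the compartment
ordering (vesicular ⊆ cellular, ID~ves~ ≤ ID~cell~) valid, at the price of
a positive rectification bias when the noise scale approaches the signal
(see *Limitations*).

**Compartments.** The cellular compartment is the full ROI, the vesicular
compartment its subset at or above the operator's `vesicular_threshold`
(a fixed intensity on background-subtracted values, per channel; the
cytokine value is reused for the marker channel unless overridden). The
vesicular percentage is 100·ID~ves~/ID~cell~, hence in [0, 100].

**Colocalization.** Manders M1/M2 are computed on *raw* channel values
over the ROI with explicit per-channel thresholds and strict inequality —
the thresholds are a separate operator choice from the vesicular
threshold, resolved per image (`coloc_threshold`, numeric or `"otsu"`).
Zero denominators (a cell with no above-threshold signal) leave the
coefficient `NA` and flagged; coercing to 0 would bias group means, so
flagged values are excluded from summaries and tests. Which channel M1
indexes is configurable (`m1_channel`) and recorded in the outputs.
The colocalizing-area percentage is the intersection of the two
per-channel vesicular masks divided by the cell area.

**Group statistics.** `mann_whitney()` computes U from rank sums with
midranks; the two-sided p-value is exact (via the exact U distribution,
equivalent to full enumeration of labelings) when n₁·n₂ ≤ 400 with no
ties, otherwise a tie- and continuity-corrected normal approximation.
Summaries are mean ± SEM (sample SD over √n; 0 for n = 1). The
significance convention is p < 0.05, reported, never used to filter data.

## The synthetic-data generator

`generate_scene()` emulates a low-density confocal field as acquired at
high magnification on a 16-bit detector. Defaults (all configurable):

| parameter | default | meaning |
|---|---|---|
| `field_shape` | 512 × 512 px | one field of view |
| `n_cells` | 12 | low cellular density |
| `cell_radius_range` | 18–26 px | round leukocyte-sized cells (~4–5 µm radius at ~0.2 µm/px) |
| `nucleus_radius_range` | 6–9 px | nucleus strictly inside the cell |
| `vesicles_per_cell` | 8 | bright puncta per cell |
| `vesicle_radius_range` | 2–3 px | diffraction-limited-ish puncta |
| `colocalized_fraction` | 0.5 | fraction of vesicles positive in both channels |
| `background` | 100 / 100 / 0 | detector offset per channel (grey values) |
| `cytoplasmic_intensity` | 600 / 300 | diffuse signal over the cytoplasm |
| `vesicle_amplitude` | 8000 / 8000 | added over a vesicle disk |
| `nucleus_intensity` | 8000 | nuclear stain, nucleus channel only |
| `poisson`, `gaussian_sd` | TRUE, 20 | shot noise then read noise |

Pixels are 1-based `(row, col)`; a pixel belongs to a disk when its center
lies within the radius. Rendering sums background + cytoplasm (cell disk
minus nucleus) + overlapping vesicle amplitudes, applies Poisson then
Gaussian noise, rounds, and clips to the bit-depth range. The nuclear
channel is positive only inside nuclei, and the measurement channels carry
pure background inside the nucleus — that is the geometric assumption
behind nuclear-region background estimation, and vesicles are placed with
their disks disjoint from the nucleus to keep it true. Cells keep a 4-px
clearance from the field border by default (`border_margin`), emulating
the practice of imaging fields with whole cells in view. Placement is
rejection sampling bounded at 10,000 attempts (a crowded field raises an
error rather than looping forever).

The number of colocalized vesicles per cell is deterministic —
`round(colocalized_fraction × vesicles_per_cell)`, the remainder
alternating between single channels — so recovery tests see no binomial
sampling variance in the planted truth. `ground_truth_metrics()` computes
the per-cell answer key (areas, integrated densities, vesicular and
colocalized area fractions, Manders values at thresholds
background + cytoplasmic intensity) by exhaustive pixel loops over the
noiseless rendering, independently of the measurement path.

What the generator does **not** emulate: point-spread-function blur,
3-D structure, photobleaching, chromatic shift, irregular cell shapes,
intensity gradients, or autofluorescence texture. Passing recovery tests
therefore demonstrates the *measurement logic* is correct, not that the
default thresholds transfer to any particular microscope's data — on real
images the thresholds remain operator calibration, exactly as in the
original workflow.

## Validation strategy and problem sizes

Three layers, all in the test suite:

* **Oracle equivalence.** Manders, colocalizing area, integrated density
  and background estimation agree *bit-exactly* with independent
  brute-force double-loop implementations on 100 seeded random 64 × 64
  instances (integer-valued grids make summation order immaterial).
* **Ground-truth recovery.** On noiseless fields (nine 384 × 384 fields of
  6 cells, 54 cells) every per-cell measurement equals the answer key
  exactly. With Gaussian read noise at 5% of the vesicle amplitude
  (σ = 400, i.e. two-thirds of the cytoplasmic contrast), means of the
  vesicular percentage (intensity- and area-derived) and colocalizing-area
  percentage recover truth within ±5 percentage points, using operator
  settings appropriate to that noise (fixed thresholds, `smooth_sigma = 2`,
  vesicular threshold ≈ 5 noise SDs above the cytoplasm level).
* **Direction of planted effects.** Mean M1 and colocalizing area are
  non-decreasing across planted colocalized fractions {0, 0.25, 0.5, 0.75,
  1} on a fixed geometry (only vesicle channel assignments change), and
  doubling the vesicle load strictly increases total and vesicular
  integrated density — the accumulation signature expected when
  autophagosome turnover is blocked.

Segmentation recovery uses 40 replicate 384 × 384 fields of 6 non-touching
cells at default parameters (≥ 95% must return exactly 6 ROIs; residual
misses are noise-speck bridges from a cell to the border, which the
border-exclusion rule then removes). The Mann–Whitney exact path is checked
against full enumeration for every n₁, n₂ ≤ 8 and its simulated type-I
error at nominal 0.05 over 10,000 null pairs (n = 10 per group) must not
exceed 0.05. These sizes keep the whole suite around half a minute on one
CPU while leaving the statistical assertions comfortably powered.

## Design choices where the design was open

* **M1/M2 channel assignment** differs between published figure legends in
  this literature; it is a config key (`m1_channel`), echoed in outputs,
  rather than an assumption.
* **Vesicular threshold for the marker channel**: reuses the cytokine
  value unless overridden — the two are independent keys.
* **Per-image, not per-cell, background**, following the source
  convention ("for each image, a background value was subtracted").
* **Negative corrected intensities clamp to 0** so that compartment
  ordering and non-negativity of integrated densities hold.
* **4-connectivity** for component labeling, stated once and matched by
  the oracles.
* **Plain multi-page TIFF** (not OME-TIFF) with channel order supplied by
  the caller: zero metadata dependence, lossless at 8 and 16 bit.
* **Grouping unit**: the pipeline treats whatever rows it is given as the
  unit of comparison (per-cell by construction); aggregation to donors or
  experiments, and any multi-factor modeling, is left to downstream tools
  via the exported CSV.

## Known limitations

* Background estimation inherits any signal contamination of the nuclear
  region; in the generator this is excluded by construction, on real data
  it is an assumption to check.
* Zero-clamped subtraction rectifies noise: when the noise SD is not small
  against the signal, integrated densities acquire a positive bias (the
  intensity-derived vesicular percentage showed ≈ +2 points under σ = 400
  noise; the area-derived version is insensitive).
* Watershed with a single global seed-separation distance can oversplit
  elongated cells or undersplit tight clusters; the per-image log records
  every resolved threshold and dropped label for audit.
* 2-D only: z-stacks must be projected or analyzed plane by plane
  upstream.
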