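# colocell

Per-cell quantification of multi-channel confocal fluorescence images, for
studies of protein trafficking through vesicular compartments — the
prototypical use case being a cytokine (e.g. IL-1β, red channel) routed
through LC3B-positive autophagic vesicles (green channel), with a nuclear
counterstain. `colocell` reimplements, as a tested and reproducible R
pipeline, the classic Fiji-macro workflow used for this kind of analysis:

1. **Segmentation.** A deliberately *low* threshold on the cytokine channel
   captures the whole cell area; attached cells are separated by watershed
   on the Euclidean distance transform of the binary mask; each surviving
   label becomes one cell ROI (region of interest).
2. **Compartment quantification.** For each image, a scalar background *b*
   is estimated as the mean intensity inside the nuclear region and
   subtracted (clamping at zero). Two masks are built per cell: the
   *cellular* compartment (the full ROI) and the *vesicular* compartment
   (ROI pixels whose corrected intensity reaches an operator-set vesicular
   threshold). The integrated density (sum of corrected intensities, in
   arbitrary units of fluorescence) is measured in both, giving per cell

   ID<sub>ves</sub> ≤ ID<sub>cell</sub>, vesicular % = 100 · ID<sub>ves</sub> / ID<sub>cell</sub>.

3. **Colocalization.** Per cell, Manders' coefficients over the ROI with
   per-channel thresholds t₁, t₂ (strict inequality):

   M1 = Σₚ ch1ₚ·[ch2ₚ > t₂] / Σₚ ch1ₚ·[ch1ₚ > t₁],   M2 symmetrically,

   both in [0, 1] (0 = no, 1 = perfect colocalization; zero denominators
   are flagged undefined, never coerced to 0), plus the colocalizing area
   of the two vesicular masks as a percentage of the cell area.
4. **Group statistics.** Mann–Whitney U test (exact by enumeration for
   small tie-free samples, corrected normal approximation otherwise) for
   two unpaired conditions, with mean ± SEM summaries.

Because public image data is rarely available for such workflows, the
package ships a synthetic confocal field generator with exhaustive ground
truth (`generate_scene()`, `render_scene()`, `ground_truth_metrics()`):
round cells with nuclei, diffuse cytoplasmic signal, bright punctate
vesicles with a controllable colocalized fraction, Poisson shot noise and
Gaussian read noise. Every stage of the pipeline is validated against this
answer key and against independent brute-force pixel-loop oracles.

## Worked example

Simulate two conditions differing in the planted colocalized vesicle
fraction (0.2 vs 0.8 — e.g. resting vs starvation-induced autophagy), run
the full pipeline from one configuration, and compare conditions:

```r
library(colocell)

base <- tempfile("demo")
p_mock    <- scene_params(colocalized_fraction = 0.2)
p_starved <- scene_params(colocalized_fraction = 0.8)
simulate_batch(p_mock,    n_images = 4, out_dir = file.path(base, "mock"),    seed = 1)
simulate_batch(p_starved, n_images = 4, out_dir = file.path(base, "starved"), seed = 100)

cfg <- pipeline_config(
  conditions      = c(mock    = file.path(base, "mock"),
                      starved = file.path(base, "starved")),
  output_dir      = file.path(base, "out"),
  quant           = quant_params(c(il1b = 1000, lc3b = 1000)),
  coloc_threshold = c(il1b = 2000, lc3b = 2000))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> 96 cell(s), 2 condition(s), 0 failure(s)
#> comparisons (Mann-Whitney, two-sided):
#>                  metric   U  p_two_sided       mean_a       mean_b
#>        id_cellular_il1b 253 4.583414e-11 1.481481e+06 1.821945e+06
#>       id_vesicular_il1b  14 7.738112e-17 8.329397e+05 1.189377e+06
#>  vesicular_percent_il1b 467 5.282353e-07 5.683699e+01 6.566235e+01
#>                      m1   0 3.234613e-17 4.828562e-01 8.808675e-01
#>                      m2   0 3.234613e-17 4.689851e-01 8.847692e-01
#>      coloc_area_percent   8 5.331372e-17 2.861582e+00 7.520413e+00
#>  ...

compare_conditions(res$cells, "coloc_area_percent")
#> <group_comparison> n = 48 vs 48, U = 8, p = 5.331e-17 (normal_approximation)
#>   group A: 2.862 +/- 0.1331 (mean +/- SEM)
#>   group B: 7.52 +/- 0.2346
```

All 96 planted cells are recovered; the vesicular LC3B–IL-1β colocalizing
area rises from ≈2.9% to ≈7.5% of the cell area and both Manders
coefficients from ≈0.47 to ≈0.88, mirroring the planted fraction, with
p ≪ 0.05 by Mann–Whitney. `run_pipeline()` writes `cells.csv` (one row per
cell), `summary.json` (mean/SEM/n per metric per condition),
`comparisons.csv` and a `run.log` recording every threshold resolved per
image.

A thin command-line wrapper over the same functions is installed at
`inst/cli/colocell` (subcommands `simulate`, `run`, `compare`).

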