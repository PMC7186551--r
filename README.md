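# SpotQuant

Quantification of single-molecule RNA FISH (smFISH) combined with
immunofluorescence (IF) in budding yeast, with a synthetic ground-truth
microscope so every stage of the analysis is testable.

smFISH tiles a transcript (here the G1 cyclin *CLN2*, probed with 48
singly-labelled 20-mers) so each mRNA appears in a widefield z-stack as a
diffraction-limited spot of near-constant brightness. SpotQuant turns such
multichannel stacks (41 planes, 200 nm spacing, 64.5 nm pixels) plus cell
outline files into per-cell transcript counts:

* **Detection** — difference-of-Gaussians filtering, 3D local-maxima
  pre-detection, and bounded Levenberg–Marquardt fitting of each candidate
  with a voxel-integrated tri-axial Gaussian
  `B + Q·g(x,y,z; σ_xy, σ_xy, σ_z)` on the raw stack, with
  neighbour-subtraction refinement so nearby spots do not share photons.
  The integrated intensity is `Q = A·(2π)^{3/2}·σ_xy²·σ_z/(dx·dy·dz)`.
* **Single-mRNA reference** — accepted spots are averaged (subvoxel
  re-centring, background subtraction, 3D-Gaussian refit) and the reference
  intensity `Q_ref` is taken as the median per-spot `Q`.
* **Transcription sites** — intra-nuclear spots with `Q ≥ 1.5·Q_ref` are
  TS; the nascent count is `max(1, round(Q_ts/Q_ref))`.
* **Per-cell outputs** — point-in-polygon assignment to cell outlines,
  integrated tubulin-IF intensity over a maximal projection (excluding the
  bottom-of-slide planes), bud-ratio and spindle-span morphology, and a
  rule-based cell-cycle score (G1/S/G2/M).
* **Reporting** — expressing-cell mean with a percentile-bootstrap 95% CI,
  nascent mean ± SD per TS, frequency distributions, and evaluation against
  ground truth (F1, count MAE, nascent exact-match rate, phase accuracy).
* **QC** — per-plane z-drift estimation by regularized phase correlation
  (flagging ~1 px/plane oil-bubble drift) and DIC-to-fluorescence
  registration.

The `scene_synthesis` side (`scenarioParams()`, `sampleScene()`,
`renderStack()`) generates the ground truth: yeast-like cell/nucleus
polygons with cell-cycle phases, negative-binomial mature counts
(mean 10.1/cell), zero-truncated-Poisson nascent counts (mean 3.6/TS),
per-molecule brightness from binomial occupancy of the 48-probe set, a
voxel-integrated Gaussian PSF, Poisson + read camera noise, and the
acquisition artifacts worth testing against (z-drift, DIC offset, slide
debris).

## Worked example

```r
library(SpotQuant)

params <- scenarioParams(nCells = 25, seed = 1)   # one 512x512x41 position
res <- runCohortAnalysis(params, nCellsTotal = 100, seed = 20, nBoot = 2000)
res$summary
#> 100 cells, 20 expressing
#>   expressing-cell mean: 13.45 mRNAs/cell (95% CI 9.45-17.75)
#>   nascent: 4.00 +/- 1.41 RNA/TS over 6 sites
res$QRef                     # single-mRNA reference intensity (ADU voxel)
#> [1] 19297.4
res$metrics$count_mae        # per-cell count error vs generator truth
#> [1] 0.07
```

The cohort of 100 cells here contains 20 expressing cells whose true mean
count is 13.60 mRNAs/cell; the pipeline recovers 13.45 with a bootstrap CI
that covers the truth, a single-mRNA reference within 0.6% of the
generator's mean brightness (19,200 ADU·voxel), and a mean absolute
per-cell count error of 0.07 transcripts.

File IO mirrors the deposited-data dialects: multi-page 16-bit TIFF stacks
(`readStack`/`writeStack`), block-structured outline text files
(`readOutlines`), `key=value` detection-settings files (`readSettings`) and
the manual cell-cycle scoring CSV (`readScoringCsv`).

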