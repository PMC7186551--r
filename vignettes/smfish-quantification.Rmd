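---
title: "Quantifying single-molecule RNA FISH with SpotQuant: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule RNA FISH with SpotQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpotQuant)
```

## The measurement problem

Single-molecule RNA FISH (smFISH) tiles a transcript with dozens of short,
singly-labelled oligonucleotide probes, so that each mRNA appears in a
widefield fluorescence z-stack as one diffraction-limited spot of
near-constant brightness. Combined with immunofluorescence (IF) against
alpha-tubulin, the same budding-yeast cell yields its cell-cycle stage, so
transcript counts can be stratified by phase. Three quantities are the
endpoints of such an experiment:

* the number of **mature** transcripts per cell (one spot = one mRNA),
* the number of **nascent** transcripts at the transcription site (TS), read
  out as the TS intensity divided by the single-mRNA reference intensity,
* the cell-cycle **phase** of each cell, from tubulin intensity and cell
  morphology.

SpotQuant implements the full chain — band-pass filtering, 3D Gaussian spot
fitting, single-molecule averaging, TS quantification, outline-based cell
assignment, IF quantification and phase scoring — together with a
ground-truth scene generator that renders synthetic multichannel stacks with
the same statistical structure, so that every stage can be validated against
known truth at desk scale.

## The forward model (scene generator)

The generator is first-class code, not a test fixture: its defaults *are*
the study conditions the analysis is validated under.

**Geometry.** A stage position is a 41-plane z-stack with 200 nm plane
spacing and 64.5 nm lateral pixels (a 6.45 µm camera pixel behind a 100x
objective). Cells are haploid-yeast-like: round mothers of radius
`cellRadius` (default mean 1450 nm, SD 120 nm, i.e. ~2.9 µm diameter) with
a mild low-order radial irregularity; budded cells are the union of a
mother and a bud circle, with bud-to-mother area ratios drawn per phase
(S: 0.10–0.22, G2: 0.42–0.62, M: 0.55–0.75). The nucleus is a circle of
0.38 mother radii held inside the mother lobe. Cells are packed without
overlap by rejection sampling of their per-lobe bounding disks.

**Counts.** Only G1 cells can express (the transcript modelled is switched
on in late G1); a G1 cell expresses with probability
`expressingFractionG1` (default 0.5, reflecting a late-G1 expression
window of roughly half of G1). Mature counts in expressing cells are
negative binomial with mean 10.1 and size 1.3. The mean is the study
condition; the size is derived from the reported cohort dispersion: a 95%
CI half-width of 0.7 mRNAs/cell over 688 expressing cells implies an SD of
about 9.4, and matching NB moments gives size ≈ 1.3. An expressing cell
carries a visible TS with probability `tsFraction` (default 154/688 ≈ 0.22,
the ratio of reported TS to expressing cells); its nascent count is
zero-truncated Poisson with mean 3.6.

**Brightness.** Each molecule's integrated intensity is
`qProbe * Binomial(nProbes, pBind)` with 48 probes, binding probability
0.8 and 500 ADU·voxel per bound probe. This ties the brightness model to
the actual probe set (the bundled CLN2 list: 48 sequences, 47 of 20 nt and
one of 19 nt, which the validator flags rather than corrects) and produces
the narrow single-molecule intensity histogram characteristic of smFISH
(CV = sqrt((1-p)/(np)) ≈ 7%). A TS with *n* nascent transcripts is rendered
as *n* co-located molecule equivalents, each with its own binomial draw.

**Optics and camera.** Spots are voxel-integrated tri-axial Gaussians
(error-function mass per voxel face) with σ~xy~ = 130 nm and σ~z~ = 350 nm,
typical for a widefield NA 1.35 system. Voxel integration (rather than
centre sampling) makes photon bookkeeping exact: with noise off the
rendered mass equals the generator brightness to the truncation tail, which
the conservation tests exploit at the 1% level. Camera counts are
`offset + gain * Poisson(signal/gain) + N(0, read_sd)` with gain 2 ADU per
photon, offset 100 ADU and 3 ADU read noise, rounded to integers. At these
defaults a single mRNA has peak amplitude ≈ 170 ADU and peak SNR ≈ 9–10.

**Artifacts.** Three acquisition pathologies can be injected: a linear
per-plane z-drift (the oil-bubble artifact), an integer DIC-to-fluorescence
translation offset, and IF-channel debris confined to the lowest planes
(antibody aggregates on the slide).

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: autofluorescent cytoplasmic background and
its spatial texture, depth-dependent PSF aberrations, chromatic shifts
between channels, probe off-target binding, partially hybridized nascent
transcripts (nascent equivalents carry full probe complements), true DIC
physics (the DIC proxy is an edge map), photobleaching, and cell crowding
with touching or overlapping outlines.

## The analysis chain and its numerical choices

**Band-pass filtering.** SNR enhancement is a difference of Gaussians,
separable and edge-renormalized (a constant image maps to exactly zero
everywhere, including borders); defaults σ small/large = 1/5 px laterally
and 0.5/2.5 planes axially. Negative response is clipped after the
pre-detection threshold is derived.

**Pre-detection.** Candidates are 26-connected local maxima of the filtered
stack above a threshold. The threshold is a settings-file input (it is set
interactively in GUI practice); when unset it defaults to
median + 8 × MAD of the unclipped band-pass response — at the default noise
model the response MAD is ~0.7 ADU, putting the automatic threshold more
than an order of magnitude below a single-molecule peak response.
Candidates closer than `minSeparation` (3 px) merge keeping the brighter;
plateau ties resolve to the first voxel in (z, y, x) order, so the
candidate list is deterministic.

**Spot fitting.** Each candidate is fitted on the *raw* stack with
`B + Q·g(…; σ_xy, σ_xy, σ_z)`, `g` voxel-integrated, by bounded
Levenberg–Marquardt (analytic Jacobian, 200 iterations, cost tolerance
1e-8). Width bounds are σ~xy~ ∈ [50, 400] nm and σ~z~ ∈ [150, 1000] nm;
lateral symmetry (σ~x~ = σ~y~) is imposed because a 64.5 nm sampling of a
130 nm PSF cannot support full anisotropy without overfitting. Two choices
matter at realistic densities (~10 mRNAs in a 3 µm cell, where a
transcript's nearest neighbour is often inside the 15×15×11 fit window):

* the fitted centre may move at most `minSeparation` voxels from its
  candidate, so the fit of a dim spot cannot slide onto a brighter
  neighbour, and the background is bounded below at zero;
* after a first pass, each spot is refitted on a window from which the
  current model of every other spot has been subtracted (three damped
  passes, the intensity update being the geometric mean of old and new).
  Without this, neighbouring fits double-count shared photons.

Converged fits closer than `minSeparation` are de-duplicated keeping the
lower residual. A candidate on flat background converges to zero amplitude
and is reported as `fit_failure`.

**Acceptance filtering and the single-molecule reference.** Fits are
accepted when converged and inside per-parameter bounds; rejected fits are
retained with per-bound tags (`Q_high`, `sigma_xy_low`, …). The
single-mRNA reference intensity Q~ref~ is, by default, the median of
per-spot integrated intensities (robust to residual doublets), computed in
two steps: a median over all converged fits, then the median of the
[0.5, 1.5]×Q~ref~ band around it. The averaged-molecule image (windows
re-centred by trilinear interpolation, background-subtracted, voxel-wise
mean, refit) is also produced; its refit integral is the alternative `fit`
estimator, and the two agree within a few percent on clean data.

**Counting rules.** Accepted spots in the [0.5, 1.5]×Q~ref~ band count as
one mature mRNA each. Inside the nucleus polygon, spots (accepted or
rejected as too bright) with Q ≥ 1.5×Q~ref~ are TS candidates; at most one
TS per cell is kept (haploid default), and its nascent count is
max(1, round(Q~ts~/Q~ref~)), the fractional value being retained for audit.
In the cytoplasm the composed pipeline applies the same intensity ratio to
`Q_high` spots (`decomposeBright` in `buildCellRecords`): at ten transcripts
per cell a pair of mRNAs regularly falls within the axial resolution limit
(σ~z~ = 350 nm over 200 nm planes) and fuses into one bright spot, and
discarding such spots would bias per-cell counts low by several percent.
The option is off by default in `buildCellRecords` itself, where one
accepted spot is one mRNA and spot bookkeeping is exactly conservative.

Cells deep in the count distribution's tail (several tens of transcripts)
defeat independent single-emitter fitting altogether: many windows overlap
and the fits become ill-posed. The cohort pipeline therefore cross-checks
every cell's spot-based total against its photometric total — the
background-subtracted photon content of the cell polygon over all planes,
divided by Q~ref~ — which is conserved no matter how badly spots blend.
When the two disagree by more than max(2, 30% of the photometric count),
the photometric count replaces the spot-based one for that cell. Spot-based
counting, with its single-transcript precision, remains the primary path
for the overwhelming majority of cells.

**TS detectability.** A TS with a single nascent transcript is
indistinguishable in intensity from a cytoplasmic mRNA and is rejected by
the 1.5×Q~ref~ brightness rule, so the detected-TS population slightly
overrepresents higher nascent counts. With the zero-truncated Poisson law
at mean 3.6, ~11% of true TS carry n = 1, shifting the detected mean up by
roughly +0.3; this is an inherent property of intensity-threshold TS
calling, not of the implementation.

**Cell-cycle scoring.** The manual scoring procedure (spindle morphology +
tubulin intensity + bud size) is encoded as a fixed decision list evaluated
in order: M if the measured spindle span exceeds 2000 nm; else G2 if the
bud-to-mother area ratio exceeds 0.35; else S if it exceeds 0.05; else G1
if the integrated IF intensity is below the cohort's 40th percentile; else
unscored. The bud ratio is measured from the outline alone: the mother lobe
is the polygon's largest inscribed disk (inflated 8% to absorb boundary
irregularity), grid-counted at 1 px; the spindle span is the largest
pairwise distance between above-threshold IF pixels inside the cell. The
precedence of cues is a design choice — the manual procedure weighs them
jointly — and the percentile threshold deliberately leaves the brightest
unbudded cells unscored rather than guessing.

**Drift QC.** Per-plane lateral shifts are measured between *consecutive*
planes (adjacent planes share spot structure through the axial PSF; a
distant plane pair shares none, so anchoring every comparison at plane 1
is not workable on sparse smFISH content) on 2D-filtered planes, by
windowed phase correlation. The whitened cross-power spectrum is
regularized with a Gaussian low-pass (real-space σ 1.3 px) so the
correlation peak has finite width, and sub-pixel position comes from a
log-parabola, exact for a Gaussian peak — without this, sub-pixel
estimates snap to integers. Shifts are cumulated, the slope is fitted by
least squares, and a stack is flagged above 0.5 px/plane. Featureless
plane pairs are excluded by a content gate and never flag a stack.

**IF quantification.** The integrated IF intensity of a cell is the sum,
inside its outline, of the maximal projection over the configured plane
interval, minus the projection's median. Excluding the lowest three planes
(default) keeps slide debris out of the quantification; the count of
excluded planes is configurable because the debris layer's thickness is a
property of the sample preparation.

## Problem sizes

The validation suite runs, as the package's standard desk-scale study: a
1000-cell cohort (40 positions of 25 cells at 512×512×41 voxels) for the
end-to-end expression statistics; ten 100-spot fields for detection
precision/recall; 200 single-spot replicates for localization error; a
seven-step nascent ladder (n = 2…8, eight cells each); and 1000 simulated
688-cell count cohorts for bootstrap-CI coverage. These sizes are chosen so
that Monte-Carlo error is well below each check's tolerance.

## Known limitations

* Counting accuracy degrades in cells far into the negative-binomial tail
  (≳30 transcripts), where overlapping-spot decomposition by intensity
  ratio carries most of the weight.
* The TS model places full-brightness molecule equivalents at the site;
  real nascent transcripts are partially synthesized and partially probed,
  so real TS intensities are lower relative to n than the synthetic ones.
* Phase scoring assumes segmented outlines of single cells; it has no
  notion of doublets or mis-segmentation.
* The accession's raw stacks are not redistributed here; reproducing the
  deposited dataset's headline numbers requires downloading it and running
  the same chain on its TIFFs and outline files.

## A minimal worked example

```{r example, eval = FALSE}
params <- scenarioParams(nCells = 25, seed = 1)
res <- runCohortAnalysis(params, nCellsTotal = 100, seed = 20,
                         nBoot = 2000)
res$summary          # cohort aggregates
res$metrics$spot_f1  # detection quality against the generator truth
```
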