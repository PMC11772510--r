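---
title: "Correlating lipid and elemental mass spectrometry images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating lipid and elemental mass spectrometry images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimodal)
```

## The analysis problem

Two mass spectrometry imaging modalities can be acquired from one tissue
section: a soft-ionisation MALDI-type run that records a centroided lipid
mass spectrum per pixel, and an LA-ICP-MS run that ablates the section
line by line and records elemental ion counts over time. The scientific
question is spatial: which lipid species co-distribute with which
elements? `msimodal` answers it by rendering per-lipid ion images,
converting elemental line scans to quantified rasters, co-registering the
two grids from landmark correspondences, and comparing every
(lipid, element) channel pair pixel-to-pixel with Pearson's correlation
coefficient.

Each stage is an exported function; the `run_*` family chains them
through files so phantoms and real data travel the same path.

## Ion-image rendering

An ion image for target mass $m$ at tolerance $t$ ppm sums, per pixel,
all peak intensities with $|m_i - m|/m \le t \times 10^{-6}$. The window
is two-sided, relative to the target, and inclusive at its bounds — the
community convention; the default is 10 ppm. Extraction is exact
arithmetic on the stored peak list, with no resampling or profile
handling: profile-mode imzML is rejected loudly, because silently
centroiding someone's data is worse than refusing it.

**TIC normalisation** divides each pixel by its total ion current (the
summed intensity of the *entire* spectrum, not just the window). This
cancels per-pixel acquisition variability exactly: multiplying one
pixel's spectrum by any positive factor leaves the normalised image
unchanged, a property the test suite asserts to machine precision. The
result is a pure ratio; no rescaling by the mean TIC is applied, since
Pearson correlation downstream is scale-invariant.

**Hotspot clipping** caps an image at the $q$-quantile (default 0.99,
linear interpolation between order statistics) of its nonzero pixels.
Zeros are off-tissue background; including them would deflate the
threshold, though `nonzero_only = FALSE` restores the all-pixel variant
for comparison with tools that do otherwise. Clipping is *saturation*:
re-clipping an already-clipped image is a no-op. This is deliberate —
re-estimating the quantile on clipped data would creep the threshold
downwards on every application (clip 1..100 at 0.99 and the interpolated
quantile of the result is 99.0001, not 99.01), so idempotence has to be a
property of the operation, not of the arithmetic. Clipping is applied for
display only; correlation consumes normalised, un-clipped images, with a
config flag to clip first if desired.

**Mass recalibration** fits a single global multiplicative factor from
known endogenous lipid masses: for each reference, all observed peaks in
a search window are pooled across pixels, their intensity-weighted mean
m/z is the observed position, and the factor is the intensity-weighted
mean of theoretical/observed ratios. A single global factor is the
simplest model consistent with calibrating on a handful of endogenous
signals; per-pixel or polynomial models would be unidentifiable from so
few anchors. Corrections beyond ±100 ppm trigger a warning, since no
plausible instrument drift is that large.

## Elemental quantification

Line scans are rasterized by interval membership: a reading at time
$\tau$ sits at along-line position $\tau v$ (scan speed $v$), and all
readings in $[k p, (k+1) p)$ average into pixel $k$ of that line's row
(pixel pitch $p$). Half-open intervals mean every reading lands in
exactly one pixel — a conservation property the tests check literally. At
the reference geometry (750 µm/s, 30 µm pixels) the dwell is 0.04 s, so
several ICP readings fall in each pixel; averaging (median available as
an option) is the natural aggregator and interpolation would fabricate
sub-dwell information.

External calibration fits ordinary least squares of per-standard mean
counts against nominal mg/kg, with the intercept *fitted*, not forced
through zero: gelatine standards have a nonzero elemental blank, and the
0 mg/kg standard carries it. Quantification maps counts through the
inverted line, $(c - b)/a$. Negative concentrations are reported, not
clamped — clamping would bias region means and correlations — and a QC
entry in the stack metadata counts affected pixels. Channels without
usable standards pass through in counts/s; because the calibration map is
affine, Pearson coefficients are identical whether computed on counts or
mg/kg (asserted in tests), which licenses correlating unquantified
channels.

## Registration

The transform family is affine by default, degrading automatically to
similarity (2 pairs) or translation (1 pair) when landmarks are scarce.
Both acquisitions image the same physical section, so non-rigid warping
is excluded by design; affine subsumes the translation + rotation + scale
needed to co-mount the two grids, plus any residual shear from stage
geometry. The affine fit solves the normal equations; the similarity fit
is the closed-form scaled-rotation (SVD) solution without reflection.
Collinear landmark triples are refused by name rather than silently
producing a rank-deficient fit.

Resampling pulls: each fixed-grid pixel centre maps through the inverse
transform and samples the moving image, avoiding holes. Pixel centres sit
at integer coordinates; landmarks are expressed in each grid's own pixel
units, so unequal pixel pitches are absorbed into the fitted linear part.
Bilinear interpolation (default) renormalises weights around missing
neighbours and returns missing when all four are; nearest is available
for label-like data. The fixed frame is the spectral (lipid) grid —
lipid imaging runs first in the non-destructive workflow and defines the
reference — but the direction is a configuration choice.

## Correlation

The mask is the AND of spectral coverage (TIC > 0) and elemental
completeness, so off-tissue and out-of-overlap pixels never enter.
Within the mask, each (lipid, element) cell uses pairwise-complete
deletion — two images are compared at a time, and discarding a pixel for
every pair because one channel is missing there would waste data. Cells
with fewer than two complete pixels, or a constant channel, are an
explicit `NA`: reporting 0 would fabricate "no correlation". No p-values
are attached; the analysis reports coefficients, and spatial
autocorrelation would invalidate naive significance tests anyway.

False-colour composites rescale each channel independently to [0, 1]
after its own 0.99-quantile clip and blend additively: red/blue, or
magenta/cyan where co-localised signal tends toward white.

## The phantom: what it emulates and what it does not

`phantom_config()` / `generate_phantom()` build a brain-like section from
nested ellipses: a cortex-like tissue ellipse, an inner white-matter
ellipse, and a hippocampus-like ring, on a 400 × 300 px grid at 30 µm —
about a 1.2 cm section, a realistic size; small grids exaggerate the
fraction of region-boundary pixels and with it resampling error. Each
channel takes one mean per region; lipid pixels draw
$\max(0, \mathcal{N}(\mu, 0.15\mu))$ times a per-pixel TIC factor uniform
in [0.5, 2] — the explicit mechanism that makes TIC normalisation
consequential — and elemental pixels draw Poisson counts. The elemental
modality is rendered on a grid misaligned by a known similarity transform
(5°, (4.5, −3.2) px) and six peripheral fiducial landmarks carry the
transform with 0.5 px jitter; a wide landmark design keeps affine
extrapolation error small over the tissue, which is where fiducial
markers are placed in practice anyway.

The default region means are strongly contrasted (≥3× between low and
high regions per channel, elemental means at realistic 10²–10³ counts/s).
This is a deliberate modelling choice: the analytic population
correlation is only recoverable from noisy renders when between-region
variance dominates pixel noise. TIC normalisation makes lipid images
compositional (each pixel's channels are ratios summing to 1), so weakly
contrasted mean profiles would be flattened into noise-dominated ratio
images and any finite-sample estimate would be attenuated far below the
population value — not a pipeline defect but a property of Pearson
correlation under measurement error.

`expected_correlation()` is the closed-form population coefficient over
the tissue mask, computed from region areas and means with the lipid
channel taken after noiseless TIC normalisation (region mean divided by
the region's summed lipid means) — exactly what a noise-free pipeline
produces, which is why the noiseless identity-transform run matches it to
float precision.

What the phantom does *not* emulate: matrix application physics, ion
suppression, analyte delocalisation by washing, ablation-depth effects,
isobaric interferences, detector drift. Passing tests therefore show the
*computational* chain is correct and stable under realistic noise; they
say nothing about those acquisition-side effects in real data.

## Numerical choices and degenerate inputs

- Quantile type 7 (linear interpolation) everywhere a quantile appears.
- Empty spectra are first-class: TIC 0, ion-image value 0, masked out.
- An all-zero ion image clips to itself with `clipped_at = 0`.
- Duplicate m/z within a pixel are merged by summing on construction;
  non-increasing m/z from files is re-sorted with a warning.
- Transforms with $|\det A| \le 10^{-8}$ are refused.
- The imzML binary UUID is derived from the peak data (MD5), so
  identical images serialise byte-identically and provenance-equal runs
  can be diffed at the file level.
- Provenance records carry no timestamps for the same reason.

## Problem sizes in the test suite

Oracle-equivalence tests run on hundreds of 3×3-ish fixtures; recovery
tests use 10 seeds at 40×30 (recalibration), 160×120 (registration), and
the full default 400×300 phantom for end-to-end correlation recovery;
the file-based pipeline tests use 48×36 phantoms. These sizes were chosen
so the whole suite exercises every path in a few minutes on one core
while keeping boundary-pixel fractions representative.

## Known limitations

- Only centroided data; no peak picking, no ion mobility dimension.
- imzML support covers the processed/continuous, uncompressed or
  zlib-compressed, 32/64-bit numeric subset — no vendor raw formats.
- One global recalibration factor; no per-pixel mass drift model.
- No drift or internal-standard correction for LA-ICP-MS, no limits of
  detection.
- Landmark-based registration only; no intensity-based or deformable
  alignment.
- Pearson only; no spatially aware statistics (Moran's I, variograms) or
  other colocalization metrics.
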