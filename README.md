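# msimodal

Correlating lipid and elemental mass spectrometry imaging of a single
tissue section.

Modern multimodal MSI workflows image one section twice: a soft
atmospheric-pressure MALDI-type run records a centroided lipid spectrum
per pixel (imzML), and an LA-ICP-MS run ablates the section line by line,
yielding elemental counts per position. `msimodal` is the analysis side
of that workflow, for mass-spectrometry imaging groups who need the two
modalities on one grid and a number for every channel pair:

1. **Ion imaging** — per-lipid images by ppm-window extraction
   (default 10 ppm), total-ion-current normalisation, 99%-quantile
   hotspot clipping, global mass-axis recalibration from endogenous
   lipid references, and accurate-mass annotation at 5 ppm against a
   lipid mass list.
2. **Elemental quantification** — time-resolved line scans rasterized by
   dwell-interval averaging (position = time × scan speed), then external
   calibration against spiked gelatine standards: ordinary least squares
   of mean counts vs nominal mg/kg, applied as
   `concentration = (counts − intercept) / slope`; channels without
   standards pass through in counts/s.
3. **Registration** — least-squares affine (auto-degrading to
   similarity/translation) from landmark correspondences, with pull
   resampling of the elemental stack onto the lipid grid.
4. **Correlation** — Pearson's
   `r = Σ(x−x̄)(y−ȳ) / √(Σ(x−x̄)² Σ(y−ȳ)²)`
   per (lipid, element) pair over a shared tissue mask with
   pairwise-complete pixels, exported as a heatmap (CSV + PNG) and
   two-colour composites (red/blue, magenta/cyan).

A phantom generator renders paired two-modality datasets of a
brain-like section (cortex / white matter / hippocampus-ring regions)
with a known misalignment, known channel-by-region means and therefore
*analytic* ground-truth correlations — every stage and the full chain
are validated against it.

## Worked example

```r
library(msimodal)

ph  <- generate_phantom(phantom_config(width = 120, height = 90, seed = 42))
res <- correlate_phantom(ph)   # render -> extract -> calibrate -> register -> correlate
res$transform
#> <affine2d> family affine, rmse 0.696 px
#>   [ 0.99867 -0.08742 |  8.6039]
#>   [ 0.08898  0.99576 | -8.0724]
res$correlation
#> <correlation_matrix> 5 lipid x 5 element channels over 6856 mask pixels
#>                 23Na   24Mg    31P   56Fe   66Zn
#> PE 34:1        0.934  0.933  0.888 -0.525 -0.438
#> PE 36:1       -0.316 -0.314 -0.167  0.976  0.975
#> PE 38:4       -0.741 -0.743 -0.826 -0.310 -0.404
#> PE 40:6        0.940  0.940  0.899 -0.497 -0.409
#> HexCer 42:2;2 -0.730 -0.732 -0.819 -0.335 -0.429
```

The fitted transform undoes the phantom's 5° / (4.5, −3.2) px
misalignment to sub-pixel residuals, and the correlation matrix reads as
the phantom was built: the cortex-weighted PEs track Na/Mg/P, the
ring-enriched PE 36:1 tracks Fe/Zn, and the white-matter HexCer
anti-correlates with the cortical elements. On the default full-size
phantom (400 × 300 px) every coefficient lands within ±0.05 of the
analytic population value `expected_correlation_matrix(ph)`; this
120 × 90 px miniature sits at the edge of that band because boundary
pixels make up more of a small image.

Annotation resolves isobars rather than hiding them:

```r
db <- read_lipid_db(system.file("extdata", "lipid_db.csv", package = "msimodal"))
write_annotation_report(annotate(c(746.5672, 810.6817), db, 5), "ann.csv")
#>   observed_mz     best_name best_adduct   best_ppm                       all_matches
#> 1    746.5672       PE 36:1      [M+H]+ -2.9870    PE 36:1 [M+H]+/PC 34:1-CH3 [M+H]+
#> 2    810.6817 HexCer 42:2;2      [M+H]+ -0.0617                 HexCer 42:2;2 [M+H]+
```

File-based runs chain the same stages behind a flat YAML config
(`run_all()`, or the `inst/cli/msimodal` script with subcommands
`simulate | extract | quantify | register | correlate | run-all`); with
no parameter flags the provenance records the standard settings
(10 ppm, TIC on, 0.99 clip, 5 ppm annotation).

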