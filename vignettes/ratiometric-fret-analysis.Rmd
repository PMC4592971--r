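---
title: "Quantifying ratiometric FRET biosensor movies: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ratiometric FRET biosensor movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkit)
```

## The measurement problem

Single-chain FRET biosensors report the activation state of a signalling
protein (here, a RhoA-family GTPase reporter) as the ratio of sensitized
acceptor emission to donor emission. In a live-cell recording the raw camera
channels are contaminated by background, by spectral bleedthrough of the
donor into the acceptor channel, and by small optical misalignments between
the two detection paths. `fretkit` implements the full chain from raw
multi-channel TIFF movies to per-cell kinetic and spatial statistics, and
ships a forward-model simulator so every stage can be validated against known
ground truth.

## The correction chain

For each frame and channel:

1. **Background**: the modal pixel value of the integer-rounded histogram is
   subtracted (ties break toward the lower intensity). The mode is robust to
   the minority of bright cell pixels. Negative corrected values are retained
   -- clipping would bias the region medians computed later.
2. **Registration**: one global integer-pixel shift of the acceptor channel is
   estimated per movie by exhaustive normalized cross-correlation within
   `±max_registration_shift`; a best shift on the search boundary is an
   error, not a result. Sub-pixel alignment is deliberately not attempted.
3. **Bleedthrough**: sensitized emission is `acceptor − α · donor`, with
   `α ≈ 0.55` for the widefield filter configuration and `α ≈ 0.32` for
   confocal. `calibrate_bleedthrough()` re-estimates α from a donor-only
   specimen as the median pixelwise acceptor/donor ratio.
4. **Ratio**: the per-region FRET readout is the *ratio of medians*
   (`median(sensitized)/median(donor)` over the region), which a single hot
   pixel cannot move. The pixelwise ratio image (`ratio_image()`) is used for
   display; pixels with donor at or below `donor_floor` are flagged invalid.

A `region_statistic = "mean"` switch reproduces the mean-based variant used
for static single-frame comparisons; the median is the default because it is
the convention the time-lapse analyses anchor on.

## Segmentation

Cells are segmented by seeded watershed on the (Gaussian-smoothed, inverted)
summed time series, with manual seed points and optional barrier polylines
between touching cells; an automatic background marker competes in the flood
so that labels do not leak into empty field. Because the neuronal cells
analysed here do not migrate, the watershed is run once per movie and defines
static *starting regions*.

Per-frame *cell regions* are carved inside each starting region by the
threshold cascade:

* **fivefold background s.d.**: keep pixels above `bg_mean + 5·bg_sd`, with
  background statistics from pixels outside all starting regions (recomputed
  per frame by default, so lamp drift does not masquerade as retraction);
* **area refinement**: within the cell region, only pixels above 10% of the
  region's 99th percentile count toward the cell area (percentiles by linear
  interpolation between order statistics, R type 7 -- stated explicitly
  because P99 on small regions is convention-sensitive);
* **15% of max**: the single-frame variant keeps pixels above 15% of the
  region maximum.

Morphological sub-regions use the 3×3 8-connected structuring element, with
"eroding by N pixels" meaning N iterations: the **cortex band** is the mask
minus its `width`-fold erosion (default 5 px), the **center** for recruitment
readouts is the 9-fold erosion. Note the Chebyshev geometry this implies: a
cell body must fit a 19×19 square for the 9-px center to be nonempty.

## Kinetics and spatial statistics

Traces are normalised to the mean of all pre-stimulus frames and expressed as
percent change. The response half-time **t½** is the interval between
stimulus addition and the first linearly-interpolated crossing of half the
post-stimulus maximum, with the maximum taken over the unsmoothed trace in
the stated window (first crossing wins; optional moving-average smoothing is
off by default and logged when used). A trace whose in-window maximum is not
positive is flagged "no response" rather than given a number.

The **CX−CB statistic** quantifies spatial inhomogeneity of activity: the
region ratio in the 5-px cortical band minus the region ratio in the eroded
body, computed per frame from identically corrected inputs and averaged over
the analysis window. Positive values mean cortex-enriched activity, negative
body-enriched. Cells are compared at matched expression by gating on the
background-corrected mean marker (RFP) intensity, inclusive bounds 50-300
camera units.

## The synthetic world

The generator (`scene_spec()` and friends) renders movies with a
total-intensity model: inside a cell every pixel splits a fixed photon budget
`T0` between donor `T0/(1+R)` and sensitized `T0·R/(1+R)`, so the true ratio
is exactly `R` everywhere before instrument effects. The recorded acceptor is
`sensitized + α·donor`, optionally displaced by an integer registration
offset; background is added and shot (Poisson) plus read (Gaussian) noise
applied at gain 1 count/photon. True three-filter-cube photophysics is out of
scope; this model reproduces the donor-decrease/acceptor-increase
anticorrelation that defines the measurement.

Defaults are chosen once to emulate the recordings the analysis was designed
for, and are not revisited:

* **Field**: 160×160 px; 1-4 elliptical cell bodies (semi-axes 15-17 px) on a
  fixed safe grid, each with two 26×5 px neurites fanned toward the image
  centre so geometry never clips the border or a neighbour. Bodies must be at
  least 15 px in semi-axis for the 9-px center erosion to survive; neurites
  carry 22-27% of cell area so that a 20% retraction is attainable by neurite
  loss alone.
* **Signal**: `T0 = 1000` counts, background 100 counts, read noise 2 counts
  -- an in-cell SNR of ~98, typical of a well-exposed cooled-CCD recording;
  tests that need a specific SNR set `T0 = SNR·σ_bg` explicitly.
* **Kinetics**: agonist at 60 s and antagonist at 240 s, 5 s frames, a 40%
  ratio rise with `k_on = ln2/20 s⁻¹` and decay `k_off = ln2/60 s⁻¹`,
  matching the scale of fast GPCR-driven responses (half-times of tens of
  seconds).
* **Marker**: uniform at 150 counts (inside the 50-300 expression gate).
  Recruitment scenes partition the marker between a uniform cytosolic pool
  and a target compartment (plasma-membrane rim band, or the 9-px-eroded
  center as a nuclear stand-in); after the stimulus the cytosolic fraction
  decays exponentially while the per-cell total is conserved every frame.
* **Retraction**: the true area follows a linear schedule from baseline to
  the target fraction (default 0.85, within the observed 10-20% loss),
  removing neurite pixels farthest from the body first, so neurites retract
  from their tips and the body is preserved.
* **Spatial patterns**: `cortex_enriched`/`body_enriched` elevate `R` by 30%
  in a 5-px band matching the analysis band width. The band-step shape is a
  stand-in -- no quantitative gradient shape is established for the real
  cells -- and is labelled as such in the ground-truth sidecar.

Every simulator output is a deterministic function of `(spec, seed)`; the
sidecar JSON records the spec, the per-cell true ratio trajectories and
areas, and the scene SNR so tests can state noise preconditions.

What a green test establishes: that the estimators invert the stated forward
model at the stated noise levels. What it does not establish: performance
under photobleaching, cell migration, focus drift, spatially varying
background, or optical blur -- none of which the generator emulates.

## Numerical choices

* Modal background: integer-rounded histogram, ties toward the lower value.
* Percentiles: linear interpolation (R `quantile` type 7).
* Erosion: 3×3 8-connected, N px = N iterations.
* Watershed: Gaussian pre-smoothing σ = 2 px; flooding priorities quantised
  to 64 levels (label maps on smoothed landscapes are insensitive to the
  quantisation; runtime scales with it); ridge ties resolve toward the
  lowest competing label so cell seeds beat the background marker.
* Background marker: pixels below `mode + max(5·sd_below_mode, 2% of dynamic
  range)`; the range floor keeps the marker meaningful on noiseless data
  where the s.d. collapses to zero.
* Registration: integer shifts only, one global shift per movie (per-frame
  alignment is unwarranted without evidence of stage drift, and is logged as
  an open choice).
* t½ interpolation: linear between the two frames bracketing half-maximum.
* Default `donor_floor` guidance: ~5× the background s.d. after correction.
* Config files are JSON; trace CSVs store doubles at 17 significant digits so
  write→read round trips are exact.

## FLIM and spectra

The frequency-domain phase lifetime is the closed form
`τ_φ = tan(φ)/(2πf)` (75.1 MHz in the validation experiments); only the
closed form is implemented -- full phasor fitting belongs to the instrument's
own software. FRET efficiency from donor lifetimes is `E = 1 − τ_DA/τ_D`.
Emission spectra are normalised per cell by the mean acceptor-band intensity,
making spectra from differently expressing cells comparable; averaging
reports mean ± s.e.m. per wavelength. Simulated lifetime pairs default to
2.9/2.4 ns, the scale separating the reporter's bound and unbound states.

## Known limitations

* Watershed quality depends on the seeds; there is no seedless mode.
* Integer-pixel registration cannot correct sub-pixel misalignment.
* The percentile-based area threshold assumes the current frame's intensity
  distribution; a cell that dims uniformly keeps its area by construction.
* The simulator's band-step activity gradients and linear retraction
  schedules are idealisations; recovery tolerances quoted in the tests are
  for these idealised scenes.
* Statistical group comparisons are thin wrappers over standard two-sample
  tests (`wilcox.test`, `t.test`) and are intentionally not re-derived.
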