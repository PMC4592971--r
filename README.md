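# fretkit

Quantitative analysis of ratiometric FRET biosensor time-lapse recordings —
the kind of live-cell experiment in which a single-chain GTPase activity
reporter is imaged in donor (CFP), acceptor (YFP) and marker (RFP) channels
while cells are stimulated, and the biology is read out as ratio kinetics,
spatial activity gradients and morphological responses such as neurite
retraction.

The package is aimed at microscopists and image analysts who need the full
chain from raw multi-page TIFF movies to per-cell statistics, with every
stage testable against synthetic ground truth.

## What it computes

**Correction chain.** Per channel and frame: modal-background subtraction,
one global integer-pixel registration of the acceptor channel (normalized
cross-correlation), and donor bleedthrough removal

    S = Y − α·D        (α ≈ 0.55 widefield, 0.32 confocal)

where `D` is the corrected donor image, `Y` the corrected acceptor image and
`S` the sensitized emission. The region FRET readout is the ratio of medians

    R = median(S | region) / median(D | region).

**Segmentation.** Seeded watershed of the summed time series (with manual
seeds and optional separation barriers) gives static starting regions;
per-frame cell regions are pixels above `bg_mean + 5·bg_sd`; the cell area
counts pixels above 10% of the region's 99th percentile; single-frame
analyses use pixels above 15% of the region maximum. Sub-regions: a 5-px
cortical band (mask minus its 5-fold erosion) and a 9-px-eroded center.

**Statistics.** Baseline-normalised percent-change traces; response
half-time `t½` = time from stimulus to the first interpolated crossing of
half the post-stimulus maximum; the spatial statistic
`Δ = R(cortex) − R(body)` (positive ⇒ cortex-enriched activity); expression
gating on mean marker intensity (50–300 a.u.); fold changes against
untransfected controls. Frequency-domain FLIM phase lifetimes
`τφ = tan(φ)/(2πf)` and acceptor-normalised emission spectra support sensor
validation.

**Synthetic movies.** A forward-model generator renders multi-channel movies
of neuronal-like cells (elliptical bodies, thin neurites) with known ratio
fields, stimulus kinetics, marker recruitment/translocation, programmed
neurite retraction, bleedthrough, registration offsets and camera noise —
deterministic per `(scene, seed)`, with a ground-truth JSON sidecar.

## Worked example

Simulate a two-event stimulus-response recording and analyse it end to end:

```r
library(fretkit)

spec <- scene_spec(n_cells = 2, duration_s = 300, frame_interval_s = 5,
                   event_times_s = c(60, 240))   # agonist, antagonist
sim <- run_pipeline("simulate", out_dir = "sim", spec = spec, seed = 1)

cfg <- load_config("sim/config.json")
res <- run_pipeline("analyze-gpcr", out_dir = "gpcr",
                    movie = "sim/movie.tif", config = cfg,
                    seeds = "sim/seeds.json")
subset(res$cells, event == "agonist")
#>   cell_id   event t_half_s amplitude_percent no_response
#> 1       1 agonist 19.66995          41.67995       FALSE
#> 3       2 agonist 20.14782          42.40933       FALSE
```

Both simulated cells responded (no_response = FALSE) with a ~42% peak ratio
increase over baseline and a half-time of ~20 s after agonist addition —
matching the programmed kinetics (40% amplitude, `k_on = ln2/20 s⁻¹`). The
output directory also contains `traces.csv` (per-frame ratio and
percent-change traces per cell) and `run_log.json` recording every parameter
used, sufficient to re-run identically.

The other stages work the same way: `analyze-retraction` reports per-frame
cell areas as percent of the pre-stimulus baseline plus localized FRET and
recruitment traces, `analyze-spatial` reports the per-cell cortex-minus-body
statistic with expression gating, and `calibrate-bleedthrough` estimates α
from a donor-only movie. A thin command-line wrapper over the same
`run_pipeline()` calls is at `inst/cli/fretkit.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline pipeline from scratch at the given seed:
it simulates a stimulus-response recording, a neurite-retraction recording
and a cortex-enriched spatial scene, runs the corresponding analysis stages
on the written TIFF/JSON artifacts, logs the recovered kinetics, area and
spatial statistics, and writes the JSON result manifest to `--out`.

## Package layout

* `R/` — implementation: TIFF codec, movie/trace/config I/O, correction
  chain, segmentation and morphology, kinetics and spatial statistics,
  retraction pipeline, FLIM/spectra closed forms, scene simulator, pipeline
  driver.
* `tests/testthat/` — unit, property and acceptance suites; all fixtures are
  generated in code.
* `vignettes/ratiometric-fret-analysis.Rmd` — the methods vignette: models,
  assumptions, parameter defaults and their rationale, numerical choices and
  limitations.
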