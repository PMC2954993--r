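# spectrack

Multicolor nuclear cell labeling, multispectral imaging simulation, and
spectral-fingerprint cell tracking.

## The problem

Following single cells in dense embryonic tissue (e.g. migratory neural
crest streams) breaks down in two ways. Automated **counting**
undercounts: nuclei are ~10 µm across, and once density rises past a
fraction of a cell per 100 µm², same-colored labels merge into single
segmented objects. Positional **tracking** loses identities: when k
cells cross within the optical resolution limit there are k! possible
reassignments afterwards, and a tracker using position alone must
guess. Labeling each cell with a random cocktail of up to three nuclear
fluorescent proteins (2³ − 1 = 7 distinguishable combinations) helps on
both fronts, and gives every cell a **spectral fingerprint** — the
normalized fractions of its total intensity per fluorophore, whose rank
order ("red higher than green") is stable over hours and survives cell
division.

`spectrack` provides that toolbox as testable, reproducible code:

* **Counting simulation** — square nuclear footprints seeded uniformly
  in a rectangular region; a color-aware segmentation merges
  overlapping same-color cells; density sweeps compare 1-color,
  3-color (no mixing) and 3-color (mixing) labeling
  (`seedCells`, `assignColors`, `segmentObjects`, `runDensitySweep`).
* **Synthetic multispectral movies** — Gaussian-nucleus image formation
  on lambda-stack channel layouts (12 channels, 494–623 nm at 10.7 nm
  by default), with crossing / swap / division / random-walk scenarios
  and full ground truth (`makeCrossingScenario`, `makeSwapScenario`,
  `makeDivisionScenario`, `makeRandomWalkMovie`, `renderFrame`).
* **Linear unmixing** — per-pixel non-negative least squares against
  unit-sum reference spectra, autofluorescence column subtraction, the
  125%-of-background-maximum threshold rule, maximum intensity
  projection (`unmixStack`, `backgroundThreshold`, `applyThreshold`,
  `maxIntensityProjection`).
* **Spot detection & counting** — FWHM-matched Gaussian smoothing,
  local maxima, single-linkage spot linking with label-specific
  parameters (DiI 2 µm spots / 5 µm linking; nuclear 5 µm / 2 µm;
  membrane 10 µm), tissue-density estimation (`detectSpots`,
  `linkSpots`, `countCells`, `estimateDensity`).
* **Tracking** — optimal frame-to-frame assignment with a fingerprint
  cost term, conflict (crossing) detection, backward/forward spectral
  re-identification, ambiguity flagging, and ground-truth evaluation
  against a spectrum-blind baseline (`spectralTrack`,
  `nearestNeighborTrack`, `evaluateTracking`, `computeFingerprint`).

## Worked example

```r
library(spectrack)

# counting accuracy vs density under 3-color mixed labeling
runDensitySweep("mix", densities = c(0.6, 1.0, 1.6), reps = 1000, seed = 1)
#>   scheme density mean_fraction sd_fraction reps
#> 1    mix     0.6         0.858      0.0445 1000
#> 2    mix     1.0         0.769      0.0402 1000
#> 3    mix     1.6         0.653      0.0353 1000

# a two-cell trajectory crossing, tracked by spectral fingerprint
mv   <- makeCrossingScenario(2, render = FALSE, seed = 1)
dets <- truthDetections(mv, noiseSd = 0.1, seed = 2)   # 10% intensity noise
ts   <- spectralTrack(dets)
ts
#> TrackSet (spectral): 2 tracks over 21 frames
#>   conflicts 1, resolved by spectrum 1, ambiguous 0
evaluateTracking(ts, movieTruth(mv))$switches
#> [1] 0
evaluateTracking(nearestNeighborTrack(dets), movieTruth(mv))$switches
#> [1] 2
```

At density 0.6 the mixed 3-color scheme still counts ~86% of cells
(1-color counts ~30%), and the mixing curve stays above 65% out to
density 1.6 where 1-color has collapsed to ~2% — the quantitative case
for multicolor labeling. In the crossing example, both trackers face
the same conflict; only position+fingerprint cost resolves it (0
identity switches vs 2 for the blind tracker).

A command-line wrapper over the same functions ships in
`inst/cli/spectrack.R` with subcommands `simulate-counting`,
`synth-movie`, `unmix`, `track` and `run-pipeline`; every subcommand
takes `--seed` and logs its resolved parameters. See the vignette
(`vignettes/spectral-toolbox.Rmd`) for the model details, parameter
defaults, and design decisions.

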