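# cr39dose

LET spectroscopy and cell-scale dosimetry for CR-39 alpha-particle
autoradiography in R.

## The problem

Targeted alpha therapy (for example 211At-labelled antibodies) deposits its
dose over cell-sized distances, so organ-level dosimetry says little about
what individual tumor and normal cells actually receive. CR-39 plastic
nuclear track detectors solve this: a tissue section mounted on the
detector exposes it to every alpha decay, and chemical etching turns each
particle traversal into a microscopic conical pit whose elliptical aperture
encodes the particle's linear energy transfer (LET) and incidence angle.
Scanning the etched detector gives a per-track, photon-background-free map
of the alpha emission with sub-micron position resolution.

`cr39dose` is for researchers analysing such autoradiographs (or validating
analysis chains for them). It implements the full chain from etch-pit
tables to tissue dosimetry, plus a synthetic tissue phantom with complete
ground truth for end-to-end validation.

## The model

For a pit with elliptical aperture axes `D_A >= D_B` (um) on a detector
with bulk etch removal `B` (um), the detector response is

    S = sqrt( 16 B^2 D_A^2 / (4 B^2 - D_B^2)^2 + 1 ) - 1

which reduces to `S = 2 d^2 / (4 B^2 - d^2)` for circular pits. The
response fixes the critical dip angle and isotropic detection efficiency

    sin(theta_c) = 1 / (S + 1),      eta = 1 - sin^2(theta_c)

and maps to LET in water through a monotone calibration curve (a
documented synthetic power-law stand-in `S = (L/100)^1.5` is shipped;
supply your own knot table for a calibrated batch). Weighting each
registered track by `1/eta` gives the incident fluence per LET bin
`phi_i` (cm^-2), from which absorbed dose follows as

    D (Gy) = 1.6e-9 / rho * sum_i phi_i L_i

evaluated either over a whole region or per 10 um cell. Because the
detector only records between tissue mounting (`t1`) and removal (`t2`)
while activity decays with constant `lambda`, the unrecorded initial dose
is added through

    D0 / D = (1 - exp(-lambda t1)) / (exp(-lambda t1) - exp(-lambda t2))

Tissue micrographs are registered to the detector frame with an affine
transform fitted to scratched markers, segmented by a gray threshold
(tissue vs blank) and an RGB band-pass (eosin-pink tumor vs purple
normal), and the headline statistic is the concentration efficiency: the
pink-to-purple track density ratio with 1-sigma Poisson counting errors.

## Worked example

The synthetic phantom renders a two-region tissue (eosin-pink tumor foci
in purple liver, 6:1 activity contrast), simulates 211At decays and
angular acceptance, forward-models the etch pits, and then analyses the
persisted pit table, micrograph and markers exactly as real data:

```r
library(cr39dose)
report <- runPipeline(phantomConfig(seed = 20), outdir = "run1")
summarizeReport(report)
#> tracks: 22185 (of 22185 pits)
#> pink:   29765.0 +/- 257.7 tracks/mm^2 (13344 in 0.448 mm^2)
#> purple: 4939.2 +/- 52.5 tracks/mm^2 (8841 in 1.790 mm^2)
#> concentration efficiency: 6.03 +/- 0.08
#> LET spectrum mode: 130 keV/um (22185 tracks in tissue)
#> decay correction factor D0/D: 2.291
#> total dose: mode 0.75 Gy, range 0.59-9.25 Gy
```

The recovered concentration efficiency (6.03 +/- 0.08) covers the
simulated 6:1 contrast; the reconstructed LET spectrum peaks at
130 keV/um, the mode of the phantom's alpha source model; and the decay
factor 2.291 is the closed-form value for a 7.2 h half-life recorded over
12-43 h. Every intermediate (derived track table, masks, spectrum, dose
and density maps, JSON report) is persisted under `outdir`, and every
exclusion (over-etched pits, out-of-range responses, out-of-grid tracks)
is counted in the report -- nothing is dropped silently.

A thin command-line front end with `simulate` / `analyze` / `report`
subcommands is installed at `inst/scripts/pipeline.R`; `analyze` is driven
by a YAML run config whose defaults are the standard protocol values
(`B = 3.3 um`, half-life 7.2 h, window 12-43 h, gray threshold 138, pink
bands 123-177 / 42-84 / 94-139, 10 um dose cells, 50 um density bins).

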