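---
title: "Cell-scale alpha-particle dosimetry with CR-39: models, parameters and design choices"
author: "cr39dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-scale alpha-particle dosimetry with CR-39}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cr39dose)
```

# The measurement and its model

A CR-39 plastic nuclear track detector used as a microscope slide records
every alpha decay in a mounted tissue section as a latent damage trail.
Chemical etching (here 7 M NaOH, 70 °C, 2 h, recorded as metadata in
`etchConfig()`) removes a bulk thickness $B$ from the surface and opens
each trail into a conical pit. Three nested models take a scanned pit
table to tissue dosimetry.

## Pit geometry

The etch-rate ratio along and normal to the track determines the pit
shape. With aperture axes $D_A \ge D_B$ (µm) the detector response is

$$S \;=\; \sqrt{\frac{16\,B^2 D_A^2}{(4B^2 - D_B^2)^2} + 1}\; - 1,$$

dimensionless and zero for a vanishing pit. For a circular aperture
($D_A = D_B = d$, normal incidence) this reduces algebraically to
$S = 2d^2/(4B^2 - d^2)$, which the test suite verifies to $10^{-12}$
relative tolerance; the formula is also exactly scale invariant, so only
the shape of a pit relative to $B$ matters.

The response fixes the **critical dip angle** $\sin\theta_c = 1/(S+1)$:
tracks arriving at a dip angle shallower than $\theta_c$ (measured from
the detector plane) are etched away rather than revealed. For an
isotropic flux the registered fraction is the **detection efficiency**

$$\eta \;=\; \frac{\int_{\theta_c}^{\pi/2}\sin\theta\cos\theta\,d\theta}
                 {\int_{0}^{\pi/2}\sin\theta\cos\theta\,d\theta}
        \;=\; 1 - \sin^2\theta_c,$$

strictly increasing in $S$, with the exact complement
$\eta + \sin^2\theta_c = 1$. Weighting each registered track by $1/\eta$
therefore unbiases counts back to incident fluence. The angular flux
density through the detector plane is $2\sin\theta\cos\theta$, which is
also what the simulator samples, so efficiency recovery can be tested
end to end.

**Over-etched pits.** When $D_B \ge 2B$ the denominator vanishes: the
conical-pit model no longer applies. `deriveTracks()` excludes such pits
by default and counts them (`degenerate = "clamp"` instead pins them just
below the degeneracy, where their LET saturates at the calibration
ceiling). Exclusion is the default because an over-etched aperture
carries no usable LET information.

## Response-to-LET calibration

CR-39 registers particles above roughly 3.5 keV/µm and is calibrated
against heavy-ion beams over 3.5–600 keV/µm in water. A measured
batch calibration is a laboratory artifact we cannot ship, so the
packaged default curve is a **synthetic stand-in power law**

$$S = \left(\frac{L}{100\ \mathrm{keV/\mu m}}\right)^{3/2},$$

tabulated on 41 log-spaced knots and clearly labelled as synthetic in its
provenance string and file name. It was chosen once for three
properties: it is strictly monotone, nearly zero at the 3.5 keV/µm
detection threshold ($S \approx 0.0065$), and of order unity at
alpha-particle LETs ($S = 1$ at 100 keV/µm). Interpolation is log–log
linear — positive quantities spanning two decades — which makes the
forward and inverse lookups exact inverses of one another and reproduces
a power law without interpolation error. Users replace the curve with a
two-column knot file via `loadCalibration()`; everything downstream is
agnostic to its origin. Queries below the threshold response raise an
error (such particles are undetectable, and a pit implying one indicates
a measurement problem); queries above the top knot are clipped to the
ceiling and counted.

## From spectrum to dose

The efficiency-corrected fluence in LET bin $i$ over a scored area $A$ is
$\phi_i = \sum_{\text{tracks in } i} (1/\eta) / A$ (cm⁻²), and absorbed
dose follows as

$$D\ (\mathrm{Gy}) = \frac{1.6\times10^{-9}}{\rho}\sum_i \phi_i L_i,$$

with $\rho$ the specific gravity (default 1.0 g/cm³, soft tissue) and
$L_i$ the **arithmetic bin midpoint** — the bin-representative value is a
design choice; with 10 keV/µm bins the midpoint-vs-mean difference is far
below counting noise. Default bin edges are 3.5, 5, 15, …, 595, 600
keV/µm: width 10 with midpoints on multiples of 10, so that a spectral
peak at a round value (the ~130 keV/µm alpha peak) sits at a bin center.
A symmetric peak placed exactly on a bin edge would split its mass evenly
between two bins and make the modal bin a coin flip; centering removes
that degeneracy. The two boundary part-bins cover the calibration range
ends.

Dose maps use square cells of 10 µm — a typical mammalian cell diameter —
and density maps 50 µm bins. Cells are half-open $[low, high)$ in both
axes (a track exactly on an upper edge belongs to the next cell), the
grid origin snaps to the lower corner of the registered tissue bounding
box, and raw counts are stored alongside dose so Poisson uncertainty maps
can be derived later. Every map build satisfies the energy bookkeeping
identity $\sum_{cells} D\,A\,\rho / 1.6\times10^{-9} =
\sum_{tracks} L \cdot w$ to $10^{-9}$ relative tolerance, which the
acceptance suite asserts on simulated maps.

## Decay-window correction

The detector records only decays between mounting at $t_1$ (default 12 h
after injection) and removal at $t_2$ (default 43 h); dose scales with
the number of decays in a window, so the unrecorded initial dose relates
to the observed dose by the decay-count ratio

$$\frac{D_0}{D} = \frac{1 - e^{-\lambda t_1}}
                       {e^{-\lambda t_1} - e^{-\lambda t_2}},
\qquad \lambda = \ln 2 / T_{1/2},$$

and the total dose is $D\,(1 + D_0/D)$, applied cellwise for maps. For
the 211At defaults ($T_{1/2} = 7.2$ h) the factor is 2.2906. The limits
anchor the formula: $t_1 \to 0$ gives 0 (nothing decays before
mounting); $t_1 = T_{1/2},\ t_2 \to \infty$ gives exactly 1 (equal decay
counts before and after). The correction assumes the radiopharmaceutical
is bound from $t = 0$ and that its spatial distribution is stationary
between windows; redistribution before mounting is outside the model.

## Registration and segmentation

The pre-etch tissue image and post-etch detector scan are aligned with a
full six-parameter affine transform fitted by least squares to scratched
marker pairs (four in the standard protocol). Three non-collinear
markers determine the transform exactly (zero residual to machine
precision); with four or more, `rmsResidual()` is the registration QC.
A similarity-only transform was deliberately not used: shear and
anisotropic scale absorb slide-mounting distortion.

Segmentation follows fixed 8-bit thresholds: a pixel is **tissue** iff
its gray value (unweighted RGB mean, rounded half-up; luminance weights
are available) is strictly below 138 — stained tissue is darker than the
blank detector, and the threshold side is configurable since only the
level, not the side, is standard. A tissue pixel is **pink** (eosin,
necrotic tumor) iff R ∈ [123, 177], G ∈ [42, 84], B ∈ [94, 139], all
inclusive; **purple** (normal) is tissue minus pink, so the two regions
partition the tissue by construction. Track-to-pixel assignment is by
nearest pixel center with ties toward the lower index.

The concentration efficiency is the pink-to-purple track density ratio;
its 1-sigma error propagates the independent Poisson counting errors,
$\sigma_r = r\sqrt{N_p^{-1} + N_n^{-1}}$, which a $10^5$-sample
Monte-Carlo propagation in the test suite confirms within 5 %.

# The synthetic phantom

The phantom exists so the full pipeline can be validated against known
truth. It emulates, at desk scale, a stained liver section with tumor
foci on a detector:

* **Geometry.** A 2 × 2 mm field at 2 µm/pixel (1000 × 1000 px): one
  purple tissue ellipse containing two pink tumor ellipses (≈ 0.45 mm²
  tumor, 1.79 mm² normal). The real protocol's 12 × 12 mm at 0.28 µm/px
  is supported but not the default; the desk scale keeps simulations in
  seconds. Fill colors — pink (150, 60, 120), purple (120, 80, 160),
  white background — are verified against the segmentation thresholds at
  build time, so segmentation recovers the truth masks pixel-exactly by
  construction.
* **Source terms.** Activities are expected decays per mm² over all time
  from injection: 120 000 in tumor with a 6:1 tumor-to-normal contrast.
  The absolute activity of the real experiment is not a published
  quantity; these values were fixed once so that the default field
  yields ≥ 2 × 10⁴ registered tracks, giving the concentration-efficiency
  recovery test a propagated error of about 0.08 (so a 3σ coverage check
  is meaningful and fast).
* **Decay and emission.** Decay times follow the truncated exponential
  for the 7.2 h half-life over [0, 43 h]; region event counts are
  Poisson. Dip angles are drawn from $2\sin\theta\cos\theta$; an event
  registers iff $\theta > \theta_c(S(L))$ (strict, so the measure-zero
  equality case never produces a zero-width pit).
* **LET source.** A normal distribution, mean 130 keV/µm, sd 20,
  truncated to 3.5–600: a stand-in shaped to the alpha spectrum observed
  at the detector, not a transport calculation. No slowing-down through
  the 8 µm section is modelled, the distribution is position-independent,
  and only one alpha per decay is emitted (the detector is blind to the
  photon/electron channels). The distribution is pluggable.
* **Forward pit model.** With $V = S + 1$,
  $D_B = 2B\sqrt{(V\sin\theta - 1)/(V\sin\theta + 1)}$ and
  $D_A = (4B^2 - D_B^2)\sqrt{V^2 - 1}/(4B)$, constructed so
  `detectorResponse(D_A, D_B, B)` returns exactly $S$ for any dip angle:
  the minor axis carries the angle, the response survives the round
  trip identically. At normal incidence the pit is circular; just above
  the critical angle the minor axis vanishes.

What passing phantom tests do **not** show about real data: stain
variability and color gradients (phantom colors are flat fills inside
the bands), pit overlap at high track density, detector-batch response
variation, registration error from marker placement (phantom markers are
exact corners), tissue self-absorption, and pharmacokinetic
redistribution. The phantom validates the analysis chain, not the
biology.

# Numerical choices and degenerate inputs

* Axis order is enforced at parse time (swap with a warning) since
  digitized tables may be unordered; non-positive axes are an error.
* LET binning is half-open with a closed last bin, so the calibration
  ceiling value 600 keV/µm is binned, not dropped.
* Spectrum/map additivity under track-list concatenation is exact and
  property-tested.
* All exclusions — over-etched pits, below-threshold responses, clipped
  LETs, out-of-grid or out-of-image tracks — are counted and reported;
  silent data loss is treated as a bug.
* Empty inputs (no pits, empty masks, zero activity) produce empty
  results, not errors, except where the result would be undefined (zero
  region area, zero denominator density).
* All randomness flows from one integer seed; rerunning a simulation
  with the same seed reproduces byte-identical output tables.

# Problem sizes

The shipped defaults are sized for interactive use and continuous
testing: the default phantom (1000 × 1000 px, ≈ 9 × 10⁴ decay events,
≈ 2.2 × 10⁴ registered tracks) simulates and analyses in a few seconds;
the spectroscopy round-trip checks use 10⁴ registered tracks; smaller
250 × 250 px phantoms back the per-module simulation tests. All
quantitative recovery checks state their tolerance in terms of the
propagated counting error of the quantity under test (3σ), so they scale
correctly if a user reruns them at larger sizes.

# Known limitations

* The default calibration is a synthetic stand-in; absolute LET and dose
  values from it are only as good as its resemblance to a real batch
  calibration. The analysis is exact once a measured curve is supplied.
* The cited angular-LET response refinement of the registered fraction is
  absorbed entirely into the $1/\eta(S)$ weight; no separate angular
  correction is applied.
* Dose is computed from fluence and LET in 2-D cells; no 3-D transport,
  no lineal-energy microdosimetry. RBE enters only as an optional scalar
  multiplier (default 1) at reporting time.
* The pit detector (`detectPits()`) is a deliberately simple
  threshold-plus-moments component for rendered or clean images; it does
  not split merged pits and is not a replacement for dedicated pit-fitting
  software.
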