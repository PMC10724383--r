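---
title: "Models and methods behind psoct2pm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psoct2pm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct2pm)
```

`psoct2pm` implements the computational side of an integrated
serial-sectioning imaging system that combines polarization-sensitive
optical coherence tomography (PSOCT) and two-photon autofluorescence
microscopy (2PM) for label-free human brain imaging. This vignette
explains the models the package implements, the assumptions behind them,
the tunable parameters and their defaults, what the synthetic phantom
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## The polarization model

PSOCT illuminates the sample with circular polarization (a quarter-wave
plate at 45 degrees ahead of the sample arm) and detects the
interference signal in two orthogonal channels. For a sample that acts
as a linear retarder with one-way retardance accumulating along depth,
the detected Jones vector at depth $z$ is

$$
E(z) \;=\; J_{\mathrm{sys}} \; Q \; J_s\!\big(2\delta(z),\theta\big) \; Q \; E_H ,
$$

where $E_H$ is the horizontal input state, $Q$ the quarter-wave plate at
45 degrees, $J_s$ the sample retarder traversed twice (round trip), and
$J_{\mathrm{sys}}$ a *lumped* unitary representing the system
birefringence of the telescopes, dichroic and scanning mirrors. The
package deliberately models the confound as a single constant operator
on the detected state: physically the confounding optics are traversed
twice, but the lumped form makes software compensation an exact inverse
(a single left-multiplication per voxel, `apply_compensation()`), and
every claim the package tests — dynamic ranges, equivariance,
compensation recovery — holds identically under it. The uncompensated
instrument is still badly biased, which is what the compensation tests
assert; the lumped model's apparent mirror retardance simply differs
numerically from the double-passed hardware's background reading.

From the compensated channels the canonical circular-input estimators
are

* reflectivity $10\log_{10}(|E_{co}|^2 + |E_{cross}|^2)$ (dB over the
  noise floor), independent of sample birefringence because the chain is
  unitary;
* retardance $\hat\delta = \arctan(|E_{cross}|/|E_{co}|)$ in degrees,
  range exactly $[0, 90]$;
* orientation $\hat\theta = \tfrac12\big(\arg E_{cross} - \arg
  E_{co}\big)$, wrapped to $(-90, 90]$, with the zero fixed by the
  mirror calibration (see below). The estimator is directly
  equivariant: rotating the sample axis by $\alpha$ shifts the estimate
  by $\alpha$ modulo 180 degrees.

The "co" channel is, by convention, the detector that receives the full
return from a mirror. Orientation is reported as undefined (NA) where
retardance is below a floor (default 5 degrees, configurable): the phase
of a near-zero cross channel carries no information.

**Retardance bookkeeping.** The package uses the double-pass convention
throughout: the reported retardance at depth $z$ accumulates over the
round-trip path, so its expected slope is $2\,(360/\lambda)\,\Delta n$
degrees per unit depth and the birefringence fit inverts the same factor
($\Delta n = \mathrm{slope}\cdot\lambda/720$ with the slope in
degrees/µm). Generator and fit share one convention, so round trips are
exact by construction; only $\Delta n$ values quoted under a single-pass
convention would differ by a factor of two.

## Mirror calibration of the compensation

The calibration mirrors the hardware procedure with a variable retarder:
(1) image a mirror and read its apparent retardance — a mirror has none,
so the reading exposes the system; (2) seed a compensator with the
opposite retardance; (3) refine (retardance, axis) by Nelder–Mead until
the mirror's cross-channel energy stops improving.

Minimizing mirror cross power alone is under-determined: any residual
retarder diagonal in the detection basis also nulls the cross channel
and only rotates the orientation zero. That gauge is exactly the
"arbitrary global offset fixed by the mirror calibration" that the
orientation convention allows, and the package fixes it explicitly: the
objective adds a phase-reference term pinning the compensated mirror
co-channel phase to the ideal mirror phase. With the gauge fixed, the
true system operator is the unique minimizer, and a planted
(70 degrees, 25 degrees) confound is recovered to well below 0.1 degrees
on noise-free scans.

## Optical-property fitting

Depth profiles of the total intensity follow a single-scattering model
with a Lorentzian confocal envelope:

$$
I(z) = \frac{A}{1 + \big((z - z_f)/z_R\big)^2}\; e^{-2\mu_s z} + C ,
$$

with the focus depth $z_f$ (default 50 µm below the cut surface, where
the focus is placed to stay clear of cutting damage) and
$z_R = b/2$ (confocal parameter $b = 150$ µm) taken from the instrument
configuration, and the fit restricted to the in-focus band 50–200 µm
below the surface. Two numerical choices matter:

* **The offset $C$ is a calibration constant, not a free parameter.**
  $C$ is the detector noise floor, about 95 dB below the surface signal
  here (default 0 on the linear scale). Left free, $C$ trades off
  against $\mu_s$ over the short in-focus band and roughly doubles the
  variance of shallow slopes; with it fixed, $\mu_s = 2\ \mathrm{mm^{-1}}$
  is recovered within ~3% from 1600 speckled A-lines.
* **Relative weighting.** The mean of $N$ speckled A-lines has standard
  deviation proportional to its own value ($I/\sqrt N$), so the fit uses
  $1/I^2$ weights; this is equivalent to fitting relative errors and
  keeps deep, dim samples informative.

Fits are performed on spatially binned profiles (default 20×20 A-lines
per bin in `fit_property_maps()`); recovery tests use 40×40-equivalent
averaging (1600 A-lines) because the slope contrast of
$\mu_s = 2\ \mathrm{mm^{-1}}$ over a 150 µm band is only
$e^{-0.6}$. Speckle is the dominant noise source; averaged intensity is
unbiased for the envelope, so no speckle-bias correction is applied.

The cumulative retardance profile is fitted by an intensity-weighted
straight line through the surface (zero retardance at zero depth), with
the slope clipped at zero. Because the estimator folds at 90 degrees,
the fit discards everything from the first approach to the wrap
(default bound 80 degrees) onward — folded values re-entering the fit
range would otherwise corrupt the slope.

## Geometry

* **Field curvature** is estimated from the top-surface reflection of a
  grid target: per-pixel argmax along depth with parabolic sub-pixel
  refinement, lateral smoothing, zero-mean convention. Flattening
  shifts whole A-lines and sets a `flattened` flag; re-flattening is
  refused because the operation is not idempotent.
* **Grid distortion** is estimated from the imaged dot grid: centroid
  detection, nearest-node lattice assignment, and a polynomial
  displacement model (degree 3, which represents a cubic radial
  distortion exactly). The lattice phase is anchored on the most
  central dots, where radial distortion vanishes — anchoring on a
  global modular offset would absorb part of the distortion into a
  spurious translation. Unwarping resamples with the local area
  Jacobian so image mass is preserved.
* **Shading** is corrected retrospectively: per-pixel median across at
  least 20 tiles, smoothed by a low-order polynomial surface (a kernel
  smoother would bias the gain at tile borders), normalized to mean 1.
  With fewer tiles the correction falls back to unity gain with a
  warning.
* **Stitching** measures pairwise offsets by energy-normalized
  cross-correlation of the nominal overlap strips and solves for global
  tile coordinates by least squares over the tile graph with one anchor
  tile; low-correlation edges are dropped. For 3D tiles, three interior
  depth-band means vote jointly — band averaging suppresses speckle
  while keeping independent evidence. Because PSOCT tiles carry
  independent speckle, the pipeline follows the acquisition logic:
  stitch the speckle-free 2PM channel and transfer the optimized
  coordinates to PSOCT through the pixel-size ratio.
* **Cross-modality registration** fixes the scale analytically as the
  pixel ratio (3 µm / 2 µm = 1.5) and finds the integer shift as the
  argmax of the normalized cross-correlation of vessel-enhanced images
  (absolute ratio contrast, which lights up vessels of either
  polarity). The shift convention is: 2PM coordinates = scaled PSOCT
  coordinates + shift.
* **Volume assembly** concatenates each slice's in-focus band (50–200
  µm below the flattened surface) at the physical cut pitch with no
  axial blending — stage precision is at the resolution scale — and
  warns with a gap estimate if the band is thinner than the cut.

## Lipofuscin morphometry

Granules are segmented from the long-wavelength channel by
ratio-of-Gaussian thresholding: divide the image by its own Gaussian
low-pass (sigma 50 px = 100 µm at the 2 µm grid), binarize the ratio at
the fixed lower bound 1.22, label 8-connected components, drop
components below 2 px. Huang's minimum-fuzziness threshold of the ratio
image is computed and reported as a diagnostic, but the fixed bound
governs the mask. The minimum size (2 px) suppresses single-pixel noise
and is configurable.

Sliding-window metrics use 100×100 px (200×200 µm) windows at 50 px
(100 µm) step, fully inside the image: with $P_1$ segmented pixels and
$N$ granules touching a window,

* area fraction (%) $= 100\,P_1/100^2$,
* number density $= N / (0.2\times0.2\ \mathrm{mm^2})$,
* mean radius $= 2\,\mathrm{\mu m}\cdot\sqrt{P_1 / (\pi N)}$
  (undefined where $N = 0$).

Granules are counted in every window they touch, pixels where they lie;
over non-overlapping windows the pixel masses add up exactly to the
total segmented area. Age trends are ordinary least squares of
per-sample metric means against age, per metric and tissue class.

## Cells and vessels

Cell bodies appear as dark spots in the short-wavelength channel. The
detector inverts the background-ratio-normalized image (making it
equivariant to global intensity scaling), applies scale-normalized
Laplacian-of-Gaussian filtering over soma radii 5–20 µm, takes 3×3
local maxima across scale with parabolic sub-pixel refinement, and
suppresses non-maxima within the detected radius. Dark vessels also
present blob-like cross-sections, so detections inside a (dilated)
vessel mask can be excluded. A *cell* is a dark spot with at least one
lipofuscin granule centroid within the pairing radius (default 15 µm);
granules on vessels are excluded from pairing since perivascular
autofluorescence is not somatic.

Count correspondence between two point sets uses greedy one-to-one
nearest matching within 10 µm (pairs sorted by distance — declared in
place of Hungarian assignment, which changes nothing at these
densities) and reports $100\cdot\mathrm{matched}/\mathrm{mean}(|A|,|B|)$,
a denominator symmetric in the two sets; two empty sets count as 100%,
one empty as 0%.

Vessels are segmented from attenuation-normalized volumes by
multi-scale Hessian vesselness per depth frame on the ratio-contrast
image (dark tubes by default, radii 10–80 µm for the PSOCT channel),
hysteresis thresholding, and a minimum-size filter on 26-connected 3D
components. The vesselness uses an absolute structure-contrast scale
(`c_param = 0.1` in ratio-contrast units) rather than a per-frame
adaptive one, so pure noise segments nothing.

## The phantom: what it emulates, and what it does not

The phantom provides ground truth for every estimator: lateral fields
of $\mu_s$, $\Delta n$, axis orientation and surface height with
gray/white regions (defaults $\mu_s$ = 4 and 10 mm⁻¹, $\Delta n$ =
5×10⁻⁵ and 4×10⁻⁴ — values in the range reported for human cortex and
white matter at 1310 nm); fully developed speckle as a per-voxel
circular complex Gaussian common to both channels; additive detector
noise at −95 dB; the lumped system retarder (default 70 degrees at 25
degrees, the background level the instrument class exhibits); radial
grid distortion; a parabolic field-curvature bowl; multiplicative
vignetting; and a fluorophore population of bright granules, dark
somata and vessel tubes with low-frequency background.

Realism decisions fixed once in the generator: granule radii are
lognormal with median 2.5 µm, clipped to 2–8 µm (sub-resolution
granules cannot be segmentation targets at a 2 µm grid); scattered
granules keep at least 12 µm center separation (distinct lysosomal
bodies — coincident granules would merge in any connected-component
count); somata keep 1.5 radii apart and every planted soma carries at
least one perinuclear granule in a 0.5–5 µm ring, because the
lipofuscin-filled cell is the countable unit; the same vessel
centerlines are stamped into the PSOCT amplitude field so the two
modalities share the structure registration relies on.

What the phantom does *not* emulate — and what passing tests therefore
do not show about real data: no diattenuation or depth-dependent axis
rotation (only cumulative retardance from a single in-plane axis, as in
the instrument's own processing); no sensitivity roll-off (measured
negligible over the first millimetre on the hardware); no cutting
chatter or tissue deformation (cut loss is represented only by the
in-focus band convention); speckle and detector noise statistics are
generic, not calibrated to the instrument; the 2PM point-spread
function is not modelled (structures are rasterized at the grid, near
Nyquist for the 2.4 µm optical resolution); and real tissue texture,
boundary brightness artifacts and amyloid-like confounders of the
granule channel are absent.

## Problem sizes and determinism

All simulations are seeded and bit-reproducible; `run_pipeline()` writes
the resolved configuration and its hash next to the outputs, and a rerun
at the same seed produces byte-identical metric tables. The shipped
tests and the demo run at desk scale, chosen so each check exercises the
full algorithmic path: 80–150 px tiles (0.3–0.6 mm fields), 100 depth
pixels (300 µm at 3 µm sampling), 2×2 tile grids, 1600–3200 A-lines per
scattering fit, and phantoms of 0.16–0.64 mm² with 50–300 planted
objects. The instrument-scale workflow (hundreds of tiles, 10⁴–10⁵
granules per slice) runs through exactly the same functions; only array
sizes change.

## Known limitations

* The compensation model is a single constant unitary; slowly varying
  (field-position-dependent) system birefringence would require
  per-region calibration, which the API supports only by calibrating
  tile by tile.
* Only cumulative retardance is computed — no depth-resolved local
  birefringence tomography.
* The stitcher assumes nominal offsets within the search margin
  (default ±10 px) of the truth and a connected tile graph; it does not
  attempt global rotation or nonrigid alignment.
* `regress_vs_age()` fits independent per-metric lines; it does not
  model within-sample correlation across slices.
* Vessel analysis stops at segmentation and overlays; graph-theoretic
  morphometry (tortuosity, branching) is out of scope.
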