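---
title: "Phase-contrast vascular tomography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-contrast vascular tomography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pctomo)
```

## What the package models

`pctomo` is a testbed for contrast-agent-free imaging of brain
microvasculature by synchrotron inline (propagation-based) phase-contrast
tomography. In the laboratory procedure it emulates, a perfused, fixed and
ethanol-dehydrated brain is dried so that air fills the intact vascular
lumina; the refractive-index step at each air--tissue interface then
produces strong propagation fringes on a detector placed behind the sample,
and the resulting edge-enhanced projections are corrected, reconstructed,
segmented, and finally summarized by a branching morphometry statistic: the
radius ratio `K` at each bifurcation, defined as the mean post-branching
(daughter) radius divided by the pre-branching (parent) radius. Active
angiogenesis adds newborn small branches and therefore lowers `K` among
small vessels, which is what the statistic is designed to detect.

No public raw data exist for this kind of experiment, so the package is
built around a synthetic-data module that is itself first-class, tested
code: every downstream stage is exercised against phantoms whose ground
truth is known exactly.

## The synthetic acquisition model

**Vessel trees.** `generate_vessel_tree()` grows a binary tree of straight
cylindrical segments. At each bifurcation the two daughter radii average to
`ratio x parent`, with the ratio drawn from
`Normal(radius_ratio_mean, radius_ratio_sd)` clipped to (0.3, 0.95) and
split `(1 +/- asymmetry)` between the daughters. The default
`radius_ratio_mean = 0.794` is the symmetric Murray's-law value
`2^(-1/3)`, the classical expectation for healthy arterial bifurcations;
angiogenic rebuilding is emulated by lowering it (we use 0.68 in the cohort
studies, against 0.80 for the control arm). Segment length is
`length_per_radius x radius` (default 6) and growth stops below
`min_radius` or at `max_depth`.

**Optical constants.** The phantom grid stores a linear attenuation map
`mu` and a refractive-decrement map `delta`. Defaults are
`mu = 1e-4 /um` and `delta = 1e-6` for tissue at 16 keV, zero for
air-filled lumina; both are configurable, and the recovery studies below
use `mu = 1e-3 /um`, representative of dense dehydrated tissue. These
values reproduce the defining property of hard-X-ray phase contrast: the
phase cross-section is roughly three orders of magnitude above absorption.

**Propagation.** Projections are computed by parallel-ray line integration
(rotation about the z axis, bilinear sampling at half-voxel steps), and
free-space propagation over a distance `z` is modelled in the
transport-of-intensity (weak-defocus) regime:

`I_z = I_0 + z * Laplacian_perp(I_0 * integral(delta))`, with
`I_0 = exp(-integral(mu))`; the sign follows from the phase *lag*
`phi = -k integral(delta)` of a refractive-index decrement, so air-filled
lumina brighten while dense structures darken with a bright rim.

This reproduces the experimentally relevant behaviour — edge-fringe
amplitude growing with distance — and is analytically checkable: at `z = 0`
the corrected projections must equal `exp(-integral(mu))`, which the test
suite verifies to 1e-6 against an independent R-level ray-marching oracle.
Full Fresnel diffraction, partial coherence and polychromaticity are out of
scope; the weak-defocus model is adequate for the 10--110 cm, 16 keV regime
the package targets, and its validity boundary (first Fresnel fringe width
`sqrt(lambda z)` small against the imaged structures) is stated on the
simulator's help page.

**Detector.** Frames are multiplied by a vignetted flat field
(`photons_per_pixel`, `vignette_strength`), offset by a dark level, and
optionally degraded by Poisson photon noise plus Gaussian read noise. Every
frame uses an RNG substream derived from one master seed and the frame
index, so simulations are bit-reproducible. Matching dark and flat frames
are produced by the same model, and flat-dark positivity is an enforced
invariant.

## Correction, visibility, retrieval, reconstruction

Flat/dark correction is the standard normalization
`I_p = (I - I_d) / (I_f - I_d)`; pixels with `flat - dark <= 0` are
repaired from their valid 8-neighbours (median), and a frame with more than
1% such pixels is rejected. Fringe visibility over a region is
`V = (I_max - I_min) / (I_max + I_min)`; `distance_sweep()` tracks it
across propagation distances and reports the plateau onset — the smallest
distance reaching 95% of the sweep maximum — as the operational optimum,
reproducing the rise-then-plateau behaviour used to pick 60--80 cm on real
beamlines. A robust percentile variant (0.5/99.5%) exists for noisy data
and is off by default.

Single-distance phase retrieval (`paganin_retrieve()`) implements the
homogeneous-object low-pass filter
`T = -(1/mu) ln(IFFT[FFT(I_p) / (1 + lambda z delta / (4 pi beta) |k|^2)])`
with `mu = 4 pi beta / lambda` and default `delta/beta = 1000`. It is a
side branch, matching the experimental practice of reconstructing directly
from corrected images because retrieval flattens exactly the vascular
contrast of interest.

Reconstruction is classical parallel-beam filtered back projection:
`-log` conversion with an epsilon floor (1e-6), frequency-domain ramp
filtering with selectable apodization (`ramlak`, `shepp-logan`, `hann`),
power-of-two zero padding, linear-interpolation backprojection scaled by
`pi / n_angles`, rotation centre fixed at the detector centre. The test
suite pins its accuracy on an analytic disk phantom (interior mean within
3%, RMSE under 5%) and verifies linearity, slice independence,
angle-ordering invariance and convergence with angle count.

## Segmentation by ridge detection

Air-filled vessels reconstruct dark, so the volume is polarity-normalized
(inverted) and rescaled to the unit interval before enhancement; every
later threshold is derived from that normalized data, which makes the
final mask invariant under affine intensity maps of the input. Tubular ridge strength is computed from the
eigenvalues of the scale-normalized Hessian (Frangi-type vesselness,
`alpha = beta = 0.5`), taking the maximum over detection scales. Two
calibrations tie the abstract filter to vessel geometry, both fixed on the
canonical solid-cylinder model and then left alone:

* the scale parameter means *nominal vessel radius*: the internal Gaussian
  width is `sigma = scale / sqrt(2)`, which places the peak response of a
  radius-r tube at scale r (verified by a scale-sweep test);
* the mask cut sits at 5% of the typical vessel ridge amplitude
  (`boundary_frac`), because the matched response of a solid tube decays to
  a few percent of its axis value right at the tube wall — cutting at the
  conventional half-maximum would halve the recovered cross-section.

Candidate ridge points are strict local maxima of strength within the 3x3
plane transverse to the local ridge axis, above a strength quantile
(default 0.98 — the candidates are meant to be few and strong). At each
candidate (capped at `max_fits = 300`, evenly subsampled; the amplitude
mixture only needs a sample) the two transverse strength profiles are fit
with an asymmetric Gaussian
`b + A exp(-(x-c)^2 / (2 sigma_{L|R}^2))` by Levenberg--Marquardt with a
Nelder--Mead polish (the kink at `x = c` can trap purely gradient-based
steps); amplitudes are clamped to twice the profile's dynamic range so
pathological fits cannot drag the statistics. A two-component Gaussian
mixture on the amplitudes separates vessel from spurious ridges; the
equal-posterior point between the components is the rejection threshold,
with Otsu's method as the degenerate-case fallback. The final mask is the
strength grid thresholded at the *lower* of the rejection threshold and the
5% boundary cut, followed by removal of 26-connected components below
`min_component_voxels` (default 27, i.e. a 3-voxel cube). A final
plausibility guard rejects masks filling more than `max_mask_fraction`
(default 10%) of the volume: vasculature occupies a few percent of tissue
at most, and a flooded mask means the amplitude clustering found no real
vessel/background separation — the structureless-noise case — so an empty
mask with a warning is more useful than a percolated one.

## Morphometry

Masks are thinned to curve skeletons by sequential deletion of simple
(topology-preserving) border voxels in six directional subiterations.
Beyond the standard endpoint rule, voxels whose only two neighbours are
mutually adjacent ("thick endpoints") are protected — without this, a
whole branch of a 2-voxel-wide structure can retract within a single sweep.
Local radius is the Euclidean distance transform minus half a voxel (the
distance to the nearest background voxel centre overshoots the physical
surface by about half a voxel; removing it empirically debiases the radius
ratio of small vessels).

The skeleton becomes a graph: junction voxels (three or more skeleton
neighbours) are clustered into junction nodes; removing them splits the
skeleton into branches; terminal branches shorter than 5 voxels are pruned
(thinning turns surface bumps into spurs that would masquerade as
junctions); and short junction--junction bridges (under 1.5 local radii)
are contracted, because thinning splits a Y-junction into two nearby
T-nodes. Branch radius is the median of per-voxel radii outside a junction
exclusion zone of twice the junction's local radius, which avoids the
junction-bulge bias.

At each junction the parent is the incident branch with the largest radius
(flow direction is unknowable from a static volume; largest-radius-is-parent
is the physiologically standard convention), ties broken by lowest branch id
and flagged. `K = mean(daughter radii) / parent radius`. Records with
pre-branching radius at or above 20 um are discarded and the rest binned at
7.4 um (half-open bins `[0, 7.4)` and `[7.4, 20)`; 7.4 um is twice the
3.7 um effective pixel of the reference system, i.e. the smallest reliably
resolved vessel diameter). Group comparison reduces each animal to its mean
K per bin and applies a two-sample equal-variance Student's t-test — the
animal, not the branch point, is the statistical unit, which is the
conservative reading of a design where several thousand branch points per
animal would otherwise inflate significance.

## Study conditions used by the tests and the acceptance script

Three standing configurations, chosen once:

* **Oracle checks** (projection physics, FBP): 32^3 phantoms at 4 um voxels
  and a 256^2 analytic disk.
* **Segmentation recovery**: a three-level binary tree (six junctions at
  the chosen growth parameters, radii 4--8 um, all >= 2 voxels) on a 128^3
  grid at 2 um voxels, 180 angles, noise off.
* **Radius-ratio studies**: fine-voxel phantoms (112^3 at 0.9 um, 120
  angles) whose junction radii fall below 7.4 um, so the statistic is
  exercised exactly in the microvascular band; ratio recovery runs noise
  free, and the two 7-animal cohorts (K 0.80 vs 0.68) run with Poisson
  noise at 5e5 photons/pixel, a flux representative of a synchrotron
  bending-magnet beamline with 200 ms exposures.

The quantitative morphometry chain reconstructs at contact (`distance 0`).
This is a deliberate regime choice, not a simplification of convenience:
with physically realistic `delta`, the fringe term at decimetre distances
is one to two orders of magnitude stronger than the absorption contrast,
and for vessels only a few pixels wide the reconstructed lumen becomes a
fringe-dominated ring/blob whose width reflects the Fresnel fringe, not the
anatomy. Such volumes are excellent for *detecting* subpixel vessels (and
the visibility module quantifies exactly that benefit on projections), but
radii measured on them are biased by the fringe width. Since the radius
ratio is the package's quantitative deliverable, the CT path for
morphometry uses the absorption-defined lumen; the edge-enhancement study
stays on the projection side, where it belongs.

## What passing tests do and do not show

The phantoms are straight-segment binary trees in uniform tissue with an
ideal parallel beam and a PSF-free detector. Passing the recovery studies
shows the chain is internally consistent and unbiased under those
conditions; it does not certify performance on real brains, where
tortuosity, touching vessels, density heterogeneity, scintillator blur and
ring artifacts all degrade segmentation in ways this generator deliberately
does not emulate. The junction-exactness check uses one defined phantom
geometry; junction recovery on arbitrary geometries is exercised
statistically (within one or two of truth) rather than exactly.

## Numerical choices and degenerate inputs

Epsilon floors: 1e-6 before the reconstruction `-log`; 1e-8 before the
retrieval logarithm. Constant volumes enhance to all-zero strength with a
warning; empty masks skeletonize to empty skeletons and empty graphs;
sub-voxel branches always rasterize their axis voxels so thin trees remain
connected; a propagation distance whose Fresnel fringe would exceed half
the detector is rejected. All thresholds that could be data-degenerate
(mixture clustering, junction contraction, spur pruning) have deterministic
fallbacks described above. Runtime scaling chosen for a single CPU:
the complete test suite runs in roughly a quarter hour, dominated by the
14-phantom cohort study.
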