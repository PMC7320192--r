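---
title: "Missing-wedge restoration: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-wedge restoration: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomowedge)
```

## The restoration model

A single-axis tilt series measures the object's 3D Fourier transform on a
union of central planes through the tilt (Y) axis — the bow-tie-shaped
*data zone*. The complement, the *missing wedge*, is never measured: a
±15° range leaves (90−15)/90 ≈ 83.3% of Fourier space empty, ±45° leaves
50%. A reconstruction computed from such data is correct on the zone and
zero on the wedge, which in real space appears as elongation along the beam
(z) axis and anisotropic resolution.

`tomowedge` treats the wedge voxels as free variables and refines them by
alternating two constraint projections, in the manner of Gerchberg–Papoulis
band-limited extrapolation (and, in spirit, of solvent flattening and phase
extension in crystallography):

1. **Real space** (`applyRealConstraints`): the density is zero outside a
   binary support mask, imaginary parts are discarded, and negative real
   values inside the mask are clamped to zero. This is applied identically
   in every cycle; the first cycle simply has no imaginary part to remove.
2. **Fourier space** (`replaceDataZone`): on the data zone, the transform
   is overwritten with the transform of the *initial* map, `F0`, computed
   once and held fixed. The measured data are never altered; only the
   wedge evolves.

One iteration is constraints → FFT → zone lock → inverse FFT. A *round*
(`runRound`) is a fixed number of iterations (default 1,000) under one
mask; the driver (`restoreMissingWedge`) runs several rounds (default 5),
regenerating the mask after each round from that round's output, which is
less elongated than the initial map and therefore yields a more accurate
support. Later rounds continue from the previous round's map; the zone is
always locked to the original `F0`. The round output is taken after a
final real-space constraint application, so the returned map satisfies the
real-space constraints *exactly*, and matches `F0` on the zone up to the
perturbation of that single application. (The alternative convention —
output directly after the Fourier step — would satisfy the data exactly
and the support only approximately; we prefer exact support and
non-negativity because those are the physical statements about the
particle.)

Both constraint sets are convex (a cone and an affine subspace), so the
alternation converges; convergence is slow when the wedge is large, which
is why the method uses thousands of cycles. There is no early stopping by
default (`runRound` reports a per-iteration relative-change trace instead);
an all-zero initial map is an error, not a silent fixed point.

## Parameters

* `tiltMax` (degrees): half tilt range of the acquisition; defines the
  data zone. Must match the data — locking voxels that were never measured
  corrupts the result.
* `mwDa` (Dalton): particle mass, converted to a target support volume via
  `vPerDa` = 1.21 Å³/Da (protein partial specific volume 0.73 cm³/g;
  configurable). For synthetic phantoms with no physical mass the
  benchmark driver derives an *apparent* mass from the support volume
  above 10% of the map maximum.
* `maskFilterRes` (Å, default 40, sensible range 40–80): low-pass applied
  to the source map before thresholding, so the mask is featureless and
  follows only the overall particle envelope.
* `volumeFactor` (default 3, sensible range ~1.5–4): mask volume as a
  multiple of the molecular-weight-equivalent volume. The restoration is
  not very sensitive to it in the noise-free regime, but two regimes
  matter: a mask that *cuts particle density* makes the constraint sets
  inconsistent (the locked data and the support admit no common map), and
  the data-zone fidelity of the converged output then plateaus at the
  level of the cut mass; under heavy noise a *smaller* mask suppresses
  more noise. The mask threshold is found as an order statistic of the
  filtered densities (the k-th largest value for a k-voxel target), which
  hits the target volume to within one voxel; ties at the cutoff are
  included, so exact symmetries of the source map are preserved up to the
  tie set.
* `nIterPerRound` (default 1,000) and `nRounds` (default 5): the fixed
  iteration budget. Scaled-down runs (200 iterations) show the qualitative
  behavior but are under-converged: marginal FSC shells keep moving
  between 200 and 1,000 cycles.
* `maskOverride`: an externally supplied mask, e.g. a *precise* mask built
  from a known reference object (`makeMask(object, params)`); used by the
  wider-tilt-range benchmark experiments.

## Grid and Fourier conventions

Maps are `[x, y, z]` arrays with x the fastest (MRC column) axis, the tilt
axis is Y, and the box center — also the rotation fixed point and the DC
position of the centered Fourier layout — is the voxel at 0-based index
n/2 (boxes are even). On disk, maps are CCP4/MRC 2014 mode 2 (32-bit
little-endian float) with the voxel size in the cell fields and origin 0;
tilt series are multi-section MRC stacks with IMOD-style `.tlt` angle
files (one angle in degrees per section).

Projection rotates the map by minus the tilt angle about +Y and integrates
along lab z, with bilinear interpolation in the x–z plane (rotation about Y
leaves y untouched). Backprojection is direct Fourier inversion: each
frame's centered 2D transform is inserted as a central plane rotated by
the tilt angle about k_y, with bilinear gridding in (k_x, k_z) and
per-voxel weight accumulation. The same rotation convention is used by the
data zone, so projection, backprojection, and zone membership are mutually
consistent — the test suite checks this through impulse geometry and
through the information ceiling below.

Two numerical choices in the backprojection matter:

* **Weight clamp.** Accumulated gridding weights below 0.5 are clamped in
  the normalization. A voxel grazed only by the bilinear tail of a distant
  slice otherwise gets divided by its own tiny weight, amplifying leakage
  to full slice amplitude — near DC, where amplitudes are largest, this
  would fill the wedge with artifacts.
* **Zone masking.** Voxels outside the data zone of the used tilt range
  are set to zero, so the filled region *is* the data zone by
  construction, as the method assumes. Consequence: the correlation
  between object and low-tilt reconstruction is capped at the square root
  of the in-zone fraction of the object's AC Fourier energy (~0.57 at
  ±30° for an isotropic spectrum), and the reconstruction should sit just
  below that ceiling, which is what the tests assert.

The data zone itself contains voxel (k_x, k_y, k_z) iff the angle of
(|k_x|, |k_z|) from the k_x axis is at most `tiltMax` plus a half-slice
angular thickness δ = atan(0.5/(n/2)) — half a voxel at the box edge —
or the voxel lies on the tilt-axis line k_x = k_z = 0 (measured by every
projection). Membership is independent of k_y and symmetric under
k → −k, so locking preserves Hermitian symmetry and real maps stay real.
Missing-fraction counts are reported within the in-plane Nyquist disc
(√(k_x²+k_z²) ≤ n/2), where the continuum angular fraction is exact; on
the full square grid the bow-tie's area fraction is tan(θ)/2, not θ/90,
and the counts would not be comparable to the analytic values.

The mask low-pass and all other filters share one kernel family: a radial
Gaussian with gain 0.5 at the cutoff frequency 1/resolution (a raised-
cosine edge is available as an option). DC is always preserved; requests
below Nyquist are errors. FSC uses integer-radius shells (`round(|k|)`,
no smoothing) from DC to Nyquist; the resolution is the linearly
interpolated FSC = 0.5 crossing, clamped at Nyquist and flagged
`at-Nyquist` when the curve never falls below the threshold (sub-Nyquist
"resolutions" are not reported), or `no-signal` when the curve starts
below it.

## The synthetic phantom generator

`makeSyntheticPhantom` builds a compact globular particle from Gaussian
blobs: a central core plus seeded random blobs placed isotropically around
the center (widths 5–10% of the box half-width, support confined to 0.8×
the half-width), with optional exact n-fold symmetrization about Z and a
deterministic map for a fixed seed. With `nDetail > 0`, sharp sub-voxel
blobs (σ ≈ 0.45–0.75 voxel) are layered on the body to emulate the
atomic-scale detail a rasterized crystal structure has; this matters for
resolution-based comparisons, because a smooth phantom has no genuine
signal in the high-frequency shells and the FSC = 0.5 crossing there is
decided by numerical noise. The default (`nDetail = 0`) is the smooth
body, appropriate for geometry and interpolation tests.

What the phantoms do **not** emulate: electron-optical contrast transfer
(no CTF), stain or solvent background, tilt-geometry errors and alignment
noise, dose-dependent damage, and non-Gaussian noise. Passing the
simulation suite therefore demonstrates the restoration mathematics and
the pipeline's internal consistency, not performance on real micrographs —
real data additionally require CTF correction and tilt-series alignment
upstream of this package.

Noise is injected per frame as i.i.d. Gaussian with standard deviation
(signal s.d. of the frame)/SNR, so SNR 0.3 means noise s.d. 3.33× the
particle's. The printed measurement formula SNR = (I_s − I_b)/N_b (means
inside/outside the particle over the background s.d.) is a *different*
statistic and is implemented separately (`estimateSNR`); the two do not
coincide on the same frame, and the generation recipe is the s.d. ratio.

## Study conditions used by the shipped experiments

The bundled tests and the acceptance script run scaled-down conditions
chosen once: 64³ boxes at 1 Å/voxel, 1.5° tilt steps, 200-iteration
rounds for pipeline smoke tests, and full 1,000-iteration rounds for the
improvement-property runs (where under-convergence at 200 cycles leaves
marginal shells unsettled). Improvement is assessed on wedge-zeroed
objects as initial maps — the controlled artifact model, which isolates
the restoration from backprojection gridding error — with precise
object-derived masks generous enough to cover >99% of the object's mass,
mirroring the mask recipe of the wider-tilt-range experiments. Shape
(elongation) comparisons are made on maps low-pass filtered to 8 Å, the
same display filtering under which such maps are normally compared.
Full-scale runs (256³, 1,000 iterations × 5 rounds) use the identical
code path through `runBench()` and are hours of CPU per round.

## Known limitations

* Trilinear/bilinear interpolation throughout; no Kaiser–Bessel gridding.
  Adequate at the scales above, and the conventions are cross-checked by
  the adjoint and impulse tests, but gridding error grows toward Nyquist.
* The FSC = 0.5 resolution of an empty-wedge map is a knife-edge statistic:
  per shell it equals ~√(in-zone fraction) ≈ 0.6 at ±30° even where the
  map carries no real signal, so "resolution" can read near-Nyquist for a
  heavily degraded map. CCC and elongation are the more stable companions,
  and the suite asserts improvement on all three only under conditions
  where each is meaningful.
* Masks are binary (the soft boundary comes from the heavily filtered
  source map's smooth isosurface, not from apodizing the mask); an
  optional cosine-edge apodization could be added but the constraint
  equation is stated, and implemented, as a hard region.
* No CTF, no tilt-angle refinement, no dual-axis geometry, no GPU path,
  no sub-tomogram averaging.
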