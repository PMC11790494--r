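---
title: "Quantifying DNA-nanoraft-driven GUV remodelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-nanoraft-driven GUV remodelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the analyses

Giant unilamellar vesicles (GUVs, 10-40 um diameter) decorated with
membrane-anchored DNA origami nanorafts are a synthetic-cell platform in which
nanoscale raft reconfiguration (near-square, ~70.8 x 55 nm, aspect ratio 1.3,
versus elongated, ~190 x 20 nm, aspect ratio 9.5) is coupled to micron-scale
membrane remodelling and, with the help of biogenic pores, to the formation of
sealable synthetic membrane channels for large cargo. Quantifying such
experiments requires four largely independent analyses, all implemented here:

1. **Shape tracing**: automated tracing of the membrane ring in equatorial
   confocal slices, summarised by the normalized local-curvature statistic
   SD_k and a binary deformed/undeformed classification.
2. **FCS surface density**: fitting the one-component 2D diffusion model to
   fluorescence correlation spectroscopy curves, calibrating the detection
   waist, and converting particle numbers to raft surface density and
   coverage.
3. **Kinetics and flux**: exponential raft-binding fits, the relative import
   level statistic for cargo influx, FRAP-based channel gating, and
   molecular-weight cut-off summaries.
4. **Raft ordering**: a hard-rectangle Monte Carlo surrogate for the
   disorder-to-local-order transition of rafts on the membrane.

No experimental images are distributed or required: a synthetic-microscopy
module generates every input with known ground truth, which is what the test
suite and the acceptance checks run against.

# Synthetic data generator

## What it emulates

A `guv_contour` is a star-shaped closed curve $r(\theta) = R\,(1 + \sum_n
a_n\cos(n\theta + \phi_n))$ standing in for an equatorial vesicle outline;
low-order modes ($n = 2\ldots4$) emulate the gentle lobed deformations seen
when elongated rafts crowd the membrane. `render_guv_slice()` converts a
contour into a confocal-style frame: a membrane ridge with Gaussian
cross-section of the distance to the contour (width `membrane_sigma`,
default 0.2 um, the scale of confocal blur of a thin ring), flat
interior/exterior soluble-dye levels assigned by a point-in-contour test, a
constant background, then Poisson shot noise followed by additive Gaussian
read noise. The default frame is 512 x 512 px at 0.1 um/px, matching typical
confocal acquisition of 10-40 um vesicles.

Signed distances to the contour are computed from a dense polyline (0.1
degree sampling, i.e. ~0.02 um vertex spacing for a 10 um vesicle), far below
pixel scale, so the rendered geometry is exact for all practical purposes.

Time-dependent generators build on this: `simulate_influx_stack()` evolves
the interior dye level as first-order equilibration $I_{in}(t) =
I_{out}(1 - e^{-a(t - t_0)})$ after an onset $t_0$, with optional
instantaneous multiplicative bleach events (FRAP emulation);
`simulate_remodeling_stack()` couples a linearly decaying mode-2 amplitude to
such a permeability scenario, reproducing the recovery-then-influx structure
of a channel-formation experiment. `generate_fcs_curve()` and
`generate_binding_series()` evaluate the corresponding closed-form models
exactly plus optional Gaussian noise. Every generator is bit-reproducible for
a fixed seed.

## What it does not emulate

Single vesicles only (no crowded fields), no 3D z-stacks or
point-spread-function anisotropy, no photobleaching drift, no membrane
fluctuation spectrum beyond the imposed low-order modes, and confocal noise
is a generic Poisson-Gaussian pair (`poisson_gain = 1` photon per intensity
unit, `gaussian_sd = 2`; chosen as typical for photon-counting confocal
detection, not fitted to any instrument). Tests passing on these synthetic
data therefore validate the *algorithms* -- geometry, estimators, statistics
-- not robustness to every artefact of real microscopy.

# Shape tracing

## Procedure

Starting from a manually supplied (or Otsu-centroid) vesicle centre
$\mathbf{x}_0$ and a seed pixel on the membrane, each step:

1. computes an adaptive intensity threshold: the mean of a square region
   centred on $\mathbf{x}_0$ extending $d = |\mathbf{x}_i - \mathbf{x}_0| +
   20$ px from it in each direction. Because $|\mathbf{x}_i -
   \mathbf{x}_0|$ is the vesicle radius at the seed, the region covers the
   whole vesicle (interior, ring, and a 20 px margin), so its mean always
   lies strictly between background and ring peak and scales with vesicle
   size. (A region of *side* $d$ would sit entirely inside the vesicle, where
   its mean equals the interior level and the selection rule degenerates --
   on clean synthetic data every ROI pixel passes and tracing precision
   collapses; we verified this directly.)
2. collects the above-threshold pixels of the ROI around the current seed.
   The fit support is the disc inscribed in the `roi_size` square (default
   21 px): a rotation-invariant window cannot clip the membrane band
   asymmetrically at its corners, which otherwise biases the fit by several
   pixels at diagonal polar angles.
3. rotates those pixels into a local frame aligned with the seed's polar
   angle, so the membrane is locally horizontal and $y(x) = a + bx + cx^2$ is
   well-posed at every angle, and fits the parabola weighted by each pixel's
   intensity excess above the threshold. Weighting concentrates the fit on
   the ridge centre; it reduces the per-point error from ~0.5 px to ~0.1 px
   on noiseless data (`weight_fit = FALSE` restores the plain coordinate
   fit).
4. records both the sub-pixel parabola vertex and the nearest above-threshold
   pixel (ties broken by higher intensity, then lower row, then lower
   column), and obtains the next seed by rotating the membrane point about
   $\mathbf{x}_0$ by `step_deg` (default 3 degrees) *on the exact angular
   grid* $\alpha_0 + i\,\Delta$. Naive iterated rotation of the refined point
   lets sub-pixel tangential noise accumulate into angular drift -- in the
   worst case the trace stalls and never closes -- whereas grid stepping
   guarantees exactly $360/\Delta$ uniformly spaced samples.
   `rotate_refined = FALSE` switches the stepping radius to the unrefined
   seed (a pure rotation of the starting point); the default takes the radius
   from the refined point so the trace follows deformed contours.

A step with an empty thresholded ROI aborts immediately with the step angle
in the error: a missing point would silently break the fixed
$360/\Delta$-point contract that all downstream statistics rely on, and
interpolating across gaps would bias SD_k downward.

## Curvature statistic

The reference circle is the closed-form algebraic (Kasa) least-squares fit --
deterministic, non-iterative and exact on exact circles. Normalized local
curvatures are $k_i = R_0 / R_i$ with $R_i$ the distance of point $i$ from
the fitted centre, and SD_k is their *population* (divide-by-n) standard
deviation; with 120 points the $n$ versus $n-1$ distinction is negligible.
A vesicle is deformed when SD_k strictly exceeds the threshold, default
0.026, the mean SD_k of a bare-vesicle reference population;
`calibrate_baseline()` recomputes it from any user-supplied bare set.

By default curvature uses the **sub-pixel vertices** rather than the snapped
pixels. Pixel snapping imposes a quantisation floor of ~0.29 px on the radial
error, i.e. a spurious SD_k floor of $0.29/R$ that reaches 0.01 for a 30 px
vesicle -- large compared to the 0.026 classification threshold. The snapped
pixels remain available (`points = "pixel"`, `use = "pixel"`) for exact
compatibility with pixel-based conventions.

Verified accuracy at the defaults (noiseless data): maximum radial error
$\le 0.1$ px for circles of radius 30-200 px (SD_k $\le 0.0007$), and SD_k
within $\pm 2\%$ of the analytic dense-grid value for single-mode contours of
amplitude 0.02-0.15.

## Ambiguities resolved

- The stepping rule can be read as rotating either the refined point or the
  unrefined seed; both are implemented (`rotate_refined`), defaulting to the
  refined point, which is what lets the trace follow deformed contours.
- The threshold region's height is not independently specified; a square is
  used.
- For time-lapse analysis the reference circle is refitted per frame, so
  slow drift of the vesicle does not masquerade as deformation.

# FCS fitting and surface density

The one-component 2D diffusion autocorrelation model
$$G(\tau) = \frac{1}{N}\,\frac{1}{1 + \tau/\tau_D}$$
is fitted by Levenberg-Marquardt on $(\log N, \log \tau_D)$ -- the
log-parameterisation keeps both parameters positive without constrained
optimisation -- with uniform weights by default (per-point weights can be
supplied). Starting values come from the curve itself ($N \approx 1/G$ at the
smallest lag, $\tau_D$ at the half-amplitude lag), and covariance is mapped
back to $(N, \tau_D)$ by the delta method. Fitting requires at least 8 points
spanning two decades of lag; constant curves are rejected.

Calibration inverts $\tau_D = r_0^2/(4D)$ to $r_0 = \sqrt{4 D \tau_D}$ using
a reference dye of known diffusion coefficient (e.g. 414 um^2/s, a standard
free-dye value in water at 25 C; if the instrument runs warmer, supply a
temperature-corrected $D$ -- no internal viscosity model is applied). The
raft surface density is $\sigma = N/(\pi r_0^2)$ and the coverage
$\varphi = \sigma L W$ with the raft footprint defaulting to the near-square
dimensions $L = 70$, $W = 55$ nm. Waist uncertainty is the fit-propagated
standard error of $\tau_D$ only; repeat-to-repeat calibration spread is the
user's to aggregate. Triplet/blinking corrections and multi-component models
are deliberately out of scope: the analysis targets the stated one-component
2D model, and the fitting surface is an obvious extension point.

# Kinetics and flux

- **Binding**: $I(t) = I_{max}(1 - e^{-at})$ fitted by Levenberg-Marquardt on
  log-parameters; initialisation uses $\max I$ and a log-linearised early
  slope. On images, `membrane_intensity()` integrates pixels above the mean
  of a centred ROI, the same adaptive rule as the tracer threshold.
- **Relative import level**: $(\langle I_{out}\rangle - \langle
  I_{in}\rangle)/\langle I_{out}\rangle$ from a ~30 x 30 px interior ROI and
  two ~50 x 50 px exterior ROIs. The two exterior ROIs are combined as the
  mean of their means (with equal ROI sizes this equals the pooled-pixel
  mean; a `combine` flag exposes the choice). Default exterior placement is
  the two frame corners farthest from the vesicle centre; positions can be
  overridden, and supplying the vesicle contour turns on an overlap check
  that rejects exterior ROIs touching the vesicle.
- **FRAP**: recovery fraction $(I_{end} - I_{post})/(I_{pre} - I_{post})$ at
  a horizon (default 40 min) after the bleach, with `recovered` defined as
  fraction > 0.2. The 0.2/40-min pair is an operational convention for
  turning the qualitative recovery/no-recovery readout into a boolean; both
  are parameters. A bleach depth below 10% of the pre-bleach level is
  rejected as "no detectable bleach event".
- **Cut-off summary**: per-probe mean +/- s.e.m. (with $n$) of import levels
  across a molecular-weight ladder, plus the bracketing weight pair where the
  mean first reaches 0.5 -- the partial-permeability midpoint that locates
  the channel's size cut-off between two probe weights.
- **FRET proximity ratio**: $I_A/(I_D + I_A)$ from trapezoidal integration
  over fixed donor (560-580 nm) and acceptor (660-680 nm) windows. Only
  orderings between states are asserted (elongated > square states); the
  Foerster radius used by the synthetic spectra generator (default 5.4 nm) is
  a configuration parameter, and no absolute distance is ever inferred.

The pipeline driver (`run_pipeline()`) aligns per-frame SD_k with the import
level and reports the delay between sustained shape recovery (SD_k at or
below threshold for all later frames) and influx onset, operationalised as
the first frame with import level < 0.95 (configurable). Option lists are
validated against the known keys; unknown keys are rejected by name.

# Raft ordering simulator

Rafts are hard rectangles on a flat periodic plane -- at vesicle radii three
orders of magnitude above the raft size, membrane curvature is negligible at
domain scale, and membrane-deformation coupling is out of scope. Metropolis
single-particle translation/rotation moves with hard-core rejection
(separating-axis test, compiled) stand in for Brownian dynamics: the claims
under test are steady-state order contrasts, not kinetic rates. Random
sequential insertion builds initial states; requests above coverage 0.45 are
rejected outright as unreachable by insertion.

`transform_shapes()` reconfigures rectangles in place: the half-length
follows a geometric path while the area interpolates linearly (the
square-to-elongated raft transition is area-preserving to ~2.4%, and the
monotone area path keeps every substep's area change under 10%); after each
substep the configuration relaxes with MC sweeps and blocked particles retry.
A single-step transformation at working coverage reliably jams -- the
geometric demonstration of why gradual reconfiguration matters.

Local order is measured over neighbour pairs within a cutoff radius: nematic
$S_2 = \langle\cos 2\Delta\theta\rangle$ and tetratic $S_4 = \langle\cos
4\Delta\theta\rangle$ (insensitive to 90-degree flips, matching side-by-side
rectangle packing), a per-particle local $S_4$, the fraction of particles
with local $S_4 > 0.7$ ("ordered fraction"), and connected-cluster sizes
among ordered particles. The default neighbour radius is $1.2\sqrt{LW}$, the
particle footprint scale: it is invariant under the area-preserving
transformation (so square and elongated states are compared at the same
radius) and matches the measured range of contact alignment (pair
$\langle\cos 2\Delta\theta\rangle \approx 0.8$ at 40-80 nm, decaying to zero
beyond ~140 nm at coverage 0.23). A radius tied to the particle long axis
instead averages ~9 mostly-uncorrelated neighbours for elongated rafts and
~1 chance-aligned neighbour for squares, which inverts the physical contrast;
both the radius and the 0.7 cutoff remain configurable.

**Scope of the ordering claim.** At coverage 0.23 the elongated state is deep
in the isotropic phase ($\rho L^2 \approx 2.1$), so a pure hard-core model
produces *short-range contact alignment* -- strong for aspect ratio 9.5,
absent for aspect ratio 1.3 -- but no long-range order. The square-vs-
elongated contrast is therefore robust (ordered fraction ~0.05 vs ~0.23,
about 4-5x over seeds). The *pathway* contrast (in-place transformation vs
direct insertion of elongated rafts), by contrast, is **not** resolved by
excluded volume alone: we measured distance-resolved pair alignment for
transformed, freshly inserted, and briefly relaxed configurations and found
them statistically indistinguishable -- contact alignment here is an
equilibrium property reached from every preparation pathway. Reproducing the
experimentally observed pathway dependence evidently requires physics beyond
the hard core (e.g. membrane-mediated interactions or strongly suppressed
mobility of elongated rafts), which this module deliberately does not model.
The analysis script reports all three states honestly.

# Problem sizes and numerical conventions

- Tracing analyses use 512 x 512 px frames at 0.1 um/px, ROI 21 px, 3-degree
  steps (120 points per vesicle); population summaries in the analysis
  scripts use 24 vesicles per raft state.
- FCS fits use 64 log-spaced lags spanning 1 us - 1 s; parameter-recovery
  studies use 100 seeded replicates.
- Ordering experiments use n = 200 particles at coverage 0.23 (box ~1.84 um),
  10^4 equilibration sweeps for the square state, a 50-substep transformation
  with 20 relaxation sweeps per substep, and 2 x 10^3 post-transformation
  sweeps -- contact alignment equilibrates within a few hundred sweeps, which
  we verified by comparing against longer runs.
- Coordinates are 0-based pixel indices with x = column, y = row and the
  origin at the top-left pixel centre; angles are measured counter-clockwise
  in that frame. Physical positions are pixel indices times `pixel_size`.
- All RNG flows through per-call seeds; identical seeds give bit-identical
  images, curves and Monte Carlo trajectories.

# Known limitations

- The tracer assumes a star-shaped contour about the chosen centre (one
  membrane crossing per ray); strongly budded or multi-lobed vesicles violate
  this and should be rejected by the wandering/empty-ROI diagnostics rather
  than traced.
- SD_k conflates all deformation modes into one number; it cannot distinguish
  mode-2 elongation from higher-order lobes.
- The flux statistic assumes the exterior level is spatially uniform; strong
  background gradients require manual exterior ROI placement.
- The ordering module asserts qualitative contrasts only, and only those a
  hard-core model can support (see above); no quantitative comparison to any
  theoretical phase boundary is claimed.
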