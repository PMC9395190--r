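---
title: "Methods: from matrix deformation to migration gaits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from matrix deformation to migration gaits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellgait)
```

## The problem

Mesenchymal cells embedded in soft fibrous matrices move slowly and show
no cell-scale actin flow.  Instead they periodically pinch the matrix at
two contraction centers, one on each side of the nucleus.  At negligible
inertia, a time-reciprocal sequence of shape changes produces no net
motion (the scallop theorem), so directed migration requires the two
pinching cycles to break time-reversal symmetry.  The measurable
signature is a phase shift `psi = 2 pi lag / T` between the front and
back contraction-extension cycles, and, equivalently, a closed cycle of
finite area in the plane spanned by the force dipole moment D and the
force quadrupole moment Q of the matrix deformation-rate field.

`cellgait` implements the full measurement chain on displacement-rate
fields `u_i(n)` (from its own KLT-style feature tracker or from files),
plus a minimal bead model connecting the gait parameters to the net
migration velocity.

## Analysis chain

1. **Tracking** (`track()`, `subtract_drift()`): Shi-Tomasi
   minimum-eigenvalue corners, pyramidal Lucas-Kanade refinement with a
   forward-backward consistency check (< 1 px), and median-based rigid
   drift subtraction estimated from a sparse feature set.  Defaults
   (features, 40 px interrogation window, two pyramid levels, 20
   iterations) follow common practice for textured matrix imagery; for
   the small synthetic images in the tests the feature count is scaled
   down with image area.  The tracker states its failure mode explicitly:
   fewer than 10 % usable tracks raises an error instead of returning a
   sparse field.
2. **Divergence and kymographs** (`divergence_field()`, `kymograph()`,
   `extract_trace()`): scattered vectors are bin-averaged on a regular
   grid and differentiated by central differences; the divergence is
   averaged across a band around the cell axis and binned along it.
   Front/back traces average a 3 um window (middle of the conventional
   2-5 um range) centred on the nucleus front/back, and the trace mean is
   subtracted.
3. **Periods and lags** (`autocorrelate()`, `find_period()`,
   `cross_correlate()`, `phase_shift()`): correlogram-based throughout;
   no spectral estimation, matching the procedure the measurements are
   designed around.
4. **Multipoles** (`dipole_tensor()`, `quadrupole_tensor()`,
   `dq_trajectory()`, `cycle_area()`): `S = (D + D')/2` with
   `D_ij = sum_n Delta_i(n) u_j(n)` (um^2/min) and
   `Q_ijk = sum_n Delta_i Delta_j u_k` (um^3/min).  The main dipole is
   the eigenvalue of largest magnitude with its sign retained
   (contraction is negative); the quadrupole is fully contracted along
   the cell axis, the rank-3 analogue of `e' S e`.  Cycle areas
   (um^5/min^2) are signed shoelace areas of one-period windows;
   normalized areas express them as a percentage of the bounding
   rectangle of the whole trajectory.

## Numerical choices

* **Autocorrelation estimator.**  The biased (divide by the full-sample
  energy) estimator is used, so the zero-lag value is exactly 1 and all
  magnitudes stay within 1.  Its values taper by `(n - k)/n`, which the
  peak threshold takes into account (below).
* **Period threshold.**  The selection rule is "first strict local
  maximum above one standard deviation of the positive-lag correlogram
  values".  That dispersion collapses for structureless traces, which
  would let pure noise qualify, so the threshold is floored at the
  lag-dependent white-noise band `3 sqrt(n - k)/n`.  With this guard the
  measured false-positive rate on seeded white noise is a few percent
  while recovery of periods at signal-to-noise 5 is unaffected (both
  properties are exercised in the test suite).  Peaks are strict
  three-sample maxima; ties break toward smaller lags.  Constant traces
  yield "no period" rather than an error, matching the discard
  convention for uninterpretable correlograms.
* **Cross-correlation sign.**  Positive lag means the front trace leads
  the back trace.  For near-sinusoidal traces the largest-magnitude rule
  is sign-ambiguous (a trough of equal magnitude sits half a period from
  the true peak), so extrema of positive correlation are preferred
  within 80 % of the top magnitude - front and back are same-sign
  contraction waveforms - with remaining ties resolved toward smaller,
  then positive, lags.
* **Degenerate dipole tensors.**  An isotropic `S` has no defined axis;
  the frame is flagged and the previous frame's axis is carried forward.
* **Cutoff radii.**  The D-Q trajectory is computed for an ensemble of
  cutoff radii (default 0.6-1.2 times the field extent measured from the
  cell centre); the spread across radii stands in for an error bar.  The
  geometry container carries nucleus positions, not the full cell
  outline, so the field extent is the reference length.

## The synthetic generator

`gen_dipole_field()` emulates the study conditions: two pinching units
15 um apart (a 10-20 um nucleus gap), periods 5-11 min, matrix
displacement amplitudes of about 2.5 um, sampling every 30 s, durations
of 36-100 min, optional front-back phase shift, and additive Gaussian
noise standing in for tracker jitter.  Each pinch is a radially
symmetric, Gaussian-enveloped sink of width `sigma = 5` um - the spatial
decay of a pinch in a fibrous matrix is not constrained by available
measurements, so `sigma` is a documented convention, not a fitted value.
The matrix is treated as linearly elastic with no memory (displacement
prescribed directly), justified by the measured linear elasticity of
such matrices (about 50 Pa).  `gen_texture_sequence()` builds a fibrous
texture and warps it with the cumulative field so the tracker can be
validated against per-pixel ground truth.

What passing tests on these fields do *not* show: real matrices are
discrete fiber networks with non-affine deformation, the noise of a real
tracker is spatially correlated with texture, and real cells change
shape and axis over time.  The generator validates the measurement
chain, not the biology.

One consequence of the radially symmetric kernel is worth noting: a
radial pinch contributes an almost isotropic dipole tensor (the vectors
of a radial field sum to zero, removing the offset term), so the main
dipole axis is ill-conditioned on these fields.  Axis-alignment
behaviour is therefore tested on uniaxial pinch fields, which also match
the biological situation of contraction along the cell axis.

## The bead model

`bead_model()` configures four collinear beads of radius `a = 1` um:
two dipolar units of rest length `D = 10` um whose lengths oscillate in
`[D, D + d]` with `d = 0.5` um and period `T`, unit centers `r = 60` um
apart, and unit B lagging unit A by `psi`.  The shape is fully
prescribed; only rigid translation is free.  The default sinusoidal
waveform makes analytic checks easy; the smoothed square waveform
reproduces the idealized four-state cycle.

**Swimmer.**  Oseen-type `1/distance` mobility coupling between beads
with self-mobility `1/(6 pi eta a)`, solved under the gap-rate
constraints and the force-free condition at every step.  Stokes
kinematics makes the per-cycle displacement independent of the period,
so `V ~ 1/T` holds exactly, and the small-amplitude velocity scales as
`d^2` with `V(psi)` odd and `V(0) = 0`.

**Crawler.**  No hydrodynamics.  Each bead adheres to the matrix through
bonds of stiffness `k_b` turning over at rate `k_off`; in the
fast-binding, small-force limit this yields a slip law
`F = xi0 w / (1 + |w| / v_adh)` with friction `xi0 = k_b / k_off` and
adhesion velocity scale `v_adh = delta_off k_off`, where `delta_off` is
the bond mechanosensitivity length.  The matrix is a quasi-static linear
elastic medium coupling the beads through a `1/distance` compliance
kernel.  This inter-unit coupling is essential: a symmetry analysis
(verified numerically during development) shows that any purely local
adhesion law - odd in force, even in force magnitude - yields exactly
zero net displacement on this geometry for sinusoidal or symmetric
square gaits.  Consistently, the crawler's geometric prefactor involves
the unit separation `r`.

Crawler defaults are chosen from the stated limits, not fitted:
`k_off = 10` per minute (fast binding compared with every gait frequency
in the sweeps), `delta_off = 0.1` um (keeps slip below about 20 % of
`v_adh` over the sweeps, inside the linearized small-force regime), and
`k_b` such that the adhesion-matrix relaxation time
`tau_m = xi0 / (6 pi mu a)` is one minute, the order of the matrix
recoil time observed after local detachment events.

**Measured scaling behaviour.**  With these defaults the amplitude
exponent of the crawler velocity is 3 (the Bell-law `|q| q`
rectification contributes amplitude as `d^2 |d|`), and the swimmer
recovers exponents 2 (amplitude) and exactly -1 (period).  The
crawler's period dependence is not a single power law: the rectified
velocity peaks where the gait frequency matches `1/tau_m` and steepens
beyond, so the log-log slope fitted over the period window 2-32 min is
about -2.3, consistent with an inverse-square trend over that window
but not an asymptote of this model.  The acceptance script reports the
fitted values; they are measurements of this implementation, not inputs.

**Integration.**  Fixed-step 4th-order Runge-Kutta for the crawler's
bond-force state (the kernel tables are periodic in the gait phase and
precomputed once per cycle), Simpson quadrature for the state-free
swimmer.  The default step `T/2000` changes per-cycle displacements by
well under 1 % when halved (checked by a Richardson test); 3 transient
cycles are discarded and 10 cycles averaged.  An overloaded adhesion
linearization (`|F|` approaching `xi0 v_adh`) raises an error suggesting
smaller amplitudes rather than returning silently nonlinear garbage.

## Classification rule

`gait_analysis()` labels a cell migrating when its normalized D-Q cycle
area exceeds a noise floor *and* the front-back lag magnitude exceeds
one frame interval.  The floor comes from `dq_noise_floor()`: the 95th
percentile of normalized areas over seeded noise-only replicates of the
same study conditions.  This is a repository convention - the original
labels came from trajectory inspection, and no persistence criterion is
prescribed - so the rule and its threshold are explicit, tunable inputs.

## Problem sizes

The test suite runs the generators at 2-4 periods of 8 min sampled every
30 s on 3 um grids, tracker checks on 160-224 px textures with a few
hundred features, bead-model property checks at 500-1000 steps per cycle,
and the study-scale checks at the full 2000 steps per cycle with 5-point
period sweeps and 4-point amplitude sweeps.  These sizes were chosen so
the whole chain, including the Monte-Carlo noise floor (100 replicates),
runs comfortably on a single core.

## Known limitations

* The crawler is a reconstruction from stated physical ingredients; its
  period-scaling window behaviour (above) is the main caveat.
* The tracker is dense enough for matrix textures but has no occlusion
  handling and no affine window deformation; large rotations or shears
  between frames will shed tracks.
* Geometry is assumed rigid per frame (center, axis, nucleus front/back);
  cell outlines and axis curvature are out of scope.
* The D-Q cycle segmentation uses the correlogram period; when none is
  found the whole trajectory is closed into a single loop and flagged.
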