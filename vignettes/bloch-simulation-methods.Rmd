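---
title: "Simulation methods: operator splitting, spinors, and sequence-aware stepping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation methods: operator splitting, spinors, and sequence-aware stepping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsim)
```

## The model

`mrsim` simulates a collection of independent isochromats ("spins"), each
with a position $x$, proton density $M_0$, relaxation times $T_1, T_2$ and
off-resonance $\Delta\omega$, evolving under the Bloch equations in the
rotating frame:

$$\frac{dM}{dt} = \gamma\, M \times B
  + \frac{(M_0 - M_z)\hat z}{T_1} - \frac{M_x\hat x + M_y\hat y}{T_2},
\qquad
B = \begin{pmatrix} B_{1,x}(t) \\ B_{1,y}(t) \\
    G(t)\cdot x(t) + \Delta\omega/\gamma \end{pmatrix}.$$

Spins do not interact, which is what makes the signal a plain sum of
transverse magnetizations and the computation embarrassingly parallel.
The acquired sample at an ADC time is $\sum_i M_{xy,i}$ — one uniform
receive coil, no noise (`simulate_mri()`).

Assumptions inherited from this model: no diffusion or exchange
(Bloch–Torrey / Bloch–McConnell terms), magnetic properties constant over
time, motion only through a prescribed Lagrangian displacement field
$u(x_0, t)$, and $T_2^\ast$ only as far as a spin distribution represents
it.  $T_2 \le T_1$ is deliberately *not* enforced: the built-in test
phantoms use $T_1 = T_2$.

## Operator splitting and the two regimes

Each time step applies (1) the exact rotation generated by the effective
field held constant over the step, then (2) exact relaxation
($M_{xy} \mathrel{*}= e^{-\Delta t/T_2}$,
$M_z \leftarrow M_z e^{-\Delta t/T_1} + M_0(1 - e^{-\Delta t/T_1})$) —
first-order splitting, in that order.

The sequence is classified into two regimes per simulation block:

* **Excitation** (some $B_1 \ne 0$).  Rotations are stored as SU(2)
  spinors $(\alpha, \beta)$ with
  $\alpha = \cos(\varphi/2) - i n_z \sin(\varphi/2)$,
  $\beta = -i\, n_{xy} \sin(\varphi/2)$,
  $\varphi = -\gamma |B| \Delta t$ (`spinor_from_field()`), applied
  elementwise by `apply_spinor()`.  Gradients and off-resonance both enter
  $B_z$, so slice-profile-type effects of off-resonance during RF are
  captured.  For rastered (piecewise-constant) RF the per-step rotation is
  exact; for a smooth envelope sampled on a raster the method's local
  error is $O(\Delta t^3)$, globally second order, which the test suite
  verifies empirically on a ramped pulse with an off-resonant spin (the
  off-resonance makes consecutive rotation axes non-commuting — with a
  fixed axis the composition would be exact and there would be nothing to
  measure).  The convergence fixture uses $T_1 = T_2 = \infty$ so the
  measured slope isolates the rotation error rather than the
  rotation–relaxation commutator, which is a separate $O(\Delta t)$ term
  with a tiny prefactor ($\sim \Delta t \cdot \theta / T_2$ over a pulse of
  flip $\theta$).

* **Precession** ($B_1 = 0$ throughout).  All rotations are about $z$, so
  the transverse magnetization just accumulates phase
  $\varphi = -\gamma \int B_z\, dt$.  `precession_block()` evaluates this
  integral with the cumulative trapezoidal rule over the node set, which is
  *exact* when gradients are piecewise-linear and spins static.  $T_2$
  decay is tracked per node (ADC samples need it); $M_z$ recovery does not
  couple to precession and is applied once over the block — algebraically
  identical to per-step application.

Sign convention: $\varphi = -\gamma B \Delta t$ throughout, so positive
off-resonance accrues negative phase; all tests and the k-space definition
$k(t) = (\gamma/2\pi)\int G\,d\tau$ follow this consistently.

## Sequence-aware time stepping

`critical_times()` builds the node set the solver must visit:

* block boundaries and every gradient vertex (trapezoid exactness means no
  interior nodes are needed between them),
* RF raster boundaries, refined to spacing $\le$ `dt_rf` wherever the
  envelope is nonzero,
* every ADC sample time (flagged, not duplicated, when it coincides with a
  vertex; duplicate merge tolerance $10^{-12}$ s),
* interior nodes at spacing $\le$ `dt` *only when the phantom moves* —
  positions are then refreshed at every node and the trapezoid uses the
  updated $B_z$ endpoints.

Defaults: `dt = 1e-3` s (motion refinement cap; effectively vertex-only
stepping for static phantoms), `dt_rf = 1e-5` s (500 steps across a
typical 0.5 ms hard pulse would be overkill — 50 are already exact for a
constant envelope; the value matters only for shaped pulses), `n_blocks =
20`, `n_threads = 1`.  `n_blocks` and `n_threads` are memory/layout knobs:
the signal is invariant to both (verified to $10^{-12}$ relative), because
chunk partial signals are accumulated in separate buffers and summed, and
block boundaries only re-slice a deterministic sweep.

`partition_blocks()` cuts the steps into `n_blocks` near-equal contiguous
spans, tagging each excitation or precession.  Two gluing rules keep the
semantics clean: a boundary never bisects a contiguous nonzero-$B_1$ run
(a pulse stays in one regime) and never separates two samples of the same
ADC event.  Both shift the boundary forward.

One modelling caveat: waveforms are assumed continuous at block
boundaries.  A gradient that jumps discontinuously between blocks
(infinite slew — unphysical, and rejected by `validate_sequence()` within
events) would make both the trapezoid and the midpoint-averaged excitation
step attribute half the jump to the preceding interval.  All built-in
sequence builders ramp to zero at block edges.

## Phantoms: what they emulate, and what they do not

* `column_phantom()` — four contiguous 50 mm segments along the
  phase-encode axis with $M_0 = (1, 0.5, 1, 0.5)$ and $T_1 = T_2 = (100,
  50, 100, 50)$ ms at 1 mm spacing: one-dimensional structure for
  quantitative solver comparisons.
* `circles_phantom()` — a 50 mm disc ($T_1 = T_2 = 100$ ms) whose inner
  25 mm core is off-resonant by 200 rad/s ($T_1 = T_2 = 50$ ms):
  the classic off-resonance displacement fixture.  Region membership is
  strict-interior / half-open so boundary spins belong to exactly one
  region.
* `pseudo_brain_phantom()` — a fully synthetic multi-ellipse head with
  three tissue classes (WM-, GM-, CSF-like values at 1.5 T) and an
  optional smooth off-resonance field over a stated range.  It mimics the
  geometry of an axial slice and is deterministic given its seed; it is
  *not* derived from any imaging database, so tests that pass on it
  demonstrate solver and pipeline behavior, not anatomical realism.

All phantoms are delta distributions on ~1 mm grids.  Real tissue is
continuous: delta rasters alias once gradient moments approach the raster
Nyquist (spurious echoes from spoilers), and intra-voxel dephasing
($T_2^\ast$) appears only to the extent the spin density resolves it.
Increasing spin density is the standard mitigation.

## Sequence builders

EPI (`epi_sequence()`): hard 90, pre-phasers to the k-space corner, `n`
serpentine lines with samples on flat-tops only (dwell 4 us, ramps
100 us → 0.6 ms per line at `n = 100`), phase blips on the falling ramps.
ADC samples sit at dwell centers; pre-phaser areas are solved so sample
$j$ of line $m$ lands exactly on $(j - n/2, m - n/2)\,\Delta k$ with
$\Delta k = 1/\mathrm{FOV}$, and the delay before the train places the
center-line center sample at TE.  The spin-echo variant inserts a real,
simulated hard 180 at TE/2 whose `refocus` flag negates accumulated k in
`k_trajectory()` (display metadata; the physics comes from the pulse).

Spiral (`spiral_sequence()`): an Archimedean-type outward spiral
$k(\tau) = k_\mathrm{max}\tau^2 e^{i(2\pi N \tau + \theta_0)}$ whose
duration is chosen numerically to respect 90 % of $G_\mathrm{max}$ and
$S_\mathrm{max}$; the $\tau^2$ radius keeps $G(0) = 0$.  Each shot tapers
to zero and rewinds its net moment so interleaves start from $k = 0$.
This is a deliberate simplification — adequate for limit/trajectory tests
and artifact demonstrations, not a time-optimal design.

Radial bSSFP fingerprinting (`mrf_schedule()`, `mrf_bssfp_sequence()`):
flip angles in $[0, 80^\circ]$ from seeded gradient noise (4 octaves) or a
noisy sinusoid, TRs uniform in $[14.5, 18]$ ms, TE = 5 ms, inversion with
TI = 50 ms, RF phase alternating $0/\pi$ with the ADC phase following the
RF, spokes advancing by $\pi/N$ or the tiny golden angle $\pi/(\phi + 6)
\approx 0.41239$ rad, and every TR's gradient moment refunded to zero.

## File formats

Pulseq: the writer emits a v1.4 subset (trapezoids in `[TRAP]`, arbitrary
waveforms resampled at gradient-raster centers in `[GRADIENTS]`, RF
resampled onto the 1 us RF raster as magnitude/phase shape pairs); the
reader also accepts v1.2/1.3 block layouts with `[DELAYS]`.  Shapes are
stored as run-length-encoded derivatives and reconstructed by cumulative
sum; shape data are printed at full precision because the codec's run
detection relies on printed equality matching double equality.  Amplitudes
are stored in Hz and Hz/m and converted through the scanner's $\gamma$.
Trapezoids round-trip to $<10^{-9}$ T/m; resampled arbitrary waveforms to
within one raster of slew.

Raw data: a simplified ISMRMRD-flavored HDF5 profile — `/header`
attributes (FOV, matrix, name, `sim_*` parameter snapshot) and per-readout
groups `acq{i}/data` (real/imaginary pairs), `/t`, `/traj` — chosen so a
converter to the strict standard is a thin adapter.  Round-trips are exact
at double precision.

## Reconstruction and fingerprint matching

`recon_cartesian_epi()` reverses even lines and applies a centered inverse
2-D FFT.  `recon_adjoint()` is the direct conjugate-phase sum with uniform
or ramp ($|k|$) density weights — $O(\text{samples} \times \text{pixels})$,
intended for desk-scale non-Cartesian data; on a complete Cartesian raster
with uniform weights it equals the FFT reconstruction to $10^{-8}$.

`build_dictionary()` simulates one on-resonance isochromat per $(T_1,
T_2)$ pair (defaults: 300–2500 ms every 10 ms; 40–350 ms every 4 ms —
221 × 78 atoms) through the schedule's inversion/TI/flip/TR/TE structure
with instantaneous rotations and no gradients: every TR is balanced, so
gradients contribute no net phase at TE and single-isochromat dictionary
practice applies.  Atoms are L2-normalized; `match_fingerprints()`
maximizes $|\langle s, d\rangle|$ (phase- and scale-invariant), breaking
ties toward the lowest atom index, with pixels below 5 % of the maximum
first-frame magnitude masked (a choice to avoid matching background;
disable with `mask_threshold = 0`).  Atoms with $T_2 > T_1$ are kept by
default (`exclude_t2_gt_t1 = FALSE`).  A subtlety worth recording: with no
relaxation and constant 90° flips the alternating-phase pulse pair
composes to the identity, so such a fingerprint is exactly 2-periodic
(1, 0, 1, 0, …), not constant — the no-transient property is what is
testable.

The noise model used in recovery tests is per-sample complex Gaussian
scaled to a stated SNR (30 dB) relative to the fingerprint RMS — an
idealization of thermal noise after reconstruction; it contains no
undersampling streaks, so recovery rates on it bound from above what a
158-spoke radial acquisition would achieve.

## The reference integrator

`reference_simulate()` is the package's internal accuracy oracle: uniform
steps (plus exact ADC times), per-step effective field obtained by exact
*averaging* of the piecewise waveforms over the step (exact for constant
fields, second-order otherwise), rotation applied as a Rodrigues 3×3
matrix, then relaxation.  It shares no solver code with the fast path —
different time grid, different field sampling, different rotation algebra
— so agreement (e.g. 0.0002 % normalized MAD on the column-EPI fixture at
a 1 us step) is evidence rather than tautology.  Its cost is what the
sequence-aware solver avoids: the EPI fixture needs ~130,000 uniform steps
against ~10,500 sequence-aware nodes (most of them mandatory ADC sample
times), and the fast path additionally vectorizes whole precession spans.

## Problem sizes and numerical choices in the test suite

The shipped tests run the full 200-spin column EPI against the 1 us
reference, two 7,829-spin circles simulations (off-resonance on/off), one
moving-phantom simulation, the full 17,238-atom dictionary with 400 noisy
pixels, and assorted small fixtures (8×8 EPI, 5–16-TR trains) — sizes
chosen so the whole suite documents the claims at desk scale in about two
minutes.  Key tolerances: spinor normalization $10^{-9}$; rotation vs.
matrix oracle $10^{-12}$; closed forms $10^{-10}$; thread/block invariance
$10^{-12}$ relative; time-merge $10^{-12}$ s.

## Known limitations

No coil sensitivities or multi-coil noise, no eddy currents or concomitant
gradients, no diffusion/exchange, no regularized or gridding-based
reconstruction (the adjoint is quadratic-cost), no GPU path.  The Pulseq
subset covers what the builders emit plus tolerant legacy reading — not
`[EXTENSIONS]`.
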