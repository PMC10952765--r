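# mrsim

Bloch-equation simulation of MRI acquisitions in R.

`mrsim` computes the complex signal an MR scanner would acquire from a
numerical phantom under an arbitrary pulse sequence, by solving the Bloch
equations in the rotating frame for every isochromat:

```
dM/dt = gamma * M x B(t)  +  relaxation,
B(t)  = ( B1x(t), B1y(t), G(t) . x(t) + dw/gamma )
```

Each spin carries a position, proton density M0, relaxation times T1/T2 and
an off-resonance frequency dw, and may move through a Lagrangian
displacement field.  The solver uses first-order operator splitting — per
time step an exact rotation under the effective field, then exact T1/T2
relaxation — with two specialized regimes:

* **Excitation** (B1 nonzero): rotations are composed in SU(2) spinor form
  with Cayley–Klein parameters `alpha = cos(phi/2) - i nz sin(phi/2)`,
  `beta = -i nxy sin(phi/2)`, `phi = -gamma |B| dt`; exact for
  piecewise-constant RF.
* **Precession** (B1 = 0): the phase `phi = -gamma * integral(Bz dt)` is
  accumulated by the trapezoidal rule, which is *exact* for piecewise-linear
  gradients and static spins — so between RF and ADC events the solver only
  needs to visit gradient vertices ("sequence-aware" time stepping).

Around the solver the package provides the full pipeline: phantom
generators (four-segment column, concentric circles with an off-resonant
core, a synthetic pseudo-brain), sequence builders (hard pulses, single-shot
GRE/SE EPI, interleaved spirals, radial bSSFP fingerprinting trains), a
Pulseq `.seq` reader/writer (v1.4 subset, tolerant of 1.2/1.3), raw-data
HDF5 I/O, Cartesian and adjoint reconstruction, and magnetic resonance
fingerprinting (MRF) dictionary simulation and maximum-dot-product
matching.  An independent dense-timestep reference integrator
(`reference_simulate()`, uniform steps, Rodrigues rotation matrices, no
regime logic) serves as the in-package accuracy oracle.

Intended users: MR physicists and methods developers who want to prototype
sequences, study artifacts (off-resonance displacement, motion ghosting),
or generate training/validation data without scanner time.

## Worked example

Single-shot gradient-echo EPI (TE = 100 ms, FOV = 230 mm, 100 x 100) of the
four-segment column phantom (segments with M0 = 1, 0.5, 1, 0.5 and
T1 = T2 = 100, 50, 100, 50 ms):

```r
library(mrsim)
sc  <- scanner()                 # 1.5 T defaults, gamma/2pi = 42.58 MHz/T
ph  <- column_phantom()          # 200 spins along y, 1 mm spacing
sq  <- epi_sequence(fov = 0.23, n = 100, te = 0.1, scanner = sc)
sq
#> <mr_sequence> 'epi': 103 blocks, 1 RF, 100 ADC, 129.948 ms

raw <- simulate_mri(ph, sq, sc, sim_config(dt_rf = 1e-5))
raw
#> <raw_data> 'epi': 100 readouts, 10000 samples

img <- recon_cartesian_epi(raw)  # complex 100 x 100 image
```

The image is one bright column at x = 0: magnitudes along it alternate with
the segments' T2-weighting (at TE = 100 ms the 100 ms-T2 segments retain
`exp(-1) = 0.37` of their signal per spin, the 50 ms segments `exp(-2) =
0.14`).  Checking the solver against the dense 1 microsecond reference:

```r
ref <- reference_simulate(ph, sq, sc, step = 1e-6)
signal_mad(unlist(lapply(raw$readouts, `[[`, "data")),
           unlist(lapply(ref$readouts, `[[`, "data")))
#> [1] 0.0002183761
```

i.e. the sequence-aware solver and the brute-force integrator agree to
0.0002 % of the peak signal, while the fast path visits ~12x fewer time
points and integrates whole RF-free spans in closed form.

A command-line front end is installed with the package
(`exec/mrsim`): `mrsim simulate --phantom builtin:column --seq
builtin:epi --out raw.h5`, plus `phantom`, `seq`, `recon` and
`inspect-raw` subcommands.

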