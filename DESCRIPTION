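Package: mrsim
Title: Bloch-Equation Simulation of MRI Acquisitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: General magnetic resonance imaging (MRI) acquisition simulator.
    Solves the Bloch equations in the rotating frame with a first-order
    operator-splitting scheme: RF excitation is applied as SU(2) spinor
    rotations and free precession is integrated exactly by trapezoidal phase
    accumulation over piecewise-linear gradients.  Pulse sequences are
    discretized with sequence-aware time stepping (gradient vertices, RF
    raster, ADC sample times), partitioned into excitation and precession
    blocks, and simulated over arbitrary spin phantoms with off-resonance and
    nonrigid motion.  Includes builders for the standard test phantoms and
    sequences (single-shot EPI, spiral, radial bSSFP fingerprinting trains),
    a Pulseq (.seq) reader/writer, ISMRMRD-flavored HDF5 raw-data I/O, basic
    Cartesian and adjoint reconstruction, and magnetic resonance
    fingerprinting dictionary matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
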