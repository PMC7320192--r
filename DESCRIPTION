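Package: tomowedge
Title: Missing-Wedge Restoration for Single-Particle Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Iterative, model-free correction of the missing-wedge artifact in
    low-tilt electron-tomography 3D reconstructions of single macromolecular
    particles. The restoration alternates real-space constraints (support mask,
    non-negativity, realness) with locking of the measured Fourier data zone,
    in the manner of Gerchberg-Papoulis band-limited extrapolation. Includes a
    complete simulation and evaluation harness: atom-model and synthetic
    phantom generation, tilt-series projection, direct Fourier backprojection,
    SNR-controlled Gaussian noise, Fourier shell correlation, resolution
    estimation, and real-space cross-correlation, together with MRC/CCP4 map
    and tilt-stack I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'fourier.R'
    'io.R'
    'phantom.R'
    'metrics.R'
    'tomosim.R'
    'restore.R'
    'bench.R'
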