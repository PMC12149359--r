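Package: sonotongue
Title: Ultrasound Monitoring of Artificial Tongue Deformation During Food
    Compression and Shear
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the deformation of a soft artificial
    tongue from B-mode ultrasound image sequences acquired on a
    tongue-palate biomimetic testing bench. Provides the imposed
    compression/shear motion protocol and force-frame alignment, a
    synthetic speckle phantom with known ground-truth deformation for
    validation, a frame-conditioning chain that isolates the bright
    dorsal-surface interface, open active-contour (snake) tracking of the
    surface with pixel, millimetre and time-of-flight views, multi-pass
    FFT particle image velocimetry with window deformation over a
    surface-anchored region of interest, and analysis of stick-slip
    friction phases, residual deformation and Young's modulus estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
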