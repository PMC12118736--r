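Package: ironmap
Title: Iron-Sensitive Cardiac MR Relaxometry and Particle-Binding Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for iron-oxide (MPIO) molecular cardiac MRI
    studies of ischemia/reperfusion. Generates digital left-ventricle phantoms
    and synthetic multi-echo, inversion-recovery and T2-prepared magnitude
    image series with Rician noise; computes pixel-wise R2*/T2*, T1 and T2
    maps (log-linear and nonlinear least-squares fits); derives coronary
    territory statistics including the pre/post-contrast delta-R2* measure and
    the ex vivo Gaussian-tail pixel-count-ratio statistic; and quantifies the
    accompanying microscopy read-outs: immunofluorescence coverage with
    remote-calibrated thresholds, spot counting per high-power field,
    proximity-rule particle binding, and dwell-time classification of
    flow-chamber particle tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
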