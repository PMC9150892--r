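Package: pialtof
Title: Flow-Related Enhancement Modelling and Vessel Segmentation for
    Mesoscopic Time-of-Flight MR Angiography
Version: 0.1.0
Authors@R:
    person("pialtof", "maintainers", email = "pialtof@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for time-of-flight MR angiography of
    mesoscopic (50-300 micrometre) pial arteries: closed-form spoiled
    gradient-echo signal and inflow magnetization, relative flow-related
    enhancement (FRE), blood dwell time, protocol optimization over
    repetition time and flip angle, a cylinder-in-voxel partial-volume
    FRE model, velocity-dependent vessel displacement prediction, a
    synthetic 3D angiogram phantom generator (branching vessel trees,
    two-echo T2* contrast, Rician noise, bias fields), a threshold plus
    region-growing vessel segmentation pipeline with skeleton-length
    quantification, and two-echo T2*-based removal of pial veins.
    Includes a minimal NIfTI-1 reader/writer and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
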