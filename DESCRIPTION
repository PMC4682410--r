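Package: mapvpeaks
Title: Peak Detection and Quantification for MALDI Mass Spectra Using an
    Asymmetric Pseudo-Voigt Model
Version: 0.1.0
Authors@R:
    person("mapvpeaks", "developers", email = "mapvpeaks@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies peaks in profile-mode MALDI mass
    spectra. Spectra are smoothed with a dual-tree complex wavelet
    transform using per-level soft thresholds selected by Stein's
    unbiased risk estimate, the baseline is removed with a monotone
    local-minimum curve, and peaks are fitted with a modified asymmetric
    pseudo-Voigt profile whose six parameters are estimated by
    self-organizing hierarchical particle swarm optimization.
    Overlapping peaks are decomposed recursively by re-splitting broad
    or highly asymmetric components at interior valleys. Includes
    simulators for two-component mixtures and multi-peak MALDI-like
    spectra, and evaluation utilities (peak matching at a relative m/z
    tolerance, sensitivity, FDR, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    base64enc,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
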