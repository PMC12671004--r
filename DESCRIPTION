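Package: pcfc
Title: Partial Modulation Index for Cross-Regional Phase-Amplitude Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimation of cross-regional phase-amplitude cross-frequency
    coupling with a back-door-adjusted partial modulation index (PMI) that
    removes the confounding bias introduced by local same-frequency phase
    coupling between regions. Includes the classical Kullback-Leibler
    modulation index, zero-phase FIR band decomposition with analytic-signal
    phase and amplitude extraction, time-shift surrogate permutation testing
    with two-dimensional cluster-based multiple-comparison correction,
    paired-signal simulators for validation (sinusoidal and LFP-like
    variants), Monte-Carlo sensitivity sweeps over noise, duration, and bin
    count, and directed-connectivity checks via the directed transfer
    function and binned phase transfer entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
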