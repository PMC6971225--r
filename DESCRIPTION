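Package: tactspike
Title: Spiking Models of Tactile Afferents with Bit-Accurate Fixed-Point Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates populations of SA-I and FA-I primary tactile afferents
    with four Euler-discretized spiking neuron models (Izhikevich, linearized
    Izhikevich, quadratic integrate-and-fire, and linearized QIF), both in
    floating point and in bit-accurate signed Q13.18 fixed-point arithmetic as
    used by digital neuromorphic circuits, including a shift-only variant whose
    coefficients are powers of two. Provides synthetic force stimuli
    (trapezoidal indentations, multi-sensor grid touch scenarios, and a
    glove-grasp experiment design), population spike rasters, and a
    rate-coding decoder based on spike counts, principal component analysis,
    and k-nearest-neighbour classification with stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    class,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
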