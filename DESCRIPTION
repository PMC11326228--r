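Package: cortistream
Title: Sound-Driven Cochlear Fluid Streaming and Inner-Ear Drug Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models sound-driven stirring of the cochlear fluids and its effect
    on inner-ear drug delivery. A parametric traveling-wave surrogate generates
    peristaltic organ-of-Corti wall motion; a two-layer incompressible
    Navier-Stokes solver with a Darcy-permeable basilar membrane computes the
    period-averaged drift (steady streaming) flow; and an advection-diffusion
    solver transports a round-window-applied drug through the Corti and
    scala-tympani fluids to produce effect-time maps. The package also
    implements the matching experimental analysis chain (Teager-energy response
    amplitudes, driven-response decay curves, 75-percent-criterion effect
    times, one-dimensional diffusion trend fitting, dB normalization, group
    comparisons, and swept-tone distortion-product otoacoustic emission level
    estimation) together with a seeded synthetic-data generator that emulates
    the recording protocol, so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    methods,
    generics,
    ggplot2,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
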