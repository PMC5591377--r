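Package: berryflux
Title: Oxygen Budgets of Photosynthetic Microbial Aggregates from Microsensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reaction-diffusion oxygen budgets for millimeter-sized
    photosynthetic microbial aggregates ("green berries" and similar marine
    snow particles). Provides the closed-form steady-state oxygen field of a
    uniformly reacting sphere in a diffusive medium, the diffusion-limitation
    (critical respiration) threshold for core anoxia, a conservative
    finite-volume transient solver for light-dark shift experiments,
    estimators that turn Clark-type microsensor depth profiles and point time
    series into per-aggregate and volumetric rates of dark respiration, net
    and gross photosynthesis and carbon fixation, acetylene-reduction
    (nitrogenase) and elemental C:N rate arithmetic, and a synthetic-data
    generator that emulates microsensor recordings from the forward models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
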