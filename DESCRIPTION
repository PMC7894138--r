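Package: ppsnet
Title: Peripersonal Space Representation from Multisensory Statistics in a
    Restricted Boltzmann Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the emergence of peripersonal space (PPS)
    representation in a two-layer Restricted Boltzmann Machine over
    probabilistic population codes. Unisensory populations (visual,
    proprioceptive, tactile) encode stimuli as Poisson spike counts with
    Gaussian tuning curves; one-step contrastive divergence learns the
    body-constrained statistics that couple touch to visuo-proprioceptive
    geometry. Provides synthetic stimulus-stream generators (Cartesian,
    joint-angle, gaze and hand-vision variants), training orchestration
    with epoch metrics, receptive-field characterizations, evoked tactile
    activity maps, population receptive-field shift analyses, and
    simulations of the proprioceptive drift observed in the invisible and
    rubber hand illusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
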