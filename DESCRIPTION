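Package: fermga
Title: Hybrid Genetic Algorithm and Neural-Network Surrogate Optimization of Fermentation Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Surrogate-assisted optimization of submerged-fermentation medium
    composition for flavonoid production by the medicinal fungus Phellinus
    igniarius. A small single-hidden-layer feedforward network (tanh hidden
    units, linear output) is trained by Levenberg-Marquardt or scaled
    conjugate gradient backpropagation on condition-to-yield records after
    min-max scaling, then maximized over a bounded nine-dimensional
    concentration box by a real-coded genetic algorithm with roulette-wheel
    selection, arithmetic crossover and uniform-reset mutation. Includes the
    packaged training and optimized-condition tables, cross-validated
    hidden-layer-size selection, multi-seed ensemble runs, a synthetic
    response-surface generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
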