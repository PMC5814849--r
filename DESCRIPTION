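Package: dnawalker
Title: Stepping Kinetics and Coarse-Grained Mechanics of a DNA Bipedal Walker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the leg-placing reaction of a DNA bipedal walker striding
    on a DNA origami track. Implements the kinetic-competition yield model
    (stepping versus irreversible fuel trapping), extraction of stepping rates
    from measured yields, a coarse freely-jointed-chain / rigid-rod Monte
    Carlo of the walker and fuel-bearing foothold over a hard-wall flat or
    cylindrical origami surface to estimate leg-placing contact probabilities
    and relative activation barriers versus step size, a fuel-hairpin
    correction, a synthetic single-molecule FRET burst generator with a
    two-population mixture estimator for yields, and a pipeline comparing
    model and synthetic-experiment yield curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
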