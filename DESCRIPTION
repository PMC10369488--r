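Package: regpes
Title: Relative Energy Gradient Analysis of Partitioned Potential Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis layer of relative energy gradient (REG)
    studies of additively partitioned energies (such as interacting quantum
    atoms, IQA, terms) along a one-dimensional control coordinate. The
    package segments a discrete potential energy surface at its stationary
    points, ranks every partitioned term by its ordinary least-squares slope
    against the total energy on each segment together with the Pearson
    correlation, calibrates a minimal geometry subset with the
    Ramer-Douglas-Peucker line simplification driven by an interpolated
    root-mean-square error scan, quantifies recovery error of the
    decomposition, and assesses atom-subset (cluster truncation) choices via
    slope, coefficient of determination and activation-energy-ratio
    diagnostics. A seeded synthetic-decomposition generator and a command
    line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
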