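Package: stromaefm
Title: Constrained Elementary Flux Mode Analysis of Tumour Metabolism and
    Stroma Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of a core model of cancer cell
    metabolism extended with tumoral stroma formation (collagen synthesis,
    inflammation markers IL1-beta and TNF-alpha, and growth factor VEGF-A).
    Provides a stoichiometric network container with SBML read/write,
    network compression into enzyme subsets, exhaustive and brute-force
    Elementary Flux Mode (EFM) enumeration at toy scale, a constrained EFM
    sampler combining logical activity constraints, strict linear
    inequalities and a support-size cap, linear-regression scoring of flux
    modes against exometabolomic exchange-flux data, parsimonious flux
    balance analysis, reaction essentiality checks, and artificial-centering
    hit-and-run flux sampling for method comparison. Includes synthetic-data
    generators for cell-line exchange-flux tables, planted-mode recovery
    experiments and toy networks with enumerable EFM sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
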