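Package: il35sim
Title: Radially Symmetric PDE Model of IL-35-Driven Tumor Growth and
    Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a ten-field reaction-diffusion-chemotaxis model of
    the tumor microenvironment under radial symmetry, in which tumor-derived
    interleukin-35 (IL-35) expands myeloid-derived suppressor cells, promotes
    VEGF-driven angiogenesis, and suppresses activated CD8+ T cells. The
    package couples tumor cells, M-CSF, MDSCs, IL-35, regulatory T cells,
    TGF-beta, CD8+ T cells, VEGF, endothelial cells and oxygen on the radius
    of a sphere (finite-volume method of lines, stiff time integration),
    supports anti-IL-35 dosing protocols (continuous and intermittent at
    equal total dose), and provides Latin-hypercube / partial-rank-correlation
    global sensitivity analysis of drug efficacy. Results are returned as
    tidy tibbles with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
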