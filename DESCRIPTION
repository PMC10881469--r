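Package: DEPSpectra
Title: Single-Shell Dielectrophoresis Spectra: Simulation, Fitting and
    Microfluidic Cell-Separation Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free electrical characterization of cells by
    dielectrophoresis (DEP). Implements the single-shell dielectric model of
    a cell (Clausius-Mossotti factor, DEP force, crossover frequencies),
    a generator of synthetic 3DEP-style relative-force spectra with
    population-level parameter variability, bounded nonlinear least-squares
    extraction of membrane permittivity, membrane conductivity and cytoplasm
    conductivity from measured spectra with R-squared gating and robust
    outlier removal, one-way ANOVA with Tukey HSD group comparisons, and a
    two-dimensional finite-difference model of a microfluidic DEP sorter
    (Laplace field solve, laminar transport, Stokes-drag particle tracing)
    reporting separation purity and yield.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: CellBiology, Software, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
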