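## Config-driven pipeline stages tying the modules together:
## simulate-spectra -> fit -> stats, and the separation run.  Each stage
## reads/writes CSV so any stage can be re-run standalone (or pointed at
## real 3DEP exports later).

#' Default pipeline configuration
#'
#' A nested list describing a full run: output paths, the synthetic-study
#' layout (groups, replicates, buffer, noise), the fit configuration and
#' the separation settings, all under one global seed.  Configurations can
#' be written to / read from YAML with \code{\link{writePipelineConfig}} /
#' \code{\link{readPipelineConfig}}.
#'
#' @param outDir output directory
#' @param seed global integer seed; every random draw in a run derives
#'   from it
#' @return A config list with components \code{version}, \code{seed},
#'   \code{paths}, \code{spectra}, \code{fit}, \code{separation}.
#' @export
pipelineConfig <- function(outDir = "dep-pipeline-out", seed = 1L) {
    list(
        version = 1L,
        seed = as.integer(seed),
        paths = list(
            out_dir = outDir,
            spectra = file.path(outDir, "spectra.csv"),
            fits = file.path(outDir, "fits.csv"),
            stats = file.path(outDir, "stats.csv"),
            outcomes = file.path(outDir, "sim_outcomes.csv"),
            sim_summary = file.path(outDir, "sim_summary.csv")),
        spectra = list(
            groups = c("MSC", "diff_w1"),
            n_per_group = c(24L, 24L),
            buffer_conductivity_S_per_m = 0.04,
            buffer_rel_permittivity = 78,
            scale = 1,
            noise_sd = 0.05),
        fit = list(r2_threshold = 0.85, outlier_k = 3,
                   max_outlier_fraction = 0.2, n_starts = 5L),
        separation = list(
            pop_a = "diff_w1", pop_b = "MSC",
            n_per_pop = 200L, v_rms = 10, mean_speed = 2e-3,
            frequency = "auto", viscosity = 1e-3,
            nx = 501L, ny = 61L, max_time = 30))
}

#' @rdname pipelineConfig
#' @param config a pipeline config list
#' @param path YAML file path
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$version) || is.null(cfg$seed))
        stop("invalid pipeline config: missing 'version' or 'seed'")
    cfg
}

.builtinPopulations <- function() {
    list(MSC = mscPopulation(),
         diff_w1 = differentiatedPopulation("diff_w1"))
}

.resolvePopulation <- function(name) {
    pops <- .builtinPopulations()
    if (!name %in% names(pops))
        stop("unknown population label '", name, "'; available: ",
             paste(names(pops), collapse = ", "))
    pops[[name]]
}

.fitConfigFrom <- function(cfg) {
    FitConfig(mediumRelPermittivity = cfg$spectra$buffer_rel_permittivity,
        mediumConductivity = cfg$spectra$buffer_conductivity_S_per_m,
        r2Threshold = cfg$fit$r2_threshold,
        outlierK = cfg$fit$outlier_k,
        maxOutlierFraction = cfg$fit$max_outlier_fraction,
        nStarts = cfg$fit$n_starts)
}

.writeCsv <- function(df, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(df), path, row.names = FALSE)
    invisible(path)
}

#' Pipeline stage: simulate spectra
#'
#' Generates the configured synthetic study and writes the long-format
#' spectra CSV.  Byte-identical output for identical config and seed.
#'
#' @param config a pipeline config list (see \code{\link{pipelineConfig}})
#' @return The spectra CSV path, invisibly.
#' @export
cmdSimulateSpectra <- function(config) {
    sp <- config$spectra
    pops <- lapply(sp$groups, .resolvePopulation)
    for (i in seq_along(pops)) pops[[i]]@label <- sp$groups[i]
    medium <- DielectricMedium(sp$buffer_rel_permittivity,
                               sp$buffer_conductivity_S_per_m)
    x <- simulateStudy(pops, medium, n = sp$n_per_group,
        scale = sp$scale, noiseSD = sp$noise_sd, seed = config$seed)
    dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
    message("simulate-spectra: ", ncol(x), " spectra (",
            paste(sp$groups, sp$n_per_group, sep = "=", collapse = ", "), ")")
    writeSpectra(x, config$paths$spectra)
    invisible(config$paths$spectra)
}

#' Pipeline stage: fit spectra
#'
#' Fits every spectrum in the stage-1 CSV; rejected spectra are flagged in
#' the output, never dropped.
#'
#' @param config a pipeline config list
#' @return The fits CSV path, invisibly.
#' @export
cmdFit <- function(config) {
    if (!file.exists(config$paths$spectra))
        stop("missing upstream file '", config$paths$spectra,
             "'; run cmdSimulateSpectra first")
    x <- readSpectra(config$paths$spectra)
    fits <- fitSpectra(x, .fitConfigFrom(config), seed = config$seed)
    nr <- sum(fits$rejected)
    message("fit: ", nrow(fits), " spectra, ", nr, " rejected")
    .writeCsv(fits, config$paths$fits)
    invisible(config$paths$fits)
}

#' Pipeline stage: group statistics
#'
#' Tukey HSD comparisons of every fitted parameter across groups, written
#' as a long-format CSV (one row per parameter and group pair).
#'
#' @param config a pipeline config list
#' @return The stats CSV path, invisibly.
#' @export
cmdStats <- function(config) {
    if (!file.exists(config$paths$fits))
        stop("missing upstream file '", config$paths$fits,
             "'; run cmdFit first")
    fits <- read.csv(config$paths$fits, stringsAsFactors = FALSE)
    gated <- gateByR2(fits, config$fit$r2_threshold)
    stats <- compareGroups(gated$accepted)
    message("stats: ", nrow(stats), " pairwise comparisons")
    .writeCsv(stats, config$paths$stats)
    invisible(config$paths$stats)
}

#' Pipeline stage: separation simulation
#'
#' Runs \code{\link{runSeparation}} with the configured populations and
#' writes the per-particle outcomes and the purity/yield summary.
#'
#' @param config a pipeline config list
#' @return The summary CSV path, invisibly.
#' @export
cmdSeparate <- function(config) {
    sc <- config$separation
    res <- runSeparation(
        popA = .resolvePopulation(sc$pop_a),
        popB = .resolvePopulation(sc$pop_b),
        medium = DielectricMedium(config$spectra$buffer_rel_permittivity,
            config$spectra$buffer_conductivity_S_per_m),
        nPerPop = sc$n_per_pop, vRms = sc$v_rms,
        meanSpeed = sc$mean_speed, frequency = sc$frequency,
        viscosity = sc$viscosity, nx = sc$nx, ny = sc$ny,
        seed = config$seed, maxTime = sc$max_time)
    message(sprintf("separate: f = %.4g Hz; purity %s", res$frequency,
        paste(sprintf("%s@%s %.1f%%", res$summary$target,
                      res$summary$outlet, res$summary$purity),
              collapse = ", ")))
    .writeCsv(res$outcome, config$paths$outcomes)
    .writeCsv(res$summary, config$paths$sim_summary)
    invisible(config$paths$sim_summary)
}

#' Run the full pipeline
#'
#' simulate-spectra, fit, stats, then the separation simulation.
#'
#' @param config a pipeline config list
#' @return The config, invisibly.
#' @export
cmdRunAll <- function(config = pipelineConfig()) {
    cmdSimulateSpectra(config)
    cmdFit(config)
    cmdStats(config)
    cmdSeparate(config)
    invisible(config)
}
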