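## DepSpectra: a SummarizedExperiment of relative-DEP-force spectra
## (frequencies x wells), plus the synthetic 3DEP-style generator and CSV IO.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importMethodsFrom SummarizedExperiment cbind
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Collection of DEP spectra
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' \code{"relativeForce"} holds the dimensionless relative-DEP-force readout
#' (rows = frequencies, columns = wells/replicates).  \code{rowData} carries
#' the frequency grid (\code{frequency_hz}, strictly increasing);
#' \code{colData} carries per-spectrum metadata: \code{group},
#' \code{replicate}, \code{well_id}, \code{buffer_conductivity_S_per_m},
#' \code{buffer_rel_permittivity}, \code{radius_m}, \code{seed}.
#'
#' @name DepSpectra-class
#' @exportClass DepSpectra
setClass("DepSpectra", contains = "SummarizedExperiment")

.requiredColData <- c("group", "replicate", "well_id",
    "buffer_conductivity_S_per_m", "buffer_rel_permittivity",
    "radius_m", "seed")

setValidity("DepSpectra", function(object) {
    msg <- character()
    if (!"relativeForce" %in% names(assays(object)))
        msg <- c(msg, "assay 'relativeForce' is required")
    rd <- rowData(object)
    if (!"frequency_hz" %in% names(rd)) {
        msg <- c(msg, "rowData column 'frequency_hz' is required")
    } else {
        f <- rd$frequency_hz
        if (any(!is.finite(f)) || any(f <= 0) ||
            is.unsorted(f, strictly = TRUE))
            msg <- c(msg, "frequency_hz must be finite, positive, strictly increasing")
    }
    miss <- setdiff(.requiredColData, names(colData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
    if ("relativeForce" %in% names(assays(object)) &&
        any(!is.finite(assay(object, "relativeForce"))))
        msg <- c(msg, "relative force values must be finite")
    if (length(msg)) msg else TRUE
})

#' @describeIn DepSpectra-class Constructor.
#' @param relativeForce numeric matrix, frequencies x spectra
#' @param frequencies frequency grid in Hz (one per row)
#' @param colData a \code{DataFrame}/\code{data.frame} of per-spectrum
#'   metadata with at least the required columns (see class description)
#' @return A \code{DepSpectra} object.
#' @export
DepSpectra <- function(relativeForce, frequencies, colData) {
    relativeForce <- as.matrix(relativeForce)
    colData <- DataFrame(colData)
    se <- SummarizedExperiment(
        assays = list(relativeForce = relativeForce),
        rowData = DataFrame(frequency_hz = frequencies),
        colData = colData)
    colnames(se) <- colData$well_id
    new("DepSpectra", se)
}

#' Frequency grid of a spectra collection
#' @param x a \code{\linkS4class{DepSpectra}}
#' @return Numeric vector of frequencies (Hz).
#' @export
frequencies <- function(x) rowData(x)$frequency_hz

#' Relative-DEP-force matrix
#' @param x a \code{\linkS4class{DepSpectra}}
#' @return Numeric matrix, frequencies x spectra.
#' @export
relativeForce <- function(x) assay(x, "relativeForce")

setMethod("show", "DepSpectra", function(object) {
    cat("DepSpectra:", nrow(object), "frequencies x", ncol(object), "spectra\n")
    f <- frequencies(object)
    cat(sprintf("  grid: %.3g Hz - %.3g Hz\n", min(f), max(f)))
    cat("  groups:", paste(unique(colData(object)$group), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Synthetic data generation
## ---------------------------------------------------------------------------

#' Default 3DEP-style frequency grid
#'
#' Twenty logarithmically spaced frequencies from 10 kHz to 40 MHz, the
#' acquisition grid of a 3DEP well-plate run (instrument range
#' 10 kHz - 50 MHz).
#'
#' @return Numeric vector of 20 frequencies in Hz.
#' @examples
#' defaultFrequencyGrid()
#' @export
defaultFrequencyGrid <- function() {
    10^seq(log10(1e4), log10(4e7), length.out = 20)
}

## Run fn() under a given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, fn) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    fn()
}

## One draw of the four variable parameters for n cells; matrix n x 4.
.drawParams <- function(model, n) {
    draw <- function(mean, sd) {
        if (model@distribution == "uniform") runif(n, mean - sd, mean + sd)
        else rnorm(n, mean, sd)
    }
    cbind(radius = draw(model@radiusMean, model@radiusSD),
          memPerm = draw(model@memPermMean, model@memPermSD),
          memCond = draw(model@memCondMean, model@memCondSD),
          intCond = draw(model@intCondMean, model@intCondSD))
}

.paramsValid <- function(m, model) {
    m[, "radius"] > model@membraneThickness & m[, "memPerm"] > 0 &
        m[, "memCond"] >= 0 & m[, "intCond"] >= 0
}

## Parameter table for n cells, redrawing invalid rows (bounded retries).
.sampleParamTable <- function(model, n, seed) {
    validObject(model)
    .withSeed(seed, function() {
        m <- .drawParams(model, n)
        for (try in seq_len(100L)) {
            bad <- which(!.paramsValid(m, model))
            if (!length(bad)) break
            m[bad, ] <- .drawParams(model, length(bad))[seq_along(bad), , drop = FALSE]
        }
        if (any(!.paramsValid(m, model)))
            stop("could not draw valid particle parameters for population '",
                 model@label, "' after 100 retries")
        as.data.frame(m)
    })
}

#' Draw individual cells from a population model
#'
#' Each of the four variable parameters (radius, membrane permittivity and
#' conductivity, cytoplasm conductivity) is drawn independently, by default
#' uniformly on \code{[mean - sd, mean + sd]}.  Draws violating the
#' single-shell invariants are redrawn (at most 100 rounds), then an error
#' is raised.
#'
#' @param model a \code{\linkS4class{PopulationModel}}
#' @param n number of cells (>= 1)
#' @param seed integer seed; the same seed reproduces the same cells
#' @return A list of \code{n} \code{\linkS4class{ShelledParticle}} objects.
#' @export
samplePopulation <- function(model, n, seed = 1L) {
    if (n < 1L) stop("n must be >= 1")
    tab <- .sampleParamTable(model, n, seed)
    lapply(seq_len(n), function(i)
        ShelledParticle(radius = tab$radius[i],
            membraneThickness = model@membraneThickness,
            memRelPermittivity = tab$memPerm[i],
            memConductivity = tab$memCond[i],
            intRelPermittivity = model@intRelPermittivity,
            intConductivity = tab$intCond[i]))
}

#' Synthetic spectrum of a single cell
#'
#' Emulates the 3DEP readout: \code{scale * Re[K(f)]} plus additive
#' homoscedastic Gaussian noise.  The proportionality factor between the
#' instrument's dimensionless relative force and \eqn{Re[K]} is not known a
#' priori, which is why the fitter treats it as a free parameter.
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param frequencies frequency grid (Hz); default \code{defaultFrequencyGrid()}
#' @param scale positive proportionality factor
#' @param noiseSD standard deviation of the additive noise (>= 0)
#' @param seed integer seed
#' @param group,replicate metadata labels
#' @return A one-column \code{\linkS4class{DepSpectra}}.
#' @export
generateSpectrum <- function(particle, medium,
                             frequencies = defaultFrequencyGrid(),
                             scale = 1, noiseSD = 0.05, seed = 1L,
                             group = "synthetic", replicate = 1L) {
    if (!(scale > 0)) stop("scale must be positive")
    if (noiseSD < 0) stop("noiseSD must be >= 0")
    .checkGrid(frequencies)
    clean <- scale * reCMSpectrum(particle, medium, frequencies)
    y <- if (noiseSD > 0)
        .withSeed(seed, function() clean + rnorm(length(clean), 0, noiseSD))
    else clean
    cd <- DataFrame(group = group, replicate = as.integer(replicate),
        well_id = sprintf("%s_w%03d", group, as.integer(replicate)),
        buffer_conductivity_S_per_m = medium@conductivity,
        buffer_rel_permittivity = medium@relPermittivity,
        radius_m = particle@radius, seed = as.integer(seed),
        scale = scale,
        true_mem_rel_permittivity = particle@memRelPermittivity,
        true_mem_conductivity_S_per_m = particle@memConductivity,
        true_int_conductivity_S_per_m = particle@intConductivity)
    DepSpectra(matrix(y, ncol = 1), frequencies, cd)
}

#' Synthetic spectra for a whole population
#'
#' Draws \code{n} cells from \code{model} and generates one noisy spectrum
#' per cell.  Per-spectrum noise seeds are derived deterministically from
#' \code{seed}.  The per-spectrum \code{radius_m} metadata records each
#' cell's true radius (emulating the bench-top cell-size measurement that
#' accompanies a 3DEP run); the generating parameters are kept in
#' \code{colData} columns prefixed \code{true_} for validation work.
#'
#' @param model a \code{\linkS4class{PopulationModel}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param n number of replicate spectra (default 24, a typical per-group
#'   replication in 3DEP work)
#' @param frequencies frequency grid (Hz)
#' @param scale proportionality factor relative force / Re[K]
#' @param noiseSD additive noise SD
#' @param seed integer seed controlling both the cell draw and the noise
#' @return A \code{\linkS4class{DepSpectra}} with \code{n} columns.
#' @export
generateGroupSpectra <- function(model, medium, n = 24L,
                                 frequencies = defaultFrequencyGrid(),
                                 scale = 1, noiseSD = 0.05, seed = 1L) {
    cells <- samplePopulation(model, n, seed = seed)
    cols <- lapply(seq_len(n), function(i)
        generateSpectrum(cells[[i]], medium, frequencies, scale = scale,
            noiseSD = noiseSD, seed = seed + 7919L * i,
            group = model@label, replicate = i))
    do.call(cbind, cols)
}

#' Simulate a multi-group 3DEP study
#'
#' @param populations list of \code{\linkS4class{PopulationModel}} objects
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param n spectra per group (scalar or one per population)
#' @param frequencies,scale,noiseSD as in \code{\link{generateGroupSpectra}}
#' @param seed integer seed; group g uses sub-seed \code{seed + 104729 * g}
#' @return A combined \code{\linkS4class{DepSpectra}}.
#' @export
simulateStudy <- function(populations, medium, n = 24L,
                          frequencies = defaultFrequencyGrid(),
                          scale = 1, noiseSD = 0.05, seed = 1L) {
    n <- rep_len(as.integer(n), length(populations))
    parts <- lapply(seq_along(populations), function(g)
        generateGroupSpectra(populations[[g]], medium, n[g], frequencies,
            scale = scale, noiseSD = noiseSD, seed = seed + 104729L * g))
    do.call(cbind, parts)
}

## ---------------------------------------------------------------------------
## Fixture populations (synthetic stand-ins)
## ---------------------------------------------------------------------------

#' Synthetic fixture populations
#'
#' Two stand-in cell populations used throughout examples and tests: an
#' undifferentiated "MSC"-like population and an early-differentiated one
#' with lower membrane permittivity and conductivity (hence a higher first
#' crossover frequency).  Parameter means sit inside the membrane
#' permittivity (6-9) and conductivity (0.7-5e-6 S/m) ranges reported for
#' mammalian cells by DEP; the spreads are modest laboratory-scale
#' variability.  These are synthetic defaults, not measured values.
#'
#' @param label population label
#' @return A \code{\linkS4class{PopulationModel}}.
#' @examples
#' crossoverFrequencies(meanParticle(mscPopulation()), DielectricMedium())
#' @export
mscPopulation <- function(label = "MSC") {
    PopulationModel(label = label,
        radiusMean = 9e-6, radiusSD = 0.5e-6,
        memPermMean = 9, memPermSD = 0.3,
        memCondMean = 1e-6, memCondSD = 0.1e-6,
        intCondMean = 0.4, intCondSD = 0.05)
}

#' @rdname mscPopulation
#' @export
differentiatedPopulation <- function(label = "diff_w1") {
    PopulationModel(label = label,
        radiusMean = 9e-6, radiusSD = 0.5e-6,
        memPermMean = 6, memPermSD = 0.3,
        memCondMean = 0.5e-6, memCondSD = 0.1e-6,
        intCondMean = 0.3, intCondSD = 0.05)
}

## ---------------------------------------------------------------------------
## CSV round trip
## ---------------------------------------------------------------------------

.dialectCols <- c("frequency_hz", "relative_force", "group", "replicate",
    "well_id", "buffer_conductivity_S_per_m", "buffer_rel_permittivity",
    "radius_m", "seed")

#' Write / read spectra as long-format CSV
#'
#' One row per (spectrum, frequency) with mandatory header
#' \code{frequency_hz, relative_force, group, replicate, well_id,
#' buffer_conductivity_S_per_m, buffer_rel_permittivity, radius_m, seed};
#' any additional \code{colData} columns (e.g. the \code{true_*} generator
#' columns) are preserved.  Numbers are written with 17 significant digits
#' so the round trip is exact.
#'
#' @param x a \code{\linkS4class{DepSpectra}}
#' @param path file path
#' @return \code{writeSpectra} returns \code{path} invisibly;
#'   \code{readSpectra} returns a \code{\linkS4class{DepSpectra}} (or an
#'   empty list when the file holds only a header).
#' @export
writeSpectra <- function(x, path) {
    cd <- as.data.frame(colData(x))
    extra <- setdiff(names(cd), .dialectCols)
    f <- frequencies(x)
    m <- relativeForce(x)
    long <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
        row <- data.frame(frequency_hz = f, relative_force = m[, j],
            group = cd$group[j], replicate = cd$replicate[j],
            well_id = cd$well_id[j],
            buffer_conductivity_S_per_m = cd$buffer_conductivity_S_per_m[j],
            buffer_rel_permittivity = cd$buffer_rel_permittivity[j],
            radius_m = cd$radius_m[j], seed = cd$seed[j])
        for (e in extra) row[[e]] <- cd[[e]][j]
        row
    }))
    if (is.null(long))
        long <- as.data.frame(setNames(
            rep(list(character(0)), length(.dialectCols)), .dialectCols))
    num <- vapply(long, is.numeric, logical(1)) &
        !vapply(long, is.integer, logical(1))
    for (cn in names(long)[num]) long[[cn]] <- sprintf("%.17g", long[[cn]])
    write.csv(long, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(path) {
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    miss <- setdiff(.dialectCols, header)
    if (length(miss))
        stop("spectra CSV is missing column(s): ", paste(miss, collapse = ", "))
    long <- tryCatch(
        read.csv(path, stringsAsFactors = FALSE, fill = FALSE,
                 colClasses = NA, check.names = FALSE),
        error = function(e) stop("malformed spectra CSV: ", conditionMessage(e)))
    if (ncol(long) != length(header))
        stop("malformed spectra CSV: ragged rows")
    if (nrow(long) == 0L) return(list())
    for (cn in c("frequency_hz", "relative_force",
                 "buffer_conductivity_S_per_m", "buffer_rel_permittivity",
                 "radius_m")) {
        v <- suppressWarnings(as.numeric(long[[cn]]))
        if (any(is.na(v)))
            stop("malformed spectra CSV: non-numeric value in column '", cn,
                 "', row ", which(is.na(v))[1])
        long[[cn]] <- v
    }
    ids <- unique(long$well_id)
    f <- long$frequency_hz[long$well_id == ids[1]]
    .checkGrid(f)
    m <- matrix(NA_real_, length(f), length(ids))
    extra <- setdiff(names(long), .dialectCols)
    cdCols <- c("group", "replicate", "well_id", "buffer_conductivity_S_per_m",
        "buffer_rel_permittivity", "radius_m", "seed", extra)
    cd <- vector("list", length(ids))
    for (j in seq_along(ids)) {
        sub <- long[long$well_id == ids[j], , drop = FALSE]
        if (nrow(sub) != length(f) || any(sub$frequency_hz != f))
            stop("malformed spectra CSV: inconsistent frequency grid for well '",
                 ids[j], "'")
        m[, j] <- sub$relative_force
        cd[[j]] <- sub[1L, cdCols, drop = FALSE]
    }
    cd <- do.call(rbind, cd)
    cd$replicate <- as.integer(cd$replicate)
    cd$seed <- as.integer(cd$seed)
    DepSpectra(m, f, cd)
}
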