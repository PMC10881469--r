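## Bounded nonlinear least-squares extraction of cell electric parameters
## from relative-DEP-force spectra, with robust outlier removal and
## R-squared gating.

#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

#' Configuration of the spectrum fitter
#'
#' Fixed (not fitted) quantities, box bounds for the four free parameters
#' (membrane relative permittivity, membrane conductivity, cytoplasm
#' conductivity, and the instrument scale factor), and the quality-control
#' knobs.  Conductivities and the scale are optimized on a log10 scale, so
#' their initial guesses default to the geometric mid-bounds.
#'
#' @slot radius fixed cell radius (m); per-spectrum metadata overrides this
#' @slot membraneThickness fixed membrane thickness (m)
#' @slot intRelPermittivity fixed interior relative permittivity
#' @slot mediumRelPermittivity,mediumConductivity buffer properties
#' @slot memPermBounds,memCondBounds,intCondBounds,scaleBounds length-2
#'   numeric bounds (lower, upper)
#' @slot memPermInit,memCondInit,intCondInit,scaleInit initial guesses
#' @slot r2Threshold R-squared acceptance gate (0, 1)
#' @slot outlierK multiplier of the robust residual scale beyond which a
#'   point is dropped (> 0)
#' @slot maxOutlierFraction largest fraction of points that may be removed
#' @slot nStarts number of seeded multi-starts for the optimizer
#' @name FitConfig-class
#' @exportClass FitConfig
setClass("FitConfig",
    representation(radius = "numeric", membraneThickness = "numeric",
        intRelPermittivity = "numeric",
        mediumRelPermittivity = "numeric", mediumConductivity = "numeric",
        memPermBounds = "numeric", memCondBounds = "numeric",
        intCondBounds = "numeric", scaleBounds = "numeric",
        memPermInit = "numeric", memCondInit = "numeric",
        intCondInit = "numeric", scaleInit = "numeric",
        r2Threshold = "numeric", outlierK = "numeric",
        maxOutlierFraction = "numeric", nStarts = "integer"))

setValidity("FitConfig", function(object) {
    msg <- character()
    bnd <- function(b, init, nm) {
        if (length(b) != 2L || b[1] >= b[2])
            return(paste(nm, "bounds must be (lower < upper)"))
        if (init < b[1] || init > b[2])
            return(paste(nm, "initial guess must lie inside its bounds"))
        NULL
    }
    msg <- c(msg,
        bnd(object@memPermBounds, object@memPermInit, "memPerm"),
        bnd(object@memCondBounds, object@memCondInit, "memCond"),
        bnd(object@intCondBounds, object@intCondInit, "intCond"),
        bnd(object@scaleBounds, object@scaleInit, "scale"))
    if (!(object@r2Threshold > 0 && object@r2Threshold < 1))
        msg <- c(msg, "r2Threshold must be in (0, 1)")
    if (!(object@outlierK > 0)) msg <- c(msg, "outlierK must be > 0")
    if (object@maxOutlierFraction < 0 || object@maxOutlierFraction >= 1)
        msg <- c(msg, "maxOutlierFraction must be in [0, 1)")
    msg <- msg[!vapply(msg, is.null, logical(1))]
    if (length(msg)) msg else TRUE
})

#' @describeIn FitConfig-class Constructor with package defaults.
#' @param radius fixed cell radius (m)
#' @param membraneThickness fixed membrane thickness (m)
#' @param intRelPermittivity fixed interior relative permittivity
#' @param mediumRelPermittivity,mediumConductivity buffer properties
#' @param memPermBounds,memCondBounds,intCondBounds,scaleBounds free-parameter
#'   box bounds
#' @param memPermInit,memCondInit,intCondInit,scaleInit initial guesses
#'   (defaults: geometric mid-bounds)
#' @param r2Threshold R-squared gate (default 0.85)
#' @param outlierK robust outlier multiplier (default 3)
#' @param maxOutlierFraction cap on removed points (default 0.2)
#' @param nStarts optimizer multi-starts (default 5)
#' @return A \code{FitConfig} object.
#' @export
FitConfig <- function(radius = 9e-6, membraneThickness = 5e-9,
                      intRelPermittivity = 60,
                      mediumRelPermittivity = 78, mediumConductivity = 0.04,
                      memPermBounds = c(1, 30),
                      memCondBounds = c(1e-9, 1e-4),
                      intCondBounds = c(0.01, 2),
                      scaleBounds = c(1e-3, 1e3),
                      memPermInit = sqrt(prod(memPermBounds)),
                      memCondInit = sqrt(prod(memCondBounds)),
                      intCondInit = sqrt(prod(intCondBounds)),
                      scaleInit = sqrt(prod(scaleBounds)),
                      r2Threshold = 0.85, outlierK = 3,
                      maxOutlierFraction = 0.2, nStarts = 5L) {
    new("FitConfig", radius = radius, membraneThickness = membraneThickness,
        intRelPermittivity = intRelPermittivity,
        mediumRelPermittivity = mediumRelPermittivity,
        mediumConductivity = mediumConductivity,
        memPermBounds = memPermBounds, memCondBounds = memCondBounds,
        intCondBounds = intCondBounds, scaleBounds = scaleBounds,
        memPermInit = memPermInit, memCondInit = memCondInit,
        intCondInit = intCondInit, scaleInit = scaleInit,
        r2Threshold = r2Threshold, outlierK = outlierK,
        maxOutlierFraction = maxOutlierFraction, nStarts = as.integer(nStarts))
}

setMethod("show", "FitConfig", function(object) {
    cat("FitConfig: r =", object@radius, "m, d =", object@membraneThickness,
        "m, eps_int =", object@intRelPermittivity, "\n")
    cat("  medium eps_r =", object@mediumRelPermittivity, ", sigma =",
        object@mediumConductivity, "S/m\n")
    cat("  R2 gate:", object@r2Threshold, "; outlier k:", object@outlierK, "\n")
})

## model prediction (no scale) for parameter vector on the internal scale
## p = (memPerm, log10 memCond, log10 intCond, log10 scale)
.fitModel <- function(p, f, cfg, radius) {
    10^p[4] * .reCM(f, radius, cfg@membraneThickness, p[1], 10^p[2],
        cfg@intRelPermittivity, 10^p[3],
        cfg@mediumRelPermittivity, cfg@mediumConductivity)
}

.fitBoundsInternal <- function(cfg) {
    list(lower = c(cfg@memPermBounds[1], log10(cfg@memCondBounds[1]),
                   log10(cfg@intCondBounds[1]), log10(cfg@scaleBounds[1])),
         upper = c(cfg@memPermBounds[2], log10(cfg@memCondBounds[2]),
                   log10(cfg@intCondBounds[2]), log10(cfg@scaleBounds[2])))
}

## Core least squares on (f, y) vectors; returns list(par, sse, converged).
.lsqCore <- function(f, y, cfg, radius, seed = 1L) {
    b <- .fitBoundsInternal(cfg)
    start0 <- c(cfg@memPermInit, log10(cfg@memCondInit),
                log10(cfg@intCondInit), log10(cfg@scaleInit))
    ## data-driven start: positive plateau of Re[K] is ~0.5-0.8, so the
    ## largest |y| pins the scale to within a factor of ~2
    scaleGuess <- max(abs(y)) / 0.6
    scaleGuess <- min(max(scaleGuess, cfg@scaleBounds[1]), cfg@scaleBounds[2])
    start1 <- start0; start1[4] <- log10(scaleGuess)
    starts <- list(start0, start1)
    if (cfg@nStarts > 2L) {
        rand <- .withSeed(seed, function()
            lapply(seq_len(cfg@nStarts - 2L), function(i)
                b$lower + runif(4) * (b$upper - b$lower)))
        starts <- c(starts, rand)
    }
    best <- NULL
    for (s in starts) {
        fit <- tryCatch(
            nls.lm(par = s,
                   fn = function(p) y - .fitModel(p, f, cfg, radius),
                   lower = b$lower, upper = b$upper,
                   control = nls.lm.control(maxiter = 500, ftol = 1e-15,
                                            ptol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(fit$fvec^2)
        conv <- fit$info %in% c(1L, 2L, 3L, 4L)
        if (is.null(best) || sse < best$sse)
            best <- list(par = fit$par, sse = sse, converged = conv)
    }
    best
}

.rejectedResult <- function(reason, nUsed = NA_integer_, removed = integer(0)) {
    DataFrame(mem_rel_permittivity = NA_real_,
        mem_conductivity_S_per_m = NA_real_,
        int_conductivity_S_per_m = NA_real_, scale = NA_real_,
        r_squared = NA_real_, co_first_hz = NA_real_, co_second_hz = NA_real_,
        n_points_used = nUsed, n_points_removed = length(removed),
        rejected = TRUE, reject_reason = reason)
}

#' Remove outlying points from a spectrum
#'
#' Iterative robust cleaning: fit the single-shell model, then drop every
#' point whose absolute residual exceeds
#' \code{outlierK * 1.4826 * median(|residual|)} and refit, stopping at a
#' fixed point or when more than \code{maxOutlierFraction} of the points
#' would be removed.
#'
#' @param f,y frequency (Hz) and relative-force vectors (length >= 6)
#' @param cfg a \code{\linkS4class{FitConfig}}
#' @param radius cell radius to hold fixed (default \code{cfg@radius})
#' @param seed seed for the optimizer multi-starts
#' @return List with \code{keep} (logical vector) and \code{removed}
#'   (integer indices into the original spectrum).
#' @export
removeOutliers <- function(f, y, cfg = FitConfig(), radius = cfg@radius,
                           seed = 1L) {
    n <- length(y)
    if (n < 6L) stop("need at least 6 points for outlier screening")
    keep <- rep(TRUE, n)
    maxDrop <- floor(cfg@maxOutlierFraction * n)
    repeat {
        fit <- .lsqCore(f[keep], y[keep], cfg, radius, seed = seed)
        if (is.null(fit)) break
        res <- abs(y - .fitModel(fit$par, f, cfg, radius))
        thr <- cfg@outlierK * 1.4826 * median(res[keep])
        # floor keeps numerically-exact fits from flagging rounding noise
        thr <- max(thr, 1e-8 * max(abs(y)))
        if (thr <= 0) break
        bad <- keep & res > thr
        if (!any(bad)) break
        if (sum(!keep) + sum(bad) > maxDrop) {
            # remove only the worst offenders up to the cap
            room <- maxDrop - sum(!keep)
            if (room <= 0L) break
            ord <- order(res, decreasing = TRUE)
            ord <- ord[keep[ord] & (res[ord] > thr)]
            bad <- rep(FALSE, n); bad[ord[seq_len(room)]] <- TRUE
        }
        keep[bad] <- FALSE
        if (sum(keep) < 6L) { keep[bad] <- TRUE; break }
    }
    list(keep = keep, removed = which(!keep))
}

#' Fit the single-shell model to one spectrum
#'
#' Bounded Levenberg-Marquardt least squares of
#' \code{relative_force = scale * Re[K(f)]} over membrane permittivity,
#' membrane conductivity, cytoplasm conductivity and scale (conductivities
#' and scale on a log10 internal scale), after robust outlier removal.
#' Crossover frequencies are computed from the fitted parameters on the
#' 10 kHz - 50 MHz instrument range.  Degenerate spectra (no variance) and
#' non-converged optimizations are flagged \code{rejected}, never dropped.
#'
#' @param f,y frequency (Hz) and relative-force vectors
#' @param cfg a \code{\linkS4class{FitConfig}}
#' @param radius cell radius to hold fixed (default \code{cfg@radius})
#' @param seed seed for the optimizer multi-starts
#' @param screenOutliers run \code{\link{removeOutliers}} first (default TRUE)
#' @return A one-row \code{DataFrame} with columns
#'   \code{mem_rel_permittivity}, \code{mem_conductivity_S_per_m},
#'   \code{int_conductivity_S_per_m}, \code{scale}, \code{r_squared},
#'   \code{co_first_hz}, \code{co_second_hz}, \code{n_points_used},
#'   \code{n_points_removed}, \code{rejected}, \code{reject_reason}.
#' @export
fitSpectrum <- function(f, y, cfg = FitConfig(), radius = cfg@radius,
                        seed = 1L, screenOutliers = TRUE) {
    if (length(f) != length(y)) stop("f and y must have equal length")
    if (length(y) < 6L)
        stop("need at least 6 frequency points to fit 4 free parameters")
    if (all(y == 0) || var(y) == 0)
        return(.rejectedResult("degenerate spectrum: no variance, scale unidentifiable",
                               length(y)))
    removed <- integer(0)
    if (screenOutliers) {
        scr <- removeOutliers(f, y, cfg, radius, seed = seed)
        removed <- scr$removed
        f <- f[scr$keep]; y <- y[scr$keep]
    }
    if (length(y) < 6L)
        return(.rejectedResult("fewer than 6 points after outlier removal",
                               length(y), removed))
    fit <- .lsqCore(f, y, cfg, radius, seed = seed)
    if (is.null(fit) || !fit$converged)
        return(.rejectedResult("optimizer did not converge", length(y), removed))
    p <- fit$par
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot > 0) 1 - fit$sse / ssTot else NA_real_
    cell <- ShelledParticle(radius = radius,
        membraneThickness = cfg@membraneThickness,
        memRelPermittivity = p[1], memConductivity = 10^p[2],
        intRelPermittivity = cfg@intRelPermittivity, intConductivity = 10^p[3])
    med <- DielectricMedium(cfg@mediumRelPermittivity, cfg@mediumConductivity)
    co <- crossoverFrequencies(cell, med, 1e4, 5e7)
    DataFrame(mem_rel_permittivity = p[1],
        mem_conductivity_S_per_m = 10^p[2],
        int_conductivity_S_per_m = 10^p[3], scale = 10^p[4],
        r_squared = r2,
        co_first_hz = if (length(co) >= 1) co[1] else NA_real_,
        co_second_hz = if (length(co) >= 2) co[2] else NA_real_,
        n_points_used = length(y), n_points_removed = length(removed),
        rejected = FALSE, reject_reason = NA_character_)
}

#' Fit every spectrum in a collection
#'
#' Applies \code{\link{fitSpectrum}} column by column.  When the
#' per-spectrum metadata carries a measured \code{radius_m} it overrides the
#' fixed radius in \code{cfg} (the bench measurement of mean cell size).
#' The buffer properties are likewise taken from the metadata.
#'
#' @param x a \code{\linkS4class{DepSpectra}}
#' @param cfg a \code{\linkS4class{FitConfig}}
#' @param seed base seed; spectrum j uses \code{seed + j}
#' @return A \code{DataFrame} with one row per spectrum (columns as in
#'   \code{\link{fitSpectrum}}, plus \code{group}, \code{replicate},
#'   \code{well_id}).
#' @export
fitSpectra <- function(x, cfg = FitConfig(), seed = 1L) {
    cd <- colData(x)
    f <- frequencies(x)
    m <- relativeForce(x)
    rows <- lapply(seq_len(ncol(x)), function(j) {
        cfgJ <- cfg
        cfgJ@mediumRelPermittivity <- cd$buffer_rel_permittivity[j]
        cfgJ@mediumConductivity <- cd$buffer_conductivity_S_per_m[j]
        r <- if (!is.null(cd$radius_m) && is.finite(cd$radius_m[j]))
            cd$radius_m[j] else cfg@radius
        fitSpectrum(f, m[, j], cfgJ, radius = r, seed = seed + j)
    })
    res <- do.call(rbind, rows)
    cbind(DataFrame(group = cd$group, replicate = cd$replicate,
                    well_id = cd$well_id), res)
}

#' Partition fit results by R-squared
#'
#' @param results a \code{DataFrame}/\code{data.frame} of fit results with an
#'   \code{r_squared} column
#' @param threshold acceptance threshold; results with
#'   \code{r_squared >= threshold} (and not otherwise rejected) are accepted
#' @return List with elements \code{accepted} and \code{rejected}; row counts
#'   always sum to \code{nrow(results)}.
#' @export
gateByR2 <- function(results, threshold = 0.85) {
    ok <- !is.na(results$r_squared) & results$r_squared >= threshold &
        !results$rejected
    list(accepted = results[ok, , drop = FALSE],
         rejected = results[!ok, , drop = FALSE])
}

#' Per-group summary of fitted parameters
#'
#' Mean, SD and n of each fitted quantity over the accepted (non-rejected)
#' results, the numbers that feed group comparisons and
#' \code{\linkS4class{PopulationModel}} construction.
#'
#' @param results fit results (as from \code{\link{fitSpectra}})
#' @param parameters columns to summarize
#' @return A \code{data.frame} with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{n}.
#' @export
summarizeGroup <- function(results,
                           parameters = c("mem_rel_permittivity",
                               "mem_conductivity_S_per_m",
                               "int_conductivity_S_per_m", "scale",
                               "co_first_hz", "co_second_hz")) {
    keep <- !results$rejected
    if (!any(keep)) stop("no accepted results to summarize")
    res <- results[keep, , drop = FALSE]
    parameters <- intersect(parameters, colnames(results))
    do.call(rbind, lapply(parameters, function(pn) {
        v <- res[[pn]]; v <- v[is.finite(v)]
        data.frame(parameter = pn, mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0, n = length(v))
    }))
}
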