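#' @import methods
#' @importFrom stats median sd setNames rnorm runif uniroot var aov anova TukeyHSD
#' @importFrom utils read.csv write.csv
NULL

#' Vacuum permittivity (F/m)
#'
#' The electric constant \eqn{\varepsilon_0} used throughout the package to
#' convert relative permittivities to absolute ones.
#'
#' @format A length-one numeric, 8.8541878128e-12 F/m.
#' @export
EPS0 <- 8.8541878128e-12

## ---------------------------------------------------------------------------
## DielectricMedium
## ---------------------------------------------------------------------------

#' Suspending medium for DEP experiments
#'
#' A lossy dielectric liquid characterized by its relative permittivity and
#' DC conductivity.  The two DEP buffers used for cell work are sucrose-based
#' low-conductivity media; the package default is a relative permittivity of
#' 78 (aqueous sucrose at room temperature) with conductivity chosen by the
#' experimenter (typically 0.04 or 0.128 S/m).
#'
#' @slot relPermittivity relative permittivity (dimensionless, > 0)
#' @slot conductivity conductivity in S/m (>= 0)
#' @name DielectricMedium-class
#' @exportClass DielectricMedium
setClass("DielectricMedium",
    representation(relPermittivity = "numeric", conductivity = "numeric"),
    prototype(relPermittivity = 78, conductivity = 0.04))

setValidity("DielectricMedium", function(object) {
    msg <- character()
    if (length(object@relPermittivity) != 1L || !is.finite(object@relPermittivity) ||
        object@relPermittivity <= 0)
        msg <- c(msg, "relPermittivity must be a single positive number")
    if (length(object@conductivity) != 1L || !is.finite(object@conductivity) ||
        object@conductivity < 0)
        msg <- c(msg, "conductivity must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' @describeIn DielectricMedium-class Constructor.
#' @param relPermittivity relative permittivity (dimensionless)
#' @param conductivity conductivity (S/m)
#' @return A \code{DielectricMedium} object.
#' @examples
#' DielectricMedium(relPermittivity = 78, conductivity = 0.04)
#' @export
DielectricMedium <- function(relPermittivity = 78, conductivity = 0.04) {
    new("DielectricMedium", relPermittivity = relPermittivity,
        conductivity = conductivity)
}

setMethod("show", "DielectricMedium", function(object) {
    cat("DielectricMedium: eps_r =", object@relPermittivity,
        ", sigma =", object@conductivity, "S/m\n")
})

## ---------------------------------------------------------------------------
## ShelledParticle
## ---------------------------------------------------------------------------

#' Single-shell model of a cell
#'
#' A cell idealized as a conductive homogeneous sphere (the cytoplasm)
#' covered by a thin, poorly conducting shell (the plasma membrane).  All
#' permittivities are relative; conversion to absolute values happens
#' internally.
#'
#' @slot radius cell radius in m
#' @slot membraneThickness shell thickness in m (\code{0 <= d < radius})
#' @slot memRelPermittivity membrane relative permittivity
#' @slot memConductivity membrane conductivity, S/m
#' @slot intRelPermittivity cytoplasm (interior) relative permittivity
#' @slot intConductivity cytoplasm conductivity, S/m
#' @name ShelledParticle-class
#' @exportClass ShelledParticle
setClass("ShelledParticle",
    representation(radius = "numeric", membraneThickness = "numeric",
        memRelPermittivity = "numeric", memConductivity = "numeric",
        intRelPermittivity = "numeric", intConductivity = "numeric"))

setValidity("ShelledParticle", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && is.finite(x)
    if (!one(object@radius) || object@radius <= 0)
        msg <- c(msg, "radius must be a single positive number")
    if (!one(object@membraneThickness) || object@membraneThickness < 0)
        msg <- c(msg, "membraneThickness must be a single non-negative number")
    if (one(object@radius) && one(object@membraneThickness) &&
        object@membraneThickness >= object@radius)
        msg <- c(msg, "membraneThickness must be smaller than radius")
    for (s in c("memRelPermittivity", "intRelPermittivity")) {
        v <- slot(object, s)
        if (!one(v) || v <= 0) msg <- c(msg, paste(s, "must be positive"))
    }
    for (s in c("memConductivity", "intConductivity")) {
        v <- slot(object, s)
        if (!one(v) || v < 0) msg <- c(msg, paste(s, "must be non-negative"))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ShelledParticle-class Constructor.
#' @param radius cell radius (m)
#' @param membraneThickness membrane thickness (m); default 5 nm
#' @param memRelPermittivity membrane relative permittivity
#' @param memConductivity membrane conductivity (S/m)
#' @param intRelPermittivity interior relative permittivity
#' @param intConductivity interior conductivity (S/m)
#' @return A \code{ShelledParticle} object.
#' @examples
#' ShelledParticle(radius = 9e-6, memRelPermittivity = 9,
#'                 memConductivity = 1e-6, intConductivity = 0.4)
#' @export
ShelledParticle <- function(radius, membraneThickness = 5e-9,
                            memRelPermittivity, memConductivity,
                            intRelPermittivity = 60, intConductivity) {
    new("ShelledParticle", radius = radius,
        membraneThickness = membraneThickness,
        memRelPermittivity = memRelPermittivity,
        memConductivity = memConductivity,
        intRelPermittivity = intRelPermittivity,
        intConductivity = intConductivity)
}

setMethod("show", "ShelledParticle", function(object) {
    cat("ShelledParticle (single-shell cell model)\n")
    cat(sprintf("  r = %.3g um, d = %.3g nm\n", object@radius * 1e6,
        object@membraneThickness * 1e9))
    cat(sprintf("  membrane: eps_r = %.4g, sigma = %.3g S/m\n",
        object@memRelPermittivity, object@memConductivity))
    cat(sprintf("  interior: eps_r = %.4g, sigma = %.3g S/m\n",
        object@intRelPermittivity, object@intConductivity))
})

## ---------------------------------------------------------------------------
## PopulationModel
## ---------------------------------------------------------------------------

#' Parameter distribution of a cell population
#'
#' Describes the between-cell variability of a population for the four
#' parameters that differ between cells (radius, membrane permittivity and
#' conductivity, cytoplasm conductivity).  Membrane thickness and interior
#' permittivity are treated as fixed.  Individual cells are drawn with each
#' parameter independent and, by default, uniform on
#' \code{[mean - sd, mean + sd]} (a Gaussian option is available).
#'
#' @slot label free-text population label (e.g. "MSC", "osteo_w1")
#' @slot radiusMean,radiusSD radius mean and spread (m)
#' @slot memPermMean,memPermSD membrane relative permittivity mean and spread
#' @slot memCondMean,memCondSD membrane conductivity mean and spread (S/m)
#' @slot intCondMean,intCondSD cytoplasm conductivity mean and spread (S/m)
#' @slot membraneThickness fixed membrane thickness (m)
#' @slot intRelPermittivity fixed interior relative permittivity
#' @slot distribution "uniform" (on mean +/- sd) or "gaussian"
#' @name PopulationModel-class
#' @exportClass PopulationModel
setClass("PopulationModel",
    representation(label = "character",
        radiusMean = "numeric", radiusSD = "numeric",
        memPermMean = "numeric", memPermSD = "numeric",
        memCondMean = "numeric", memCondSD = "numeric",
        intCondMean = "numeric", intCondSD = "numeric",
        membraneThickness = "numeric", intRelPermittivity = "numeric",
        distribution = "character"))

setValidity("PopulationModel", function(object) {
    msg <- character()
    sds <- c(object@radiusSD, object@memPermSD, object@memCondSD, object@intCondSD)
    if (any(!is.finite(sds)) || any(sds < 0))
        msg <- c(msg, "all SDs must be finite and >= 0")
    if (!object@distribution %in% c("uniform", "gaussian"))
        msg <- c(msg, "distribution must be 'uniform' or 'gaussian'")
    mp <- try(meanParticle(object), silent = TRUE)
    if (inherits(mp, "try-error"))
        msg <- c(msg, "population means do not define a valid ShelledParticle")
    if (length(msg)) msg else TRUE
})

#' @describeIn PopulationModel-class Constructor.
#' @param label population label
#' @param radiusMean,radiusSD radius mean / spread (m)
#' @param memPermMean,memPermSD membrane relative permittivity mean / spread
#' @param memCondMean,memCondSD membrane conductivity mean / spread (S/m)
#' @param intCondMean,intCondSD cytoplasm conductivity mean / spread (S/m)
#' @param membraneThickness fixed membrane thickness (m)
#' @param intRelPermittivity fixed interior relative permittivity
#' @param distribution "uniform" or "gaussian"
#' @return A \code{PopulationModel} object.
#' @export
PopulationModel <- function(label, radiusMean, radiusSD = 0,
                            memPermMean, memPermSD = 0,
                            memCondMean, memCondSD = 0,
                            intCondMean, intCondSD = 0,
                            membraneThickness = 5e-9,
                            intRelPermittivity = 60,
                            distribution = "uniform") {
    new("PopulationModel", label = label,
        radiusMean = radiusMean, radiusSD = radiusSD,
        memPermMean = memPermMean, memPermSD = memPermSD,
        memCondMean = memCondMean, memCondSD = memCondSD,
        intCondMean = intCondMean, intCondSD = intCondSD,
        membraneThickness = membraneThickness,
        intRelPermittivity = intRelPermittivity,
        distribution = distribution)
}

setMethod("show", "PopulationModel", function(object) {
    cat("PopulationModel:", object@label, "(", object@distribution, ")\n")
    cat(sprintf("  radius   %.3g +/- %.3g um\n", object@radiusMean * 1e6,
        object@radiusSD * 1e6))
    cat(sprintf("  eps_mem  %.3g +/- %.3g\n", object@memPermMean, object@memPermSD))
    cat(sprintf("  sig_mem  %.3g +/- %.3g S/m\n", object@memCondMean, object@memCondSD))
    cat(sprintf("  sig_int  %.3g +/- %.3g S/m\n", object@intCondMean, object@intCondSD))
})

#' Mean particle of a population
#'
#' @param model a \code{\linkS4class{PopulationModel}}
#' @return The \code{\linkS4class{ShelledParticle}} at the population means.
#' @export
meanParticle <- function(model) {
    ShelledParticle(radius = model@radiusMean,
        membraneThickness = model@membraneThickness,
        memRelPermittivity = model@memPermMean,
        memConductivity = model@memCondMean,
        intRelPermittivity = model@intRelPermittivity,
        intConductivity = model@intCondMean)
}
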