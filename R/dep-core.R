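## Single-shell DEP physics: complex permittivities, Clausius-Mossotti factor,
## DEP force and crossover-frequency root finding.

#' Complex absolute permittivity of a lossy dielectric
#'
#' Evaluates \eqn{\varepsilon^*(f) = \varepsilon_0 \varepsilon_r -
#' j\sigma/(2\pi f)}, the standard complex permittivity of a material with
#' relative permittivity \eqn{\varepsilon_r} and conductivity \eqn{\sigma}
#' in an AC field of frequency \eqn{f}.
#'
#' @param relPermittivity relative permittivity (dimensionless, > 0)
#' @param conductivity conductivity (S/m, >= 0)
#' @param f AC field frequency in Hz; may be a vector, all values > 0
#' @return Complex absolute permittivity (F/m), same length as \code{f}.
#' @examples
#' complexPermittivity(80, 0.04, 1e4)
#' @export
complexPermittivity <- function(relPermittivity, conductivity, f) {
    if (any(!is.finite(f)) || any(f <= 0))
        stop("frequency must be finite and positive")
    EPS0 * relPermittivity - 1i * conductivity / (2 * pi * f)
}

## Internal fully-numeric kernel shared by the S4 surface and the fitter.
## Vectorized over f; all permittivities relative on input.
.equivPermittivity <- function(f, r, d, epsMem, sigMem, epsInt, sigInt) {
    em <- complexPermittivity(epsMem, sigMem, f)
    if (d == 0) return(complexPermittivity(epsInt, sigInt, f))
    ei <- complexPermittivity(epsInt, sigInt, f)
    g <- (r / (r - d))^3
    k <- (ei - em) / (ei + 2 * em)
    em * (g + 2 * k) / (g - k)
}

.cmFactor <- function(f, r, d, epsMem, sigMem, epsInt, sigInt, epsMed, sigMed) {
    ep <- .equivPermittivity(f, r, d, epsMem, sigMem, epsInt, sigInt)
    emed <- complexPermittivity(epsMed, sigMed, f)
    den <- ep + 2 * emed
    if (any(Mod(den) < 1e3 * .Machine$double.eps * EPS0))
        stop("degenerate input: Clausius-Mossotti denominator vanishes")
    (ep - emed) / den
}

.reCM <- function(f, r, d, epsMem, sigMem, epsInt, sigInt, epsMed, sigMed) {
    Re(.cmFactor(f, r, d, epsMem, sigMem, epsInt, sigInt, epsMed, sigMed))
}

.particleArgs <- function(p) {
    list(r = p@radius, d = p@membraneThickness,
         epsMem = p@memRelPermittivity, sigMem = p@memConductivity,
         epsInt = p@intRelPermittivity, sigInt = p@intConductivity)
}

#' Equivalent complex permittivity of a shelled particle
#'
#' Collapses the core-plus-shell geometry of the single-shell cell model into
#' the complex permittivity of an equivalent homogeneous sphere.  With shell
#' thickness zero the interior permittivity is returned unchanged.
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param f frequency in Hz (vectorized)
#' @return Complex absolute permittivity (F/m) of the equivalent sphere.
#' @export
particlePermittivity <- function(particle, f) {
    validObject(particle)
    a <- .particleArgs(particle)
    .equivPermittivity(f, a$r, a$d, a$epsMem, a$sigMem, a$epsInt, a$sigInt)
}

#' Clausius-Mossotti factor of a cell in a medium
#'
#' The complex, frequency-dependent polarizability contrast
#' \eqn{K(f) = (\varepsilon_p^* - \varepsilon_{med}^*) /
#' (\varepsilon_p^* + 2\varepsilon_{med}^*)} between the equivalent particle
#' permittivity and the suspending medium.  For physical (passive) materials
#' its real part lies in \eqn{[-0.5, 1]}; its sign sets the direction of the
#' DEP force (positive DEP towards field maxima, negative away from them).
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param f frequency in Hz (vectorized)
#' @return Complex dimensionless Clausius-Mossotti factor.
#' @examples
#' p <- ShelledParticle(radius = 9e-6, memRelPermittivity = 9,
#'                      memConductivity = 1e-6, intConductivity = 0.4)
#' Re(clausiusMossotti(p, DielectricMedium(78, 0.04), 1e6))
#' @export
clausiusMossotti <- function(particle, medium, f) {
    validObject(particle); validObject(medium)
    a <- .particleArgs(particle)
    .cmFactor(f, a$r, a$d, a$epsMem, a$sigMem, a$epsInt, a$sigInt,
              medium@relPermittivity, medium@conductivity)
}

#' DEP spectrum of a cell: Re[K(f)] over a frequency grid
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param frequencies strictly increasing positive frequencies (Hz)
#' @return Numeric vector of \eqn{Re[K(f)]}, one value per frequency.
#' @export
reCMSpectrum <- function(particle, medium, frequencies) {
    .checkGrid(frequencies)
    Re(clausiusMossotti(particle, medium, frequencies))
}

.checkGrid <- function(frequencies) {
    if (length(frequencies) < 1L || any(!is.finite(frequencies)) ||
        any(frequencies <= 0))
        stop("frequency grid must contain finite positive values")
    if (is.unsorted(frequencies, strictly = TRUE))
        stop("frequency grid must be strictly increasing")
    invisible(frequencies)
}

#' Time-averaged DEP force on a spherical particle
#'
#' \eqn{F = 2\pi r^3 \varepsilon_0 \varepsilon_{med} Re[K(f)] \nabla|E|^2};
#' the sign follows \eqn{Re[K]}.
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param f frequency in Hz
#' @param gradE2 gradient of the squared field magnitude (V^2/m^3)
#' @return Force in newtons (signed, along the gradient direction).
#' @export
depForceMagnitude <- function(particle, medium, f, gradE2) {
    if (any(!is.finite(gradE2))) stop("gradE2 must be finite")
    k <- Re(clausiusMossotti(particle, medium, f))
    2 * pi * particle@radius^3 * EPS0 * medium@relPermittivity * k * gradE2
}

#' Crossover frequencies of a DEP spectrum
#'
#' Finds all frequencies in \code{[fMin, fMax]} at which \eqn{Re[K(f)] = 0}
#' (and with it the DEP force).  A dense logarithmic scan brackets sign
#' changes which are then refined by Brent's method; roots closer than 1e-6
#' relative are merged.  The first crossover is governed mainly by membrane
#' properties and medium conductivity, the second by the cytoplasm.
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param fMin,fMax search range in Hz; defaults to the 3DEP instrument
#'   range 10 kHz - 50 MHz
#' @param pointsPerDecade density of the bracketing scan (default 2000)
#' @return Increasing numeric vector of crossover frequencies in Hz
#'   (possibly empty); each satisfies \eqn{|Re[K]| < 10^{-9}}.
#' @examples
#' p <- ShelledParticle(radius = 9e-6, memRelPermittivity = 9,
#'                      memConductivity = 1e-6, intConductivity = 0.4)
#' crossoverFrequencies(p, DielectricMedium(78, 0.04))
#' @export
crossoverFrequencies <- function(particle, medium, fMin = 1e4, fMax = 5e7,
                                 pointsPerDecade = 2000) {
    if (!(fMin > 0) || !(fMax > fMin)) stop("need 0 < fMin < fMax")
    a <- .particleArgs(particle)
    g <- function(u) .reCM(10^u, a$r, a$d, a$epsMem, a$sigMem, a$epsInt,
                           a$sigInt, medium@relPermittivity, medium@conductivity)
    u1 <- log10(fMin); u2 <- log10(fMax)
    n <- max(16L, ceiling((u2 - u1) * pointsPerDecade))
    us <- seq(u1, u2, length.out = n + 1L)
    vals <- g(us)
    roots <- us[vals == 0]
    flips <- which(vals[-1] * vals[-length(vals)] < 0)
    for (i in flips) {
        rt <- uniroot(g, lower = us[i], upper = us[i + 1L],
                      f.lower = vals[i], f.upper = vals[i + 1L],
                      tol = 1e-13, maxiter = 2000L)
        roots <- c(roots, rt$root)
    }
    if (!length(roots)) return(numeric(0))
    f <- sort(10^roots)
    # merge near-duplicates (relative spacing < 1e-6)
    keep <- c(TRUE, diff(f) / f[-length(f)] > 1e-6)
    f[keep]
}
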