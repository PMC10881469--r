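## Particle tracing under Stokes drag + DEP drift, outlet assignment, and
## purity/yield bookkeeping for the 2D sorter model.

#' DEP mobility of a cell
#'
#' Quasi-steady (inertialess) balance of the DEP force against Stokes drag
#' gives a drift velocity \eqn{v = \mu \nabla|E|^2} with mobility
#' \eqn{\mu = r^2 \varepsilon_0 \varepsilon_{med} Re[K(f)] / (3\eta)}.
#' The sign of \eqn{\mu} follows \eqn{Re[K]}; at a crossover frequency the
#' mobility (and the DEP force) vanishes.
#'
#' @param particle a \code{\linkS4class{ShelledParticle}}
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param f operating frequency (Hz)
#' @param viscosity dynamic viscosity of the buffer (Pa s, > 0)
#' @return Mobility in m^4 V^-2 s^-1.
#' @export
depMobility <- function(particle, medium, f, viscosity = 1e-3) {
    if (!(viscosity > 0)) stop("viscosity must be positive")
    k <- Re(clausiusMossotti(particle, medium, f))
    particle@radius^2 * EPS0 * medium@relPermittivity * k / (3 * viscosity)
}

#' Choose the sorter operating frequency for two populations
#'
#' Returns the first crossover frequency of population A's mean cell, after
#' verifying that population B's mean cell experiences positive DEP there
#' (the condition for B to be deflected while A passes undisturbed).  When
#' B is not positive at the candidate frequency an error suggests swapping
#' the population roles.
#'
#' @param popA population whose crossover sets the frequency (these cells
#'   feel no force and exit through the right outlet)
#' @param popB population to be deflected (must be in positive DEP at the
#'   operating frequency)
#' @param medium a \code{\linkS4class{DielectricMedium}}
#' @param fMin,fMax crossover search range (Hz)
#' @return Operating frequency in Hz.
#' @examples
#' chooseOperatingFrequency(differentiatedPopulation(), mscPopulation(),
#'                          DielectricMedium(78, 0.04))
#' @export
chooseOperatingFrequency <- function(popA, popB, medium,
                                     fMin = 1e4, fMax = 5e7) {
    co <- crossoverFrequencies(meanParticle(popA), medium, fMin, fMax)
    if (!length(co))
        stop("population '", popA@label,
             "' has no crossover frequency in the search range")
    f <- co[1]
    kB <- Re(clausiusMossotti(meanParticle(popB), medium, f))
    if (!(kB > 0))
        stop(sprintf(paste0(
            "population '%s' is not in positive DEP at %.4g Hz ",
            "(Re[K] = %.3g); consider swapping the population roles"),
            popB@label, f, kB))
    f
}

#' Trace particles through the sorter
#'
#' Explicit midpoint (RK2) integration of
#' \eqn{dx/dt = u_{fluid}(x) + \mu \nabla|E|^2(x)} with bilinear field
#' interpolation.  The shared time step is capped adaptively so no particle
#' moves more than \code{cfl} grid cells per step.  A particle exits when
#' its axial position passes the channel end and is assigned to the left
#' outlet if its lateral position is below the split coordinate, else to
#' the right; particles still inside at \code{maxTime} are recorded as
#' \code{"none"}.  Particles pushed into a wall are clamped to it and
#' continue axially (the count is reported in the attribute
#' \code{"nWallContacts"}).
#'
#' @param particles data.frame with one row per particle: columns
#'   \code{id}, \code{population}, \code{entry_y} (m) and \code{mobility}
#'   (m^4 V^-2 s^-1)
#' @param geom a \code{\linkS4class{DeviceGeometry}}
#' @param flow fluid \code{\linkS4class{VectorField2D}}
#' @param gradE2 \code{\linkS4class{VectorField2D}} of \eqn{\nabla|E|^2}
#' @param maxTime integration horizon (s)
#' @param cfl per-step displacement cap in grid cells (default 0.5)
#' @return data.frame per particle: \code{id}, \code{population},
#'   \code{entry_y}, \code{outlet} ("left", "right" or "none"),
#'   \code{exit_y}, \code{transit_time}.
#' @export
advectParticles <- function(particles, geom, flow, gradE2,
                            maxTime = 30, cfl = 0.5) {
    stopifnot(all(c("id", "population", "entry_y", "mobility") %in%
                  names(particles)))
    n <- nrow(particles)
    px <- rep(0, n); py <- particles$entry_y
    if (any(py < 0 | py > geom@width))
        stop("entry positions must lie inside the channel")
    mob <- particles$mobility
    active <- rep(TRUE, n)
    exitY <- rep(NA_real_, n); exitT <- rep(NA_real_, n)
    hmin <- min(flow@x[2] - flow@x[1], flow@y[2] - flow@y[1])
    wallContacts <- 0L
    t <- 0
    vel <- function(x, y) {
        ux <- .bilinear(flow@x, flow@y, flow@vx, x, y)
        uy <- .bilinear(flow@x, flow@y, flow@vy, x, y)
        gx <- .bilinear(gradE2@x, gradE2@y, gradE2@vx, x, y)
        gy <- .bilinear(gradE2@x, gradE2@y, gradE2@vy, x, y)
        m <- mob[active]
        list(vx = ux + m * gx, vy = uy + m * gy)
    }
    while (any(active) && t < maxTime) {
        v1 <- vel(px[active], py[active])
        vmax <- max(sqrt(v1$vx^2 + v1$vy^2), 1e-12)
        dt <- min(cfl * hmin / vmax, maxTime - t)
        ## midpoint stage
        mx <- px[active] + 0.5 * dt * v1$vx
        my <- pmin(pmax(py[active] + 0.5 * dt * v1$vy, 0), geom@width)
        mx <- pmin(mx, geom@length)
        v2 <- vel(mx, my)
        nxp <- px[active] + dt * v2$vx
        nyp <- py[active] + dt * v2$vy
        hitWall <- nyp < 0 | nyp > geom@width
        wallContacts <- wallContacts + sum(hitWall)
        nyp <- pmin(pmax(nyp, 0), geom@width)
        px[active] <- nxp; py[active] <- nyp
        t <- t + dt
        out <- active & px >= geom@length
        if (any(out)) {
            exitY[out] <- py[out]
            exitT[out] <- t
            active[out] <- FALSE
        }
    }
    outlet <- ifelse(is.na(exitY), "none",
                     ifelse(exitY < geom@split, "left", "right"))
    res <- data.frame(id = particles$id, population = particles$population,
        entry_y = particles$entry_y, outlet = outlet,
        exit_y = exitY, transit_time = exitT,
        stringsAsFactors = FALSE)
    attr(res, "nWallContacts") <- wallContacts
    res
}

#' Purity and yield of a separation outcome
#'
#' Purity: percentage of particles at \code{targetOutlet} that belong to
#' \code{targetPop}.  Yield: percentage of all \code{targetPop} particles
#' recovered at \code{targetOutlet}.
#'
#' @param outcome result of \code{\link{advectParticles}}
#' @param targetPop population label
#' @param targetOutlet "left" or "right"
#' @return Named numeric: \code{purity}, \code{yield} (both in percent).
#' @export
purityYield <- function(outcome, targetPop, targetOutlet = c("left", "right")) {
    targetOutlet <- match.arg(targetOutlet)
    atOutlet <- outcome$outlet == targetOutlet
    if (!any(atOutlet))
        stop("no particle reached the ", targetOutlet,
             " outlet; purity undefined")
    isPop <- outcome$population == targetPop
    c(purity = 100 * sum(atOutlet & isPop) / sum(atOutlet),
      yield = 100 * sum(atOutlet & isPop) / sum(isPop))
}

#' Run a two-population DEP separation
#'
#' End-to-end sorter run: solve the electrode potential, derive
#' \eqn{\nabla|E|^2} and the laminar flow, draw individual cells from both
#' populations (parameters uniform within one SD of the population means),
#' compute each cell's DEP mobility at the operating frequency, inject the
#' cells at seeded random lateral positions within the right-side entry
#' band, trace them through the channel, and tabulate outlet purity and
#' yield.  Population A is the one whose mean-cell crossover sets the
#' operating frequency (these cells exit right); population B is deflected
#' to the left outlet by positive DEP.
#'
#' @param popA,popB \code{\linkS4class{PopulationModel}} objects (see above
#'   for the roles)
#' @param medium a \code{\linkS4class{DielectricMedium}}; default the
#'   0.04 S/m sorting buffer
#' @param nPerPop particles per population
#' @param geom a \code{\linkS4class{DeviceGeometry}}
#' @param vRms phase-electrode voltage (V RMS)
#' @param meanSpeed mean flow speed (m/s); the default 2 mm/s places the
#'   deflection threshold between the two populations' \eqn{|Re[K]|}
#' @param frequency operating frequency (Hz) or \code{"auto"} for
#'   \code{\link{chooseOperatingFrequency}}
#' @param viscosity buffer viscosity (Pa s)
#' @param nx,ny field grid resolution
#' @param seed integer seed for cell draws and entry positions
#' @param maxTime integration horizon (s)
#' @param cfl time-step cap in grid cells per step
#' @param smooth finite-particle-size field averaging half-width (m);
#'   defaults to the mean cell radius of the two populations
#' @return List with \code{frequency}, \code{outcome} (per-particle
#'   data.frame), \code{summary} (purity/yield per outlet) and the fields
#'   (\code{potential}, \code{gradE2}, \code{flow}).
#' @export
runSeparation <- function(popA, popB, medium = DielectricMedium(78, 0.04),
                          nPerPop = 200L, geom = defaultDeviceGeometry(),
                          vRms = 10, meanSpeed = 2e-3, frequency = "auto",
                          viscosity = 1e-3, nx = 501L, ny = 61L,
                          seed = 1L, maxTime = 30, cfl = 0.5,
                          smooth = (popA@radiusMean + popB@radiusMean) / 2) {
    f <- if (identical(frequency, "auto"))
        chooseOperatingFrequency(popA, popB, medium) else frequency
    V <- solvePotential(geom, nx, ny, vRms)
    G <- gradE2Field(V, smooth = smooth)
    U <- flowField(geom, meanSpeed, nx, ny)
    tabA <- .sampleParamTable(popA, nPerPop, seed)
    tabB <- .sampleParamTable(popB, nPerPop, seed + 1L)
    mobOf <- function(tab, model) {
        vapply(seq_len(nrow(tab)), function(i) {
            p <- ShelledParticle(radius = tab$radius[i],
                membraneThickness = model@membraneThickness,
                memRelPermittivity = tab$memPerm[i],
                memConductivity = tab$memCond[i],
                intRelPermittivity = model@intRelPermittivity,
                intConductivity = tab$intCond[i])
            depMobility(p, medium, f, viscosity)
        }, numeric(1))
    }
    n2 <- 2L * nPerPop
    entry <- .withSeed(seed + 2L, function()
        geom@width * runif(n2, geom@inletBand[1], geom@inletBand[2]))
    particles <- data.frame(
        id = seq_len(n2),
        population = rep(c(popA@label, popB@label), each = nPerPop),
        entry_y = entry,
        mobility = c(mobOf(tabA, popA), mobOf(tabB, popB)),
        stringsAsFactors = FALSE)
    outcome <- advectParticles(particles, geom, U, G,
                               maxTime = maxTime, cfl = cfl)
    pyOrNA <- function(pop, outlet) {
        tryCatch(purityYield(outcome, pop, outlet),
                 error = function(e) c(purity = NA_real_, yield = NA_real_))
    }
    summ <- rbind(
        data.frame(outlet = "right", target = popA@label,
            t(pyOrNA(popA@label, "right"))),
        data.frame(outlet = "left", target = popB@label,
            t(pyOrNA(popB@label, "left"))))
    list(frequency = f, outcome = outcome, summary = summ,
         potential = V, gradE2 = G, flow = U)
}
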