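# 2D sorter model: Laplace solve, derived fields, laminar flow, DEP
# mobility, particle tracing and outcome bookkeeping.

plateGeometry <- function(xa = 1e-3, xb = 4e-3, L = 5e-3, w = 5e-4) {
    DeviceGeometry(length = L, width = w, electrodes = list(
        list(role = "phase", x = c(xa, xa), y = c(0, w), halfWidth = 1e-5),
        list(role = "neutral", x = c(xb, xb), y = c(0, w), halfWidth = 1e-5)))
}

test_that("potential between parallel plate electrodes is the linear ramp", {
    geom <- plateGeometry()
    V <- solvePotential(geom, nx = 251L, ny = 51L, vRms = 10)
    x <- V@x
    ia <- which.min(abs(x - 1e-3)); ib <- which.min(abs(x - 4e-3))
    ramp <- 10 * (x[ib] - x) / (x[ib] - x[ia])
    inner <- (ia + 1):(ib - 1)
    err <- abs(V@values[inner, ] - ramp[inner])
    expect_lt(max(err) / 10, 1e-6)
    # outside the plates (Neumann ends): constant at the plate value
    expect_lt(max(abs(V@values[1:(ia - 1), ] - 10)) / 10, 1e-6)
    expect_lt(max(abs(V@values[(ib + 1):length(x), ])) / 10, 1e-6)
})

test_that("the Laplace solve is linear in the applied voltage", {
    geom <- plateGeometry()
    V1 <- solvePotential(geom, nx = 101L, ny = 51L, vRms = 10)
    V2 <- solvePotential(geom, nx = 101L, ny = 51L, vRms = 20)
    expect_equal(V2@values, 2 * V1@values, tolerance = 1e-10)

    # all electrodes grounded: identically zero everywhere
    geo0 <- DeviceGeometry(length = 5e-3, width = 5e-4, electrodes = list(
        list(role = "neutral", x = c(1e-3, 1e-3), y = c(0, 5e-4), halfWidth = 1e-5),
        list(role = "neutral", x = c(4e-3, 4e-3), y = c(0, 5e-4), halfWidth = 1e-5)))
    V0 <- solvePotential(geo0, nx = 101L, ny = 51L, vRms = 10)
    expect_equal(max(abs(V0@values)), 0)
    e2 <- fieldIntensity(V0)
    expect_equal(max(abs(e2@values)), 0)

    expect_error(solvePotential(plateGeometry(), nx = 101L, ny = 20L), "50")
    expect_error(solvePotential(DeviceGeometry(5e-3, 5e-4, list()),
                                101L, 51L), "no electrode")
})

test_that("grad |E|^2 matches the symbolic oracle for a quadratic potential", {
    x <- seq(0, 1e-3, length.out = 101)
    y <- seq(0, 5e-4, length.out = 51)
    V <- new("ScalarField2D", x = x, y = y,
             values = outer(x, rep(1, 51)) ^ 2)   # V = x^2
    e2 <- fieldIntensity(V)
    inner <- 2:100
    expect_equal(e2@values[inner, ], outer(4 * x[inner]^2, rep(1, 51)),
                 tolerance = 1e-10)
    G <- gradE2Field(V, smooth = 0)
    gInner <- 3:99   # nodes untouched by the one-sided boundary stencil
    expect_equal(G@vx[gInner, ], outer(8 * x[gInner], rep(1, 51)),
                 tolerance = 1e-10)
    expect_equal(max(abs(G@vy)), 0, tolerance = 1e-20)

    # finite-size averaging leaves the interior gradient of a quadratic
    # intensity unchanged
    Gs <- gradE2Field(V, smooth = 3e-5)
    far <- 8:94
    expect_equal(Gs@vx[far, 10:40], G@vx[far, 10:40], tolerance = 1e-8)

    # uniform-field region: gradient vanishes
    Vlin <- new("ScalarField2D", x = x, y = y,
                values = outer(x, rep(1, 51)))
    Glin <- gradE2Field(Vlin, smooth = 0)
    expect_equal(max(abs(Glin@vx)), 0, tolerance = 1e-12)
})

test_that("field intensity peaks along the diagonal electrode gap", {
    geom <- defaultDeviceGeometry()
    V <- solvePotential(geom, nx = 251L, ny = 61L, vRms = 10)
    e2 <- fieldIntensity(V)@values
    # the lateral position of the row-wise maximum tracks the descending
    # diagonal in the electrode region
    x <- V@x; y <- V@y
    # the high-intensity locus hugs the oblique electrode gap: every node
    # in the top 3% of |E|^2 lies within the diagonal band, and the locus
    # descends from the right wall towards the left wall
    X <- matrix(x, length(x), length(y))
    Y <- matrix(y, length(x), length(y), byrow = TRUE)
    hot <- e2 >= quantile(e2, 0.97)
    x0 <- 0.1 * geom@length; x1 <- 0.9 * geom@length
    offset <- abs(Y[hot] - geom@width * (x1 - X[hot]) / (x1 - x0))
    expect_lt(max(offset), 2.5e-4)                  # inside the gap band
    expect_lt(cor(X[hot], Y[hot]), -0.8)            # moves left downstream
    expect_gt(max(Y[hot]) - min(Y[hot]), 2e-4)      # spans the channel
})

test_that("laminar profile has the parabolic invariants", {
    geom <- defaultDeviceGeometry()
    U <- flowField(geom, meanSpeed = 2e-3, nx = 51L, ny = 201L)
    prof <- U@vx[1, ]
    expect_equal(max(prof), 1.5 * 2e-3, tolerance = 1e-12)
    expect_equal(prof[1], 0)
    expect_equal(prof[201], 0)
    expect_equal(max(abs(U@vy)), 0)
    # cross-section average equals the mean speed (trapezoid, fine grid)
    y <- U@y
    avg <- sum((prof[-1] + prof[-201]) / 2 * diff(y)) / geom@width
    expect_lt(abs(avg - 2e-3) / 2e-3, 1e-3)
    expect_error(flowField(geom, 0), "positive")
})

test_that("DEP mobility balances the DEP force against Stokes drag", {
    f <- 1e6; eta <- 1e-3; G <- 3.7e13
    mu <- depMobility(mscCell, sortBuffer, f, eta)
    expect_equal(6 * pi * eta * mscCell@radius * mu * G,
                 depForceMagnitude(mscCell, sortBuffer, f, G),
                 tolerance = 1e-12)
    # sign follows Re[K]; zero at the crossover
    co1 <- crossoverFrequencies(mscCell, sortBuffer)[1]
    expect_lt(abs(depMobility(mscCell, sortBuffer, co1)), 1e-27)
    expect_lt(depMobility(mscCell, sortBuffer, 1e4), 0)
    expect_gt(depMobility(mscCell, sortBuffer, 1e6), 0)
})

test_that("operating-frequency selection enforces the pDEP contract", {
    f <- chooseOperatingFrequency(differentiatedPopulation(), mscPopulation(),
                                  sortBuffer)
    # frequency is the deflected-free population's first crossover ...
    co <- crossoverFrequencies(meanParticle(differentiatedPopulation()),
                               sortBuffer)
    expect_equal(f, co[1])
    # ... and the other population is in positive DEP there
    expect_gt(Re(clausiusMossotti(meanParticle(mscPopulation()),
                                  sortBuffer, f)), 0)
    # identical populations cannot be separated
    expect_error(chooseOperatingFrequency(mscPopulation(), mscPopulation(),
                                          sortBuffer), "positive DEP")
    # swapped roles: MSC's crossover leaves the differentiated cells in
    # negative DEP, which the contract refuses with a role-swap hint
    expect_error(chooseOperatingFrequency(mscPopulation(),
        differentiatedPopulation(), sortBuffer), "swapping")
})

test_that("with the field off every particle is a passive tracer", {
    geom <- defaultDeviceGeometry()
    V <- solvePotential(geom, nx = 251L, ny = 61L, vRms = 0)
    G <- gradE2Field(V)
    U <- flowField(geom, 2e-3, 251L, 61L)
    entry <- c(0.72, 0.80, 0.88, 0.94) * geom@width
    parts <- data.frame(id = 1:4, population = "m", entry_y = entry,
                        mobility = 4.5e-18)
    out <- advectParticles(parts, geom, U, G, maxTime = 30)
    expect_equal(out$exit_y, entry, tolerance = 1e-12)
    expect_true(all(out$outlet == "right"))
})

test_that("particles at their crossover follow tracer trajectories", {
    geom <- defaultDeviceGeometry()
    V <- solvePotential(geom, nx = 251L, ny = 61L, vRms = 10)
    G <- gradE2Field(V)
    U <- flowField(geom, 2e-3, 251L, 61L)
    co1 <- crossoverFrequencies(mscCell, sortBuffer)[1]
    muCo <- depMobility(mscCell, sortBuffer, co1)   # ~0, not exactly 0
    entry <- c(0.75, 0.85, 0.93) * geom@width
    tracer <- advectParticles(data.frame(id = 1:3, population = "m",
        entry_y = entry, mobility = 0), geom, U, G)
    atCo <- advectParticles(data.frame(id = 1:3, population = "m",
        entry_y = entry, mobility = muCo), geom, U, G)
    expect_lt(max(abs(atCo$exit_y - tracer$exit_y)), 1e-9 * geom@width)
})

test_that("halving the time step barely moves the exit positions", {
    geom <- defaultDeviceGeometry()
    V <- solvePotential(geom, nx = 251L, ny = 61L, vRms = 10)
    G <- gradE2Field(V)
    U <- flowField(geom, 2e-3, 251L, 61L)
    parts <- data.frame(id = 1:6, population = "m",
        entry_y = rep(c(0.75, 0.9), 3) * geom@width,
        mobility = rep(c(0.5e-18, 1e-18, 4.5e-18), each = 2))
    a <- advectParticles(parts, geom, U, G, cfl = 0.5)
    b <- advectParticles(parts, geom, U, G, cfl = 0.25)
    expect_lt(max(abs(a$exit_y - b$exit_y)), 0.01 * geom@width)
})

test_that("outcome bookkeeping conserves particles and computes purity/yield", {
    out <- data.frame(id = 1:6, population = c("a", "a", "a", "b", "b", "b"),
        entry_y = 0, outlet = c("left", "left", "right", "right", "right", "none"),
        exit_y = 0, transit_time = 1)
    expect_equal(sum(out$outlet == "left") + sum(out$outlet == "right") +
                 sum(out$outlet == "none"), 6L)
    pa <- purityYield(out, "a", "left")
    expect_equal(unname(pa["purity"]), 100)
    expect_equal(unname(pa["yield"]), 2 / 3 * 100)
    pb <- purityYield(out, "b", "right")
    expect_equal(unname(pb["purity"]), 2 / 3 * 100)
    expect_error(purityYield(out[out$outlet == "left", ], "a", "right"),
                 "purity undefined")
    # single population, single outlet: 100/100
    solo <- data.frame(id = 1:3, population = "a", entry_y = 0,
        outlet = "left", exit_y = 0, transit_time = 1)
    expect_equal(unname(purityYield(solo, "a", "left")), c(100, 100))
})

test_that("a field-off separation returns the input mixture at the right outlet", {
    res <- runSeparation(differentiatedPopulation(), mscPopulation(),
        sortBuffer, nPerPop = 20L, vRms = 0, nx = 251L, ny = 61L, seed = 4)
    expect_true(all(res$outcome$outlet == "right"))
    py <- purityYield(res$outcome, "diff_w1", "right")
    expect_equal(unname(py["purity"]), 50)   # 20 of 40
    expect_equal(unname(py["yield"]), 100)
    # left outlet empty: summary reports NA rather than failing
    expect_true(is.na(res$summary$purity[res$summary$outlet == "left"]))
})

test_that("separation runs are reproducible for a fixed seed", {
    a <- runSeparation(differentiatedPopulation(), mscPopulation(),
        sortBuffer, nPerPop = 10L, nx = 251L, ny = 61L, seed = 6)
    b <- runSeparation(differentiatedPopulation(), mscPopulation(),
        sortBuffer, nPerPop = 10L, nx = 251L, ny = 61L, seed = 6)
    expect_identical(a$outcome, b$outcome)
    d <- runSeparation(differentiatedPopulation(), mscPopulation(),
        sortBuffer, nPerPop = 10L, nx = 251L, ny = 61L, seed = 7)
    expect_false(identical(a$outcome$entry_y, d$outcome$entry_y))
})
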