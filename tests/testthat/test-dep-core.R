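# Single-shell physics: complex permittivities, Clausius-Mossotti factor,
# DEP force scaling and crossover-frequency root finding.

test_that("complex permittivity follows the lossy-dielectric form", {
    # zero conductivity: purely real, frequency independent
    v <- complexPermittivity(80, 0, c(1e4, 1e6, 1e8))
    expect_equal(Im(v), rep(0, 3))
    expect_equal(Re(v), rep(80 * EPS0, 3))

    # working buffer at 10 kHz: Im = -sigma / (2 pi f)
    v <- complexPermittivity(80, 0.04, 1e4)
    expect_equal(Im(v), -0.04 / (2 * pi * 1e4))
    expect_equal(Im(v), -6.3662e-7, tolerance = 1e-4)
    expect_equal(Re(v), 80 * EPS0)

    # high-frequency limit: loss term vanishes
    expect_lt(abs(Im(complexPermittivity(80, 0.04, 1e12))), 1e-14)

    expect_error(complexPermittivity(80, 0.04, 0), "positive")
    expect_error(complexPermittivity(80, 0.04, -1), "positive")
})

test_that("shelled-particle permittivity collapses correctly in limits", {
    # d = 0: exactly the interior permittivity
    p0 <- ShelledParticle(radius = 5e-6, membraneThickness = 0,
        memRelPermittivity = 9, memConductivity = 1e-6,
        intRelPermittivity = 60, intConductivity = 0.4)
    f <- 10^seq(3, 8, length.out = 30)
    expect_equal(particlePermittivity(p0, f),
                 complexPermittivity(60, 0.4, f), tolerance = 1e-12)

    # membrane identical to interior: homogeneous sphere
    ph <- ShelledParticle(radius = 5e-6, membraneThickness = 5e-9,
        memRelPermittivity = 60, memConductivity = 0.4,
        intRelPermittivity = 60, intConductivity = 0.4)
    expect_equal(particlePermittivity(ph, f),
                 complexPermittivity(60, 0.4, f), tolerance = 1e-12)

    # invalid shell geometry
    expect_error(ShelledParticle(radius = 5e-9, membraneThickness = 5e-9,
        memRelPermittivity = 9, memConductivity = 1e-6,
        intRelPermittivity = 60, intConductivity = 0.4))
})

test_that("Re[K] matches an independent step-by-step evaluation", {
    ref <- oracleReK(1e6, 9e-6, 5e-9, 9, 1e-6, 60, 0.4, 78, 0.04)
    got <- Re(clausiusMossotti(mscCell, sortBuffer, 1e6))
    expect_equal(got, ref, tolerance = 1e-12)

    set.seed(7)
    prm <- randomCellParams(25)
    for (i in seq_len(25)) {
        p <- ShelledParticle(radius = prm$r[i], membraneThickness = prm$d[i],
            memRelPermittivity = prm$epsMem[i], memConductivity = prm$sigMem[i],
            intRelPermittivity = prm$epsInt[i], intConductivity = prm$sigInt[i])
        f <- 10^runif(1, 3.5, 8)
        expect_equal(Re(clausiusMossotti(p, sortBuffer, f)),
            oracleReK(f, prm$r[i], prm$d[i], prm$epsMem[i], prm$sigMem[i],
                      prm$epsInt[i], prm$sigInt[i], 78, 0.04),
            tolerance = 1e-12)
    }
})

test_that("Clausius-Mossotti limiting values are exact", {
    # index matching: particle indistinguishable from the medium
    pm <- ShelledParticle(radius = 5e-6, membraneThickness = 0,
        memRelPermittivity = 78, memConductivity = 0.04,
        intRelPermittivity = 78, intConductivity = 0.04)
    expect_equal(Mod(clausiusMossotti(pm, sortBuffer, 1e6)), 0)

    # lossless homogeneous sphere at eps_p = 2 eps_med: K = 1/4
    p2 <- ShelledParticle(radius = 5e-6, membraneThickness = 0,
        memRelPermittivity = 100, memConductivity = 0,
        intRelPermittivity = 100, intConductivity = 0)
    m2 <- DielectricMedium(50, 0)
    expect_equal(Re(clausiusMossotti(p2, m2, 1e5)), 0.25)
    expect_equal(Im(clausiusMossotti(p2, m2, 1e5)), 0)
})

test_that("Re[K] stays within the spherical bounds over random sweeps", {
    set.seed(42)
    prm <- randomCellParams(10000)
    f <- 10^runif(10000, 3, 9)
    lo <- Inf; hi <- -Inf
    for (i in seq_len(10000)) {
        k <- oracleReK(f[i], prm$r[i], prm$d[i], prm$epsMem[i], prm$sigMem[i],
                       prm$epsInt[i], prm$sigInt[i], 78, 0.04)
        lo <- min(lo, k); hi <- max(hi, k)
    }
    # oracle agrees with package on extreme draws and both respect bounds
    expect_gte(lo, -0.5)
    expect_lte(hi, 1.0)
    set.seed(43)
    prm <- randomCellParams(200)
    ks <- vapply(seq_len(200), function(i) {
        p <- ShelledParticle(radius = prm$r[i], membraneThickness = prm$d[i],
            memRelPermittivity = prm$epsMem[i], memConductivity = prm$sigMem[i],
            intRelPermittivity = prm$epsInt[i], intConductivity = prm$sigInt[i])
        Re(clausiusMossotti(p, randomMedium(), 10^runif(1, 3, 9)))
    }, numeric(1))
    expect_true(all(ks >= -0.5 & ks <= 1.0))
})

test_that("DEP spectra behave as expected across the acquisition grid", {
    # no conductivity anywhere: no dispersion, flat spectrum
    pl <- ShelledParticle(radius = 5e-6, membraneThickness = 5e-9,
        memRelPermittivity = 9, memConductivity = 0,
        intRelPermittivity = 60, intConductivity = 0)
    ml <- DielectricMedium(78, 0)
    s <- reCMSpectrum(pl, ml, defaultFrequencyGrid())
    expect_equal(max(s) - min(s), 0, tolerance = 1e-14)

    # MSC-like cell in the 0.04 S/m buffer: one negative-to-positive sign
    # change across the 20-point grid
    s <- reCMSpectrum(mscCell, sortBuffer, defaultFrequencyGrid())
    expect_lt(s[1], 0)
    expect_gt(s[20], 0)
    expect_equal(sum(diff(sign(s)) != 0), 1L)

    # definitional consistency with pointwise evaluation
    g <- defaultFrequencyGrid()
    expect_identical(s, Re(clausiusMossotti(mscCell, sortBuffer, g)))

    expect_error(reCMSpectrum(mscCell, sortBuffer, c(2e4, 1e4)), "increasing")
})

test_that("DEP force obeys its scaling laws", {
    co1 <- crossoverFrequencies(mscCell, sortBuffer)[1]
    expect_equal(depForceMagnitude(mscCell, sortBuffer, co1, 1e14), 0,
                 tolerance = 1e-9 * abs(depForceMagnitude(mscCell, sortBuffer, 1e6, 1e14)))
    expect_identical(depForceMagnitude(mscCell, sortBuffer, 1e6, 0), 0)

    big <- ShelledParticle(radius = 2 * 9e-6, membraneThickness = 5e-9,
        memRelPermittivity = 9, memConductivity = 1e-6,
        intRelPermittivity = 60, intConductivity = 0.4)
    # same K to good approximation is not guaranteed; compare via K ratio
    kS <- Re(clausiusMossotti(mscCell, sortBuffer, 1e6))
    kB <- Re(clausiusMossotti(big, sortBuffer, 1e6))
    fS <- depForceMagnitude(mscCell, sortBuffer, 1e6, 1e14)
    fB <- depForceMagnitude(big, sortBuffer, 1e6, 1e14)
    expect_equal(fB / fS, 8 * kB / kS, tolerance = 1e-12)
})

test_that("crossover roots carry a certificate and match a brute-force scan", {
    for (cell in list(mscCell, diffCell)) {
        co <- crossoverFrequencies(cell, sortBuffer, 1e4, 5e7)
        expect_gte(length(co), 1L)
        # certificate: |Re K| < 1e-9 at every reported root
        for (f in co)
            expect_lt(abs(Re(clausiusMossotti(cell, sortBuffer, f))), 1e-9)
        # count matches a 1e5-point log-spaced sign scan
        us <- 10^seq(log10(1e4), log10(5e7), length.out = 1e5)
        v <- reCMSpectrum(cell, sortBuffer, us)
        expect_equal(length(co), sum(v[-1] * v[-length(v)] < 0))
        # bracketing: sign change around each root
        for (f in co) {
            kl <- Re(clausiusMossotti(cell, sortBuffer, f * (1 - 1e-4)))
            kr <- Re(clausiusMossotti(cell, sortBuffer, f * (1 + 1e-4)))
            expect_lt(kl * kr, 0)
        }
    }

    # lossless contrast never crosses zero
    pl <- ShelledParticle(radius = 5e-6, membraneThickness = 0,
        memRelPermittivity = 30, memConductivity = 0,
        intRelPermittivity = 30, intConductivity = 0)
    expect_length(crossoverFrequencies(pl, DielectricMedium(78, 0), 1e4, 5e7), 0L)
})

test_that("first crossover agrees with the thin-shell closed form", {
    # f_co1 = sqrt(2) sigma_med / (2 pi r c_mem) in the insulating-shell,
    # conductive-interior regime
    cases <- expand.grid(r = c(5e-6, 9e-6), epsMem = c(6, 9, 12),
                         sigMed = c(0.04, 0.128))
    for (i in seq_len(nrow(cases))) {
        r <- cases$r[i]; em <- cases$epsMem[i]; sMed <- cases$sigMed[i]
        cell <- ShelledParticle(radius = r, membraneThickness = 5e-9,
            memRelPermittivity = em, memConductivity = 1e-8,
            intRelPermittivity = 60, intConductivity = max(10 * sMed, 0.5))
        cMem <- EPS0 * em / 5e-9
        fRef <- sqrt(2) * sMed / (2 * pi * r * cMem)
        co <- crossoverFrequencies(cell, DielectricMedium(78, sMed), 1e3, 5e7)
        expect_gt(length(co), 0)
        expect_lt(abs(co[1] - fRef) / fRef, 0.05)
    }
})

test_that("first crossover shifts up with buffer conductivity and down with membrane permittivity", {
    # higher buffer conductivity: first CO moves to higher frequency
    for (cell in list(mscCell, diffCell)) {
        coLow <- crossoverFrequencies(cell, sortBuffer)[1]
        coHigh <- crossoverFrequencies(cell, highBuffer)[1]
        expect_gt(coHigh, coLow)
    }

    # lower membrane permittivity: first CO strictly increases (the handle
    # that lets same-sized cells be separated)
    perms <- c(12, 10, 8, 6, 4)
    cos <- vapply(perms, function(em) {
        cell <- ShelledParticle(radius = 9e-6, membraneThickness = 5e-9,
            memRelPermittivity = em, memConductivity = 1e-6,
            intRelPermittivity = 60, intConductivity = 0.4)
        crossoverFrequencies(cell, sortBuffer)[1]
    }, numeric(1))
    expect_true(all(diff(cos) > 0))
})

test_that("insulating-membrane cells reach Re[K] = -1/2 at low frequency", {
    cell <- ShelledParticle(radius = 9e-6, membraneThickness = 5e-9,
        memRelPermittivity = 9, memConductivity = 0,
        intRelPermittivity = 60, intConductivity = 0.4)
    expect_equal(Re(clausiusMossotti(cell, sortBuffer, 1)), -0.5,
                 tolerance = 1e-3)
})
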