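# Shared fixtures: the sorting buffer, representative cells, and an
# independent step-by-step evaluation of the single-shell model used as an
# oracle against the package implementation.

sortBuffer <- DielectricMedium(relPermittivity = 78, conductivity = 0.04)
highBuffer <- DielectricMedium(relPermittivity = 78, conductivity = 0.128)

mscCell <- ShelledParticle(radius = 9e-6, membraneThickness = 5e-9,
    memRelPermittivity = 9, memConductivity = 1e-6,
    intRelPermittivity = 60, intConductivity = 0.4)

diffCell <- ShelledParticle(radius = 9e-6, membraneThickness = 5e-9,
    memRelPermittivity = 6, memConductivity = 0.5e-6,
    intRelPermittivity = 60, intConductivity = 0.3)

EPS0REF <- 8.8541878128e-12

# Independent term-by-term oracle for Re[K(f)]: literal transcription of the
# shelled-sphere algebra with explicit complex arithmetic, no shared code
# with the package internals.
oracleReK <- function(f, r, d, epsMem, sigMem, epsInt, sigInt,
                      epsMed, sigMed) {
    cEps <- function(er, s) complex(real = EPS0REF * er,
                                    imaginary = -s / (2 * pi * f))
    em <- cEps(epsMem, sigMem)
    ei <- cEps(epsInt, sigInt)
    emed <- cEps(epsMed, sigMed)
    ratio <- (r / (r - d))^3
    inner <- (ei - em) / (ei + 2 * em)
    ep <- em * (ratio + 2 * inner) / (ratio - inner)
    Re((ep - emed) / (ep + 2 * emed))
}

# random physically plausible single-shell parameter draw
randomCellParams <- function(n) {
    data.frame(
        r = runif(n, 2e-6, 15e-6),
        d = runif(n, 3e-9, 10e-9),
        epsMem = runif(n, 2, 20),
        sigMem = 10^runif(n, -9, -5),
        epsInt = runif(n, 40, 80),
        sigInt = runif(n, 0.05, 1.5))
}

randomMedium <- function() {
    DielectricMedium(runif(1, 40, 80), 10^runif(1, -3, -0.5))
}
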