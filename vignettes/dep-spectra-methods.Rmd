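---
title: "Single-shell DEP spectra: models, fitting and the 2D sorter"
author: "DEPSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shell DEP spectra: models, fitting and the 2D sorter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DEPSpectra)
```

## The physical model

Dielectrophoresis (DEP) is the motion of a polarizable particle in a
spatially non-uniform AC electric field.  The time-averaged force on a
sphere of radius $r$ is

$$\vec F_{DEP} = 2\pi r^3 \varepsilon_0 \varepsilon_{med}\,
  \mathrm{Re}[K(f)]\, \nabla|E|^2,$$

where the Clausius–Mossotti factor

$$K(f) = \frac{\varepsilon_p^* - \varepsilon_{med}^*}
              {\varepsilon_p^* + 2\varepsilon_{med}^*},
  \qquad
  \varepsilon_x^* = \varepsilon_0\varepsilon_x - \frac{j\sigma_x}{2\pi f}$$

encodes the polarizability contrast between particle and medium.  For a
sphere $\mathrm{Re}[K] \in [-1/2, 1]$; its sign sets the force direction
(positive DEP towards field maxima, negative DEP away).  A cell is
idealized as a conductive homogeneous core (cytoplasm) wrapped in a thin,
poorly conducting shell (plasma membrane) of thickness $d$; the shelled
sphere collapses to an equivalent homogeneous permittivity

$$\varepsilon_p^* = \varepsilon_{mem}^*
  \frac{\gamma^3 + 2\Lambda}{\gamma^3 - \Lambda},
  \qquad \gamma = \frac{r}{r-d},
  \qquad \Lambda = \frac{\varepsilon_{int}^* - \varepsilon_{mem}^*}
                        {\varepsilon_{int}^* + 2\varepsilon_{mem}^*}.$$

Frequencies where $\mathrm{Re}[K(f)] = 0$ are the *crossover* (CO)
frequencies.  The first CO is governed mainly by the membrane (through the
specific membrane capacitance $c_{mem} = \varepsilon_0\varepsilon_{mem}/d$)
and the medium conductivity; in the thin-shell limit
$f_{CO1} \approx \sqrt{2}\,\sigma_{med} / (2\pi r\, c_{mem})$, which the
test suite uses as an independent oracle.  Two consequences drive
everything downstream:

* raising the buffer conductivity raises the first CO;
* lowering the membrane permittivity raises the first CO at fixed size —
  which is why two same-sized populations differing only in membrane
  permittivity can be separated by operating at one population's CO.

User-facing permittivities are **relative** throughout; the complex
arithmetic converts to absolute values internally
(multiplication by $\varepsilon_0 = 8.8541878128\times10^{-12}$ F/m).

## Crossover root finding

`crossoverFrequencies()` scans $\mathrm{Re}[K]$ on a dense logarithmic grid
(2000 points per decade by default), brackets every sign change, and
refines each bracket with Brent's method in $\log_{10} f$ to an interval
tolerance of $10^{-13}$; every reported root satisfies
$|\mathrm{Re}[K]| < 10^{-9}$.  Roots closer than $10^{-6}$ relative are
merged; results are sorted ascending and labelled first/second by rank.
The default search range is the instrument range, 10 kHz – 50 MHz.

## What the synthetic generator emulates

3DEP-style well-plate instruments report a dimensionless *relative DEP
force* per frequency, proportional to $\mathrm{Re}[K(f)]$ with an unknown
per-spectrum proportionality.  The generator reproduces that contract:

* 20 log-spaced frequencies from 10 kHz to 40 MHz (`defaultFrequencyGrid`);
* `relative_force = scale * Re[K(f)] + N(0, noiseSD)`, homoscedastic in
  frequency, `noiseSD` defaulting to 0.05 of full scale;
* between-cell variability through `PopulationModel`: radius, membrane
  permittivity, membrane conductivity and cytoplasm conductivity drawn
  independently and *uniformly on mean ± SD* (a deliberately literal
  reading of parameters "ranging within one standard deviation"; a
  Gaussian option exists), with membrane thickness and interior
  permittivity fixed;
* 24 replicate spectra per group by default, a typical per-group
  replication for such instruments.

It does **not** emulate electrode polarization, frequency-dependent noise,
well-to-well scale drift, image-analysis artifacts, or hierarchical
(donor-level) variability.  Passing recovery tests on these spectra
therefore shows the estimation chain is correct and noise-stable, not that
real 3DEP data are free of systematic effects.

The bundled fixture populations are synthetic stand-ins chosen inside
literature ranges for mammalian cells (membrane relative permittivity
6–9, membrane conductivity below $5\times10^{-6}$ S/m, cytoplasm
conductivity a few tenths of S/m): an "MSC"-like population
($r = 9\,\mu m$, $\varepsilon_{mem} = 9$, $\sigma_{mem} = 10^{-6}$ S/m,
$\sigma_{int} = 0.4$ S/m) and a differentiated-like population with lower
membrane permittivity and conductivity ($\varepsilon_{mem} = 6$,
$\sigma_{mem} = 0.5\times10^{-6}$ S/m, $\sigma_{int} = 0.3$ S/m) — the
direction of change reported for differentiating stem cells.  Spreads
(SD 0.5 µm on radius, 0.3 on membrane permittivity, 0.1 µS/m on membrane
conductivity, 0.05 S/m on cytoplasm conductivity) are modest
laboratory-scale values chosen once so that the two populations' first-CO
distributions do not overlap, consistent with the clean separability the
fixtures are meant to exhibit.

## Fitting: free parameters, bounds, quality control

Exactly four parameters are free: membrane relative permittivity,
membrane conductivity, cytoplasm conductivity and the instrument scale.
The cell radius is *fixed* from the per-spectrum metadata (bench-top size
measurement), as are membrane thickness (5 nm), interior permittivity
(60) and the buffer properties.  Defaults:

| parameter | bounds | initial guess |
|---|---|---|
| $\varepsilon_{mem}$ | [1, 30] | 5.48 (geometric mid-bound) |
| $\sigma_{mem}$ (S/m) | [$10^{-9}$, $10^{-4}$] | $3.2\times10^{-7}$ |
| $\sigma_{int}$ (S/m) | [0.01, 2] | 0.14 |
| scale | [$10^{-3}$, $10^3$] | 1 |

The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
$\sigma_{mem}$, $\sigma_{int}$ and the scale on a $\log_{10}$ internal
scale.  Five starts are used: the mid-bound guess, a data-driven start
whose scale is `max(|y|)/0.6` (the positive plateau of $\mathrm{Re}[K]$
is typically 0.5–0.8), and three seeded random starts in the box; the
lowest-SSE converged solution wins.  $R^2$ is computed against the fitted
model, and crossovers are recomputed from the fitted parameters over
10 kHz–50 MHz.

Quality control mirrors automated spectrum-analysis practice:

* *outlier points*: iterative robust screening — fit, drop points with
  $|residual| > k \cdot 1.4826 \cdot \mathrm{median}|residual|$
  ($k = 3$), refit; at most 20 % of points may be removed, and a small
  absolute floor on the threshold keeps numerically exact fits from
  flagging rounding noise;
* *whole spectra*: an $R^2$ gate (default 0.85) partitions results into
  accepted and rejected; rejected spectra are flagged with a reason,
  never silently dropped.  Spectra with no variance (dead wells) are
  rejected outright because the scale is unidentifiable.

Residuals are unweighted across frequency; the acquisition grid is
log-spaced, so uniform weights already weight decades evenly.

## Group statistics

Fitted parameters are compared across groups with one-way ANOVA and Tukey
HSD pairwise comparisons (Tukey–Kramer for unequal group sizes), both
delegated to base R (`aov`, `TukeyHSD`).  Stars follow the figure-caption
convention `*`, `**`, `***` for $p < 0.05, 0.01, 0.001$ with *strict*
inequalities, so $p = 0.05$ exactly is "ns".  Families are per parameter
(no correction across parameters), matching per-panel annotation practice.

## The 2D sorter model

The separation device is modelled in plan view: a straight channel
(default 5 mm × 500 µm), axial coordinate $x$, lateral coordinate $y$
with the left wall at $y = 0$.  The physics chain is:

1. **Electric field** — the RMS potential obeys Laplace's equation with
   Dirichlet values on electrode strips (phase at $V_{rms}$, default 10 V;
   neutral at 0) and zero normal flux on walls and openings.  Five-point
   finite differences with mirrored ghost nodes; direct sparse solve
   (Matrix); the solution is rejected if the linear residual exceeds
   $10^{-8}$ of the boundary scale.  Default grid 501 × 61 (≈8 µm cells;
   at least 50 nodes across the width are required).
2. **Flow** — fully developed plane-Poiseuille profile
   $u(y) = 1.5\,\bar u\,[1 - (2(y - w/2)/w)^2]$, no lateral component.
   A full Stokes solve is deliberately out of scope for a straight
   channel.
3. **DEP drift** — inertialess Stokes balance: drift velocity
   $\mu \nabla|E|^2$ with mobility
   $\mu = r^2\varepsilon_0\varepsilon_{med}\mathrm{Re}[K]/(3\eta)$
   (particle Reynolds and Stokes numbers are far below 1 at these scales).
4. **Tracing** — explicit midpoint (RK2) integration with bilinear field
   interpolation and an adaptive shared time step capped at 0.5 grid
   cells per step.  Particles pushed into a wall are clamped and continue
   axially; particles that never exit within `maxTime` are reported as
   outcome "none", so every particle is accounted for.

### Electrode layout and the capture mechanism

The default layout is a continuous *neutral* strip running diagonally
from the right wall (upstream) to the left wall (downstream) and a
*phase* strip parallel to it at a fixed 150 µm clearance (strips 50 µm
wide).  The field-intensity maximum follows the diagonal gap.  A cell in
positive DEP that meets the gap is pulled onto the intensity ridge and
held there; the axial flow component along the ridge then carries it
leftward, and it exits through the left outlet.  A cell at its crossover
feels nothing and exits right at its entry lateral position.  Whether a
cell is captured is a sharp threshold competition between its lateral DEP
velocity near the ridge and the flow component normal to the ridge
($\bar u \sin\theta$ for ridge angle $\theta$); the default mean flow
speed (2 mm/s) was chosen once so that this threshold lies between the
two fixture populations' $|\mathrm{Re}[K]|$ ranges at the operating
frequency — the same operating-point design a device engineer would do.

A finger-array phase electrode (`style = "fingers"`), the layout common
in fabricated devices, is also provided.  It is not the default because
in a strict 2D plan view the discrete finger tips are isolated field
maxima that can pin captured cells permanently — an artifact of
collapsing the third dimension; the finite channel height of a real
device weakens these point traps.

Two further 2D idealizations matter:

* **Junction abstraction.** The sheath-flow inlet junction and the outlet
  fork are not meshed.  Their effect is modelled as (a) particles
  entering within a right-side lateral band (default 70–95 % of the
  width) and (b) a lateral split coordinate (default half-width) that
  assigns exiting particles to the left or right outlet.  This preserves
  the separation physics while keeping the model desk-scale; like any 2D
  treatment it tends to overestimate yield more than purity, since every
  simulated cell travels at the electrode plane.
* **Finite particle size.** $|E|^2$ is averaged over a window of one cell
  radius (9 µm by default) before differentiation.  Ultra-thin electrode
  edges make the plan-view field singular at nodes a point particle could
  approach arbitrarily closely; a real cell samples the field over its
  own volume and cannot.  The averaging leaves smooth-field gradients
  unchanged (verified against a quadratic-potential oracle in the tests).

### Operating frequency

`chooseOperatingFrequency(popA, popB, medium)` returns the first CO of
population A's mean cell and *verifies* that population B's mean cell is
in positive DEP there, refusing otherwise with a hint to swap roles.
With the bundled fixtures the differentiated-like population (lower
membrane permittivity, hence *higher* first CO) must be population A:
at its CO the MSC-like population is above its own first CO and firmly in
positive DEP, while at the MSC crossover the differentiated cells would
be in negative DEP.

## Numerical choices and degenerate inputs

* Vacuum permittivity lives in one exported constant, `EPS0`.
* The Clausius–Mossotti denominator is checked against machine tolerance;
  index-matched degenerate inputs raise an error rather than returning
  noise.
* Root deduplication at $10^{-6}$ relative spacing; ascending order.
* Population draws violating single-shell invariants (possible with the
  Gaussian option) are redrawn up to 100 rounds, then error.
* Every random draw (cell sampling, spectrum noise, optimizer restarts,
  entry positions) is controlled by an explicit integer seed, and seeded
  helpers restore the caller's RNG state.
* CSV writers emit 17 significant digits so round trips are exact.

## Problem sizes

The shipped tests and the acceptance script run at the scale the study
design calls for: 20-frequency spectra, 24 spectra per group for
group-level checks, 50 zero-noise and 100 noisy replicate fits for the
recovery suites, $10^4$-draw parameter sweeps for the bound checks,
$10^5$-point scans for root-finder certification, and 200 particles per
population on a 501 × 61 grid for the separation run.

## Known limitations

* Single-shell only: no nucleus, no multi-shell dispersion, no
  electrorotation or travelling-wave DEP; intrinsic permittivities are
  frequency independent.
* The sorter model is 2D and quasi-static: no AC electro-osmosis,
  electrothermal flow, particle–particle interactions, electrode
  polarization or heating; flow is prescribed, not solved.
* The second crossover of the bundled fixtures lies above the 50 MHz
  instrument range in the 0.04 S/m buffer, so `co_second_hz` is
  typically absent for them — extrapolating a fitted model root beyond
  the measured range is left to the user's judgement.
* Uniform mean ± SD variability is a modelling convention, not an
  empirical distribution of cell parameters.
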