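# DEPSpectra

Label-free electrical characterization and sorting of cells by
dielectrophoresis (DEP), for cell biophysicists and lab-on-chip modellers.
When cells change state — for instance when mesenchymal stem cells start
differentiating — their membrane permittivity, membrane conductivity and
cytoplasm conductivity shift before any morphological change is visible.
Those parameters can be read out from DEP spectra and exploited to sort
the populations in a microfluidic device.  DEPSpectra implements the full
computational chain:

* **Single-shell physics** — a cell as a conductive sphere (cytoplasm)
  wrapped in a thin insulating shell (membrane).  The DEP force is
  `F = 2 pi r^3 eps0 eps_med Re[K(f)] grad|E|^2` with the
  Clausius–Mossotti factor `K = (eps_p* − eps_med*) / (eps_p* + 2 eps_med*)`
  and `eps_x* = eps0 eps_x − j sigma_x / (2 pi f)`.  Crossover (CO)
  frequencies, the roots of `Re[K(f)] = 0`, are located by dense log-scan
  bracketing plus Brent refinement.
* **Synthetic 3DEP-style spectra** — 20 log-spaced frequencies
  (10 kHz–40 MHz), relative force `scale * Re[K(f)]` plus Gaussian noise,
  populations with per-cell parameter variability, CSV round trip.
* **Spectrum fitting** — bounded Levenberg–Marquardt extraction of
  membrane permittivity, membrane conductivity, cytoplasm conductivity
  and the instrument scale, with robust outlier removal and R² gating.
* **Group statistics** — one-way ANOVA and Tukey HSD pairwise comparisons
  with the `*`/`**`/`***` star convention (p < 0.05 / 0.01 / 0.001).
* **2D sorter simulation** — finite-difference Laplace solve of the
  electrode potential in a 5 mm × 500 µm channel with an oblique electrode
  pair, laminar flow, Stokes-drag particle tracing, and purity/yield at a
  two-outlet split.

The methods vignette (`vignettes/dep-spectra-methods.Rmd`) documents the
models, defaults and 2D idealizations in detail.

## Worked example

Characterize an MSC-like population from synthetic spectra:

```r
library(DEPSpectra)

med <- DielectricMedium(relPermittivity = 78, conductivity = 0.04)
msc <- meanParticle(mscPopulation())
crossoverFrequencies(msc, med)
#> [1] 59860.11

x <- generateGroupSpectra(mscPopulation(), med, n = 24, noiseSD = 0.05, seed = 1)
x
#> DepSpectra: 20 frequencies x 24 spectra
#>   grid: 1e+04 Hz - 4e+07 Hz
#>   groups: MSC

fits <- fitSpectra(x, FitConfig(), seed = 1)
summarizeGroup(fits)
#>                  parameter         mean           sd  n
#> 1     mem_rel_permittivity 8.988582e+00 3.592630e-01 24
#> 2 mem_conductivity_S_per_m 1.405607e-06 1.139275e-06 24
#> 3 int_conductivity_S_per_m 3.942308e-01 5.418918e-02 24
#> 4                    scale 1.010980e+00 3.951624e-02 24
#> 5              co_first_hz 5.954870e+04 3.145092e+03 24
```

The mean cell crosses over at ≈60 kHz in the 0.04 S/m buffer, and 24
noisy spectra recover the generating membrane permittivity (9) to ~0.1%
in the mean.  `co_second_hz` is absent because the second crossover of
this population lies above the 50 MHz instrument range.

Sorting: operate at the first crossover of the differentiated-like
population (whose lower membrane permittivity pushes its first CO up to
≈89 kHz); the MSC-like cells are then in positive DEP, get captured on
the diagonal high-field path and exit left, while the differentiated-like
cells pass straight through:

```r
res <- runSeparation(differentiatedPopulation(), mscPopulation(), med,
                     nPerPop = 200, seed = 1)
res$frequency
#> [1] 89386.46
res$summary
#>   outlet  target purity yield
#> 1  right diff_w1    100   100
#> 2   left     MSC    100   100
```

A config-driven pipeline (`pipelineConfig()`, `cmdSimulateSpectra()`,
`cmdFit()`, `cmdStats()`, `cmdSeparate()`, `cmdRunAll()`) chains the
stages through CSV files; `inst/scripts/dep_pipeline.R` wraps them for
shell use.

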