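# smlssi

Precision bounds and simulation for single-molecule localization by
sequential structured illumination (SML-SSI) — the family of methods, such
as MINFLUX and RASTMIN, that localize one fluorescent emitter by exposing it
to a sequence of doughnut-beam intensity *minima* and reading the relative
photon counts. The package covers the multiphoton generalization: the
fluorescence rate follows the excitation intensity raised to an order
`c ≥ 1` (1 = linear, 2 = two-photon, 3 = three-photon, fractional for
effective superlinear photoswitching schemes).

## Who this is for

Microscopists and method developers who want to ask, before building
anything: what localization precision does a given excitation sequence,
photon budget and signal-to-background ratio permit, how is that precision
distributed over the field of view, and does a maximum-likelihood estimator
actually attain it?

## Model

One localization event = `K` exposures of a doughnut beam
`I(ρ) = e (ρ²/R²) exp(−ρ²/R²)` (exact zero on axis, ring maximum at
`R = λ/2NA`) centered at known positions `r_i`; MINFLUX uses a triangle of
circumradius `L/2` plus a center exposure (`K = 4`), RASTMIN an `m × m`
raster spanning the FOV. With emitter at `r_E`, order-`c` weights
`w_i = I^c(r_E − r_i)` and signal-to-background ratio SBR, a detected photon
lands in exposure `i` with probability

    p_i = SBR/(SBR+1) · w_i / Σ_j w_j  +  1 / (K (SBR+1))

and the count vector is multinomial(N, p) at fixed photon budget N. The
position Fisher information `F = N Σ_i (1/p_i) ∇p_i ∇p_iᵀ` gives the
Cramér–Rao bound `σ_CRB = sqrt(tr(F⁻¹)/2)`, exactly ∝ `1/√N`. The package
computes `σ_CRB` pointwise and as FOV maps, simulates count records,
localizes them by grid-then-refine maximum likelihood, and validates the
estimator against the bound by Monte Carlo.

## Worked example

```r
library(smlssi)

beam <- makeBeamProfile(647, 1.4)          # ring radius 231.07 nm
sc   <- makeScenario(beam, minfluxSequence(100), order = 1, N = 500, SBR = 4)

crbSigma(sc)                     # bound at the pattern center
#> [1] 2.021006
centerImprovementRatio(sc, 1, 2) # 1p vs 2p center precision, same beam
#> [1] 2
photonEquivalence(sc, 1, 2)      # photons 2p needs for equal precision
#> [1] 0.25

# simulate one event with the emitter at (10, -6) nm and localize it
truth <- makeScenario(beam, minfluxSequence(100), 1, 500, 4, c(10, -6))
n <- photonCounts(sampleCounts(exposureProbabilities(truth), 500, seed = 55))
n
#> [1] 199 187  86  28
mleLocalize(n, sc)@estimate
#> [1] 11.461 -8.131

# does the MLE attain the bound? 1000 seeded repeats at the center:
monteCarloPrecision(c(0, 0), sc, repeats = 1000, seed = 2)
#> PrecisionSummary: pooled sigma 2.015 nm vs sigma_CRB 2.021 nm (ratio 0.997)
#>   per-axis (1.997, 2.032) nm, bias (-0.055, -0.054) nm, 1000 repeats, 0 excluded

# two-photon precision map over the FOV
precisionMap(makeScenario(beam, minfluxSequence(100), 2, 500, 4), 41)
#> PrecisionMap: minflux, c = 2, 41 x 41 over [-50, 50] nm
#>   sigma_CRB [nm]: center 1.011 | mean 4.285 | range 1.011-6.418 | CV 0.309
```

Reading the numbers: at `L = 100` nm, `N = 500` photons and SBR 4, the
one-photon bound at the center is ~2 nm and the matched-model MLE attains it
(ratio 0.997). Switching to two-photon excitation with the same beam doubles
the center precision (ratio 2), equivalently needs a quarter of the photons
— at the cost of a less uniform map (center 1.0 nm vs edge 6.4 nm).

Config-driven runs (`loadConfig()`, `runMap()`, `runValidate()`) write
deterministic CSV/YAML/JSON (and optional 32-bit float TIFF) artifacts; a
thin command-line front end with subcommands `map`, `simulate`, `localize`,
`validate`, `compare` lives at `inst/cli/smlssi-cli.R`:

```sh
Rscript inst/cli/smlssi-cli.R map --config run.yaml --tiff
```

See `vignettes/multiphoton-localization.Rmd` for the model's assumptions,
numerical choices, and what the synthetic data do and do not emulate.

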