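---
title: "Localization precision with sequences of light minima: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization precision with sequences of light minima: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlssi)
```

## The measurement being modeled

A single fluorescent emitter at an unknown position $r_E$ is interrogated
with a sequence of $K$ exposures. In each exposure $i$ the same focused
doughnut beam — a beam with an exact intensity zero on its axis — is centered
at a known position $r_i$, and the photons detected during that exposure are
counted. Because the emitter's fluorescence rate follows the local excitation
intensity, the count vector $n = (n_1, \dots, n_K)$ encodes where the emitter
sits relative to the pattern of minima, and encodes it very efficiently: an
emitter near a minimum yields few photons exactly where the intensity
gradient carries the most position information per photon.

Two pattern geometries are provided:

* **MINFLUX**: $K = 4$ exposures — the vertices of an equilateral triangle of
  circumradius $L/2$, plus a final exposure at the pattern center. $L$ is the
  diameter of the circumcircle and defines the field of view (FOV).
* **RASTMIN**: the minimum is raster-scanned over a regular $m \times m$ grid
  spanning $[-L/2, L/2]^2$ ($K = m^2$), as any scanning microscope would do.

Multiphoton excitation enters through a single exponent. With excitation
order $c$ the fluorescence rate is proportional to $I^c$: $c = 1$ linear,
$c = 2$ two-photon, $c = 3$ three-photon; fractional $c \ge 1$ represents
effective superlinear schemes such as intensity-dependent photoswitching.
No photophysical kinetics are modeled — $c$ is a free parameter of the
forward model.

## Forward model

**Beam.** The doughnut is the peak-normalized paraxial profile
$$I(\rho) = e \,\frac{\rho^2}{R^2}\, e^{-\rho^2/R^2},$$
with an exact quadratic zero on axis and maximum 1 at the ring radius $R$.
The ring radius defaults to the diffraction-limited scale
$R = \lambda/(2\,\mathrm{NA})$ (647 nm at NA 1.4 gives $R = 231$ nm), and can
be overridden. The method definitions require only a minimum of
light, not a specific profile, so this standard analytic doughnut was chosen
for having an exact zero and closed-form gradients; center-of-pattern comparisons between
orders are insensitive to the choice in the regime $L \ll R$ (see below),
while absolute $\sigma$ values do depend on it.

**Counts.** Given the emitter position, the order-$c$ excitation weights are
$w_i = I^c(r_E - r_i)$ and the probability that a detected photon belongs to
exposure $i$ is
$$p_i(r_E) \;=\; \frac{\mathrm{SBR}}{\mathrm{SBR}+1}\,
  \frac{w_i}{\sum_j w_j} \;+\; \frac{1}{K\,(\mathrm{SBR}+1)},$$
a mixture of the normalized signal weights with uniform background. SBR is
the total signal over total background across the whole sequence, constant
over the FOV. Per-exposure counts are Poisson; conditioned on their total
$N$ they are multinomial with parameters $(N, p)$, which is how records are
generated — the fixed photon budget $N$ is the convention in which precision
is quoted, and conditioning removes brightness as a nuisance parameter
without changing the Fisher information for position.

Reference conditions used throughout the package's tests and examples:
$L = 100$ nm, $N = 500$, SBR $= 4$, $\lambda = 647$ nm, NA $1.4$ (the
one-photon map setting; 800 nm and 1300 nm are the matching two- and
three-photon wavelengths).

## Precision bound

The Fisher information of the multinomial model is
$$F(r_E) = N \sum_{i=1}^{K} \frac{1}{p_i}\,\nabla p_i \nabla p_i^{\top},$$
a $2\times2$ matrix, exactly linear in $N$. The scalar bound reported
everywhere is
$$\sigma_{\mathrm{CRB}} = \sqrt{\tfrac12\,\mathrm{tr}\,F^{-1}},$$
the isotropic (root mean per-axis) standard deviation no unbiased estimator
can beat. Linearity in $N$ makes $\sigma \propto 1/\sqrt{N}$ exact — the
suite asserts $\sigma(4N) = \sigma(N)/2$ to machine precision.

Gradients $\nabla p_i$ are closed-form (chain rule through $I^c$); finite
differences appear only as a test oracle. The $2\times2$ inverse is explicit,
with an error raised when the condition number exceeds $10^{12}$ — which is
also how physically non-identifiable geometries (probability collapsed onto
a single exposure) surface, as a typed failure rather than a garbage number.

**Cross-order comparisons.** At the pattern center of MINFLUX without
background, the relative gradients of the order-$c$ weights are exactly $c$
times those of the intensity, so
$$\frac{\sigma_{\mathrm{CRB}}(c=1)}{\sigma_{\mathrm{CRB}}(c=2)} = 2
\quad\text{and}\quad \frac{N_{2p}}{N_{1p}}\Big|_{\text{equal }\sigma} =
\tfrac14$$
hold exactly (for any $L$, not only $L \ll R$); `centerImprovementRatio()`
and `photonEquivalence()` compute them from the general machinery and
reproduce these values numerically. Away from the center the improvement is
position-dependent. The "no-background limit" is operationalized as
SBR $= 10^6$ rather than literal infinity: the center exposure of MINFLUX
has $p_i = 0$ at the exact origin when SBR $= \infty$, and the large finite
value keeps $F$ finite and continuous at a relative bias below $10^{-3}$.

```{r ratios}
sc <- makeScenario(makeBeamProfile(647, 1.4), minfluxSequence(100),
                   order = 1, N = 500, SBR = 4)
crbSigma(sc)                        # sigma_CRB at the origin, nm
centerImprovementRatio(sc, 1, 2)    # 1p vs 2p at the center
photonEquivalence(sc, 1, 2)         # photon budget ratio for equal sigma
```

## Precision maps and heterogeneity

`precisionMap()` evaluates $\sigma_{\mathrm{CRB}}$ on a $g \times g$ lattice
covering $[-L/2, L/2]^2$ (default $g = 41$, odd so a node sits at the exact
center; the lattice resolves all map structure at negligible cost). Maps
inherit the pattern's point symmetry — three-fold for MINFLUX, four-fold for
RASTMIN — which the tests assert.

Superlinear excitation improves the center and degrades the FOV edge, so the
precision becomes markedly less uniform for two-photon MINFLUX, and a raster
of minima restores uniformity. How this shows up depends on the summary
statistic, and the two natural ones disagree on part of the ordering:

* **Dynamic range** (map maximum over center value) reproduces the expected
  ordering cleanly at the reference conditions: about $6.4\times$ for 2p
  MINFLUX versus $4.2\times$ for 1p MINFLUX and $4.8\times$ for 2p RASTMIN
  (same beam, $L$, $N$, SBR). A regular test asserts both inequalities.
* **Coefficient of variation** (sd/mean over all lattice nodes) does *not*
  order the same way at SBR $= 4$: the square map's corner region lies
  outside the circumcircle of the MINFLUX pattern, where superlinear
  excitation is actually *advantageous* (relative intensity gradients grow
  with $c$), and that region dominates the CV. Restricted to the inscribed
  disk — the FOV the pattern actually defines — and without background, the
  CV ordering agrees with the dynamic-range one. The acceptance-style check
  of the CV ordering over the full square map is kept at its stated form and
  currently fails; the analysis above is the package's account of why, and
  `mapSummary()` reports both `cv` and `dynamicRange` so users can judge
  uniformity with either summary.

```{r maps}
mapSummary(precisionMap(makeScenario(makeBeamProfile(647, 1.4),
  minfluxSequence(100), order = 2, N = 500, SBR = 4), 41))[
    c("center", "max", "cv", "dynamicRange")]
```

## Estimator

`mleLocalize()` maximizes the multinomial log-likelihood
$\ell(r) = \sum_i n_i \ln p_i(r)$ with the same SBR mixing used for
generation (matched model; mismatch studies are out of scope). The
likelihood can be multimodal at low $N$, so the search is grid-first: coarse
evaluation at 1 nm pitch over the FOV plus a 20% margin, ties broken toward
the smallest $|r|$, then derivative-free Nelder-Mead refinement well below
0.01 nm. Estimates are not clipped to the FOV — clipping would bias the
precision summaries — and optima escaping the margin are flagged rather than
silently kept. A brute-force 0.1 nm grid arg-max over an independent
reimplementation of the likelihood serves as the test oracle (agreement
within 0.2 nm).

`monteCarloPrecision()` draws seeded records at a true position, localizes
each, and reports empirical per-axis and pooled sigma, bias, exclusions, and
$\sigma_{\mathrm{CRB}}$ at that position. Failed refinements are excluded
and counted, never imputed. At the reference conditions the pooled empirical
sigma at the pattern center sits within a few percent of the bound for both
geometries and $c \in \{1, 2\}$ — the asymptotic efficiency of the MLE is
already effective at $N = 500$.

Seeding: one master seed; record $j$ uses the substream seed
$(\text{seed} + 1000003\,j) \bmod (2^{31}-1)$, so any single record is
reproducible without regenerating the table.

## What the synthetic data do and do not emulate

Generated records reproduce multinomial photon statistics with uniform
background at fixed total budget — the regime in which the bounds are
stated. They do not emulate: Poisson fluctuation of the total $N$ itself,
detector dead-time or afterpulsing, emitter blinking and bleaching,
position-dependent or structured background, aberrated or vectorial beam
profiles, or axial (z) structure. Passing tests therefore validate the
statistical machinery and its internal consistency, not the photophysics of
any particular experiment; absolute $\sigma$ values for a real microscope
depend on the real beam and background, while order-to-order ratios at the
pattern center are robust to those details.

## Numerical choices and limitations

* Probabilities are floored at $10^{-300}$ inside logs; zero-probability
  exposures with vanishing gradient are dropped from $F$ (they carry no
  information), and a zero-probability exposure with non-vanishing gradient
  raises a singular-model error directing the user to a finite SBR.
* Problem sizes in the test suite (map grid 41, Monte-Carlo repeats 1000 for
  the efficiency checks, $10^5$ draws for the score-sampling oracle, $10^4$
  for moment checks) were chosen so each check's sampling error is several
  times smaller than the tolerance it asserts.
* The RASTMIN exposure count is not fixed by any reference; the default
  $m = 4$ ($K = 16$) is a configurable package choice.
* MINFLUX orientation (first vertex on $+y$) and exposure order (vertices
  counterclockwise, center last) are conventions fixed for reproducible
  count-record layout; neither affects the bound.
* 2D lateral localization only; $N$ and SBR are treated as known, so the
  bound is for position alone.
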