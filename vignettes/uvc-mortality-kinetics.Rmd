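---
title: "Quantum-kinetic models of UV-C mortality: methods and design"
author: "uvckin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-kinetic models of UV-C mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvckin)
```

## The models

`uvckin` implements two coupled descriptions of UV-C germicidal
inactivation of *E. coli*.

**Physical model.** The cell quantum mortality yield
$\Phi_\mu$ (cQMY, mol/(erg·s)) is the efficiency with which absorbed
einsteins convert into dead cells. Taking the mortality rate proportional
to the activation energy over time, $dN/dt = \Phi_\mu E_a / t$ with
$E_a = n_0 h c / \lambda$, and integrating from $t = 1$ s gives

$$N(t) = \Phi_\mu E_a \ln t = k \ln t, \qquad N_1(t) = N_0 - k \ln t,$$

with $k$ the specific speed of mortality (SSM). The landmarks follow by
inversion: the half-lethal exposure $\mathrm{LDR}_{50} = e^{N_0/2k}$, the
minimum mortality time $t_u = 1/k$ (the exposure producing one death), and
the absolute death time $T = e^{N_0/k}$, which equals
$\mathrm{LDR}_{50}^2$.

**Corpuscular model.** Photons traverse the genome matrix as particles.
With base density $N^* = 2N_j/V_G$ (both strands) and effective impact
cross-section $\sigma$ per base, the macroscopic section is
$Z = N^*\sigma$, the mean free path $\bar l = 1/Z$, the excitation time
$\Delta t_i = 1/(N^*\sigma c)$, and the expected impacts per traversal of
the slab of thickness $\Delta x$ — the absorbed fraction — is
$\delta = N^*\sigma\Delta x$. The lethal impact number
$f(t_u) = N^*\sigma c/k$ counts impacts accumulated over one minimum
mortality time; the *proportionality hypothesis* asserts
$f(t_u) \approx N_j$, under which

$$\bar k = \frac{2\sigma c}{V_G}, \qquad
  \bar t_u = \frac{1}{\bar k}, \qquad
  \bar\Phi_\mu = \frac{2\sigma\lambda}{V_G n_0 h}.$$

The two models are exactly equivalent under the coupling
$k = N^*\sigma c / f(t_u)$; this pointwise identity is enforced by tests.

### Assumptions

1. Light behaves corpuscularly; energy deposition in the genome is
   discontinuous (photon–base impacts, not uniform wave absorption).
2. Several photons must hit a base to break/form a bond (multi-impact
   kinetics); the photons-per-dimer count $D_p = 1/\Phi_\mu$ is $\gg 1$ in
   the entire published range.
3. Pyrimidine dimers are the dominant lethal photoproduct; repair kinetics
   (photoreactivation, NER/SOS) are *not* modeled — $\Phi_\mu$ absorbs the
   repair capacity of a strain as a lumped constant.
4. Targets are homogeneous, independent and immovable, so free paths are
   exponential with rate $Z$ and traversal impact counts are Poisson with
   mean $\delta$ (the basis of the Monte Carlo oracle
   `mcImpactOracle()`).

## Units and conventions

Everything is CGS (erg, cm, s); no conversion layer is provided, because
every reference value is stated on that scale and silent conversions are a
classic source of error. Magnitude checks at construction (e.g. the UV-C
band warning on wavelength) catch the common mistakes.

Two conventions deserve emphasis:

- **Einstein accounting.** $E_a = n_0 h c/\lambda$ is *per mole of
  photons*; the per-photon energy $hc/\lambda$ is exposed separately as
  `photonEnergy()`. All yield/speed conversions use the per-mole form, so
  $k = \Phi_\mu E_a$ exactly.
- **Time in the logarithm.** $\ln t$ treats $t$ as the dimensionless
  numeric value of time in seconds, so $N(1\,\mathrm{s}) = 0$. The model is
  dimensionally informal in this respect; we freeze the operational
  convention that the fits use. Exposures $t \in (0, 1)$ s give negative
  raw mortality (the "pre-unitary regime"): values are clamped to
  $[0, N_0]$ by default and flagged, and `clamp = FALSE` preserves raw
  values for regression work. $\mathrm{LDR}_{50}$ and $T$ are computed in
  log space; if the exponent overflows the double range the functions warn
  and return `Inf` carrying `ln t` as an attribute.

The exponent $N_0/2k$ mixes a cell count with a rate, as the model's
formulation does; it is implemented as a pure number, as printed.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| $n_0$ | 6.0225e23 | 1/mol | Avogadro's constant |
| $h$ | 6.6256e-27 | erg·s | Planck's constant |
| $c$ | 2.9979e10 | cm/s | speed of light |
| $\lambda$ | 2.537e-5 | cm | low-pressure Hg lamp line (253.7 nm) |
| $N_j$ | 5.2e6 | bp | mean *E. coli* genome size |
| $V_G$ | 4.3716e-13 | cm³ | nucleoid volume |
| $\Delta x$ | 5.5111e-5 | cm | mean genome thickness |
| $\sigma$ | 4.9627e-16 | cm² | effective impact cross-section per base |

The 4–5 significant-figure values above are the package's canonical
reference set; tests pin derived quantities to them at 0.1% relative
tolerance (printed-rounding slack). No CODATA-updated constants are
substituted. The derived base density is $N^* = 2.3790 \times 10^{19}$
bases/cm³ to printed precision (source tables round the same quantity to
both 2.3790 and 2.3791; the package computes 2.37899...).

Estimation defaults: confidence level 0.97 for bands and slope intervals
and significance 0.03 for the one-mean t-test, matching the convention the
experimental analysis uses; both are arguments.

## Estimation

`fitSurvival()` is ordinary least squares of survivors on $\ln t$ via
`stats::lm`. Choices:

- **Controls.** $t = 0$ rows set $N_0$ (absolute mode) or the 100%
  viability reference (normalized mode) and are excluded from the
  regression, since $\ln 0$ is undefined.
- **Count scale.** Absolute mode fits CFU/ml; normalized mode fits percent
  of control. $R^2$ is invariant under the rescaling; $\hat k$ and hence
  $\hat\Phi_\mu$ scale with the count unit, so the result records which
  mode was used.
- **Bands.** "Confidence intervals" are mean-response bands and "fiducial
  limits" are individual-observation prediction bands
  (`predict.lm(interval = "confidence" / "prediction")`), the two band
  types a survival scatter plot carries.
- **Below-detection counts.** Zero plate counts are excluded by default
  (`dropZeros = TRUE`, counted in the fit flags). A zero count is below
  the detection limit of the dilution series, while the model line is
  already negative there; treating it as $N_1 = 0$ would bend the fitted
  line. This matters only for exposures at or beyond the absolute death
  time.
- **Replicates.** Pooled by default; `fitSurvivalByReplicate()` yields
  per-replicate $\hat k$ for `tTestVsTheory()` (one-sample Student t-test,
  `stats::t.test`). A degenerate spread of estimates (all equal) is
  handled explicitly since `t.test` refuses constant data. No
  multiple-testing correction is applied across strains.
- **Degenerate designs.** Fewer than 3 distinct positive times is an
  error; a negative fitted intercept is flagged and warned about, not
  silently truncated.

## The synthetic-data generator

`simulateDataset()` emulates the plating experiment the models were tested
against: a stationary-phase culture of about $10^8$ CFU/ml with 3 ml per
dish ($N_0 = 3\times10^8$ by default), exposures every 30 s up to 300 s,
triplicate series, five decimal serial dilutions, and a fluence rate of
2.75 mJ/(s·cm²) attached as metadata only (the model is parameterized by
time, not dose; the printed dose bookkeeping for this design is internally
inconsistent by a factor of ten, so only per-cm² fluence is recorded).

Design choices:

- **Noise.** Poisson plate counts — the canonical CFU counting model; the
  experiment itself specifies none. An optional mean-preserving lognormal
  multiplier on the Poisson intensity (`poisson_lognormal`) covers
  real-plate overdispersion in robustness tests, and `none` gives exact
  expected counts, making the generator the exact inverse of
  `countsToSurvivors()` + `fitSurvival()` (machine-precision recovery,
  asserted in tests).
- **Dilution selection.** For each time the simulator plates the dilution
  whose expected count falls in the standard countable window of 30–300
  colonies; when no dilution reaches the window it takes the closest on a
  log scale (ties resolve to the lower dilution). The chosen factor is
  recorded per record.
- **Clamping.** Expected survivors are clamped at zero before sampling;
  designs entirely beyond the absolute death time warn.
- **True k default (5e7 s⁻¹).** Mid-range of the strain-level estimates
  (2–7 ×10⁷ s⁻¹) the model family reports.

`recoveryStudy()` wraps seeded simulate–fit loops and reports median
relative error, RMSE and slope-CI coverage with Monte Carlo standard
errors. Per-simulation seeds are pre-drawn from the master seed so results
do not depend on evaluation order. Simulations whose datasets leave fewer
than 3 positive distinct times (possible at the high-$k$ edge, where the
population is extinct within the first two exposures) are counted as
failures rather than silently dropped.

What the simulator does *not* emulate: repair-capable subpopulations and
tailing, shoulder effects from multi-hit survival curves, lamp geometry
and shading, plating efficiency below 1, and counting error beyond the
noise model. Passing recovery tests therefore show that *if* mortality is
log-linear in time with Poisson plate noise, the pipeline recovers its
parameters — not that real survival curves are log-linear.

## Proportionality accounting

`proportionalityCoefficient()` evaluates
$N_j/f(t_u) = \Phi_\mu n_0 h V_G / (2\sigma\lambda)$, which is exactly
$\Phi_\mu / \bar\Phi_\mu$; `photonsPerDimer()` is $D_p = 1/\Phi_\mu$ in
the model's numerical convention (the reciprocal of a per-(mol·erg·s)
yield read as a photon count; implemented as printed, without unit
reconciliation). Every (coefficient, $D_p$) pair multiplies to the
genome/wavelength constant $n_0 h V_G/(2\sigma\lambda) \approx 6.9275
\times 10^4$, the internal-consistency law the ten published rows obey to
better than 0.1%.

All rows of the published table — including the literature rows annotated
at 260/254 nm — are completed at $\lambda = 253.7$ nm: only that
wavelength reproduces every printed $D_p$ from its printed coefficient, so
the per-row wavelength column is treated as annotation. $D_p$ is rounded
to integer for display only; the exact value is retained.

$\gamma_{abs}$ (absorbed photons per cell) is never measured here;
`cqmyFromBudget()` exists for caller-supplied budgets.

The absorbed fraction is the *linear* expected impact count
$N^*\sigma\Delta x$, not a Beer–Lambert probability
$1 - e^{-Z\Delta x}$; the exponential variant is exposed separately
(`absorbedProbabilityBeerLambert()`) for comparison only, as the linear
form is the one the model's bookkeeping (and its printed value
$\delta = 0.6506$) uses.

## Numerical and testing choices

- Reciprocal/product identities ($\bar l Z = 1$, $f\Delta t_i = 1$,
  $k t_u = 1$, unitary mortality $\equiv 1$, the three $\delta$ forms) are
  tested at 1e-12 relative tolerance on randomized inputs.
- Property-style tests draw parameters with $N_0/k \in 10^{[-2,\,2.5]}$ so
  the landmark times $e^{N_0/2k}$ stay resolvable in double precision:
  for $N_0/2k \lesssim 10^{-5}$, $\mathrm{LDR}_{50} - 1$ itself is at the
  rounding floor and the analytic identity cannot be evaluated to 1e-12 in
  floating point (an evaluation limit, not a model property).
- Monte Carlo checks use $10^5$ photons and 3-standard-error bands; the
  recovery study uses 200 simulations (50 at each of
  $k = 2, 3.5, 5, 6.5 \times 10^7$ s⁻¹ at the reference design), sizes at
  which the whole suite runs in well under a minute while Monte Carlo
  standard errors stay a few percent.
- Published strain-level fit statistics ($R \in [0.9526, 0.9949]$,
  $R^2 \in [0.9074, 0.9898]$, $p \ge 0.045$) are not reproducible without
  the raw plate counts, which are not printed; the suite instead asserts
  exact recovery on noiseless data and accuracy/coverage on the seeded
  Poisson design above.

## Known limitations

- The log-time law has no shoulder and predicts unbounded mortality in
  $\ln t$; it is only meaningful on $1 \le t \le T$, and the package
  clamps and flags outside that window rather than extrapolating.
- $\Phi_\mu$ lumps repair biology into one constant; strain differences
  are visible only as different fitted constants, never mechanistically.
- $\sigma$ is wavelength-independent here (no action spectrum), and dimer
  chemistry is not partitioned by dinucleotide type.
- OLS assumes homoskedastic Gaussian errors; back-calculated CFU/ml from
  different dilutions violates this mildly, which shows up as slope-CI
  coverage slightly below nominal in the recovery study (still within the
  tested ±5 percentage-point band at 0.97).
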