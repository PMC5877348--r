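---
title: "Photocycle kinetics and spectral decomposition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photocycle kinetics and spectral decomposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodofit)
```

This vignette documents the models behind `rhodofit`, the assumptions
they make, the defaults and why they were chosen, and where the
analysis is expected to break down. The running example is a
halorhodopsin-like chloride pump: a retinal protein whose photocycle
carries a Cl⁻ ion across the membrane, with an N⇌O quasi-equilibrium
whose composition reports on chloride release.

## The sequential photocycle model

Flash photolysis measures ΔA(λ, t), the light-minus-dark absorbance
difference, here on a 400–710 nm grid at 10-nm intervals over
10 μs – 388 ms. We model the relaxation as an irreversible first-order
chain

$$P_0 \xrightarrow{h\nu} P_1 \xrightarrow{1/\tau_1} P_2 \to \cdots \to
P_n \xrightarrow{1/\tau_n} P_0 ,$$

with kinetically defined states: each $P_i$ may itself be a rapid
quasi-equilibrium of physical intermediates (L-, N-, O-like), in which
case its difference spectrum is the population-weighted mixture and the
chain stays $n$-state. The occupancies have the exact Bateman closed
form (`state_populations()`); its correctness is checked in the test
suite against a matrix-exponential oracle on random rate sets.

Two consequences structure the whole analysis:

1. The noiseless signal is exactly
   $\Delta A(\lambda,t)=\sum_i A_i(\lambda)\,e^{-t/\tau_i}$ — a global
   multi-exponential with shared time constants.
2. The amplitude spectra $A_i$ and the state difference spectra
   $\Delta\varepsilon_i$ are related by an exact triangular linear map
   (`amplitudes_from_states()` and its inverse), so no information is
   lost moving between the two representations.

Assumptions: no back-reactions or branches, distinct time constants
(equal τ are rejected as degenerate rather than handled with
polynomial-in-$t$ terms — measured photocycles have distinct τ, and the
restriction keeps the amplitude algebra exact), no sub-microsecond
(K-intermediate) kinetics, and no photoselection effects.

## Global fitting

`fit_global()` uses separable least squares (variable projection): for
any trial set of τ the per-wavelength amplitudes are the exact linear
least-squares solution, so only the τ are optimized nonlinearly. This is
the standard, stable formulation for global exponential analysis; it
cannot converge to a worse amplitude set than the linear optimum at the
final τ. Choices that matter:

* **Parameterization.** τ are optimized in log₁₀ space with box
  constraints `[artifact_cutoff/3, 10 × t_max]`: scale-free across the
  4.6 measured decades, and collapse onto one another is penalized by
  the geometry rather than by ad-hoc ordering constraints.
* **Initialization.** Log-equally spaced across the observed decades
  unless `init_tau_ms` is given.
* **Weighting.** Equal across wavelengths and times by default; a
  weight matrix is accepted.
* **Standard errors.** Gauss-Newton curvature of the projected residual
  at the optimum, delta-method back to ms. These treat the amplitudes
  as nuisance parameters solved exactly; no bootstrap is performed.
* **Degenerate input.** An all-zero matrix is returned with zero
  amplitudes, zero residual SD, τ at initialization and a
  `non_identifiable` flag rather than an error.

`select_n_exponents()` fits n = 1…max_n and picks the smallest n whose
relative residual-SD reduction to n+1 falls below 5%. The threshold is a
package default: the underlying criterion ("stop when adding a
component no longer reduces the residual SD appreciably") is inherently
qualitative, and 5% separates the sharp drops seen while real
components are missing (tens of percent) from the sub-1% flattening
beyond the true count at realistic noise. Each fit n > 1 is warm-started
from the previous solution with one extra component inserted in the
widest log-time gap; because the warm start's design matrix nests the
previous one, the residual SD is provably non-increasing in n (a
property the test suite asserts).

`reconstruct_states()` converts fitted amplitudes to
$\Delta\varepsilon_i$ through the chain algebra and adds the
unphotolyzed-state spectrum: states are reported with a refined
absorption maximum obtained by quadratic interpolation through the three
grid points around the maximum — necessary because a 10-nm grid cannot
otherwise resolve shifts smaller than one step.

## Band shapes and spectral decomposition

All bands are skewed Gaussians in wavenumber (Fraser-Suzuki form,
evaluated at ν = 10⁷/λ):

$$A(\nu)=A_{max}\exp\left\{-\ln 2\left[\frac{\ln\!\big(1+2b(\nu-\nu_{max})/\Delta\nu\big)}{b}\right]^2\right\},$$

defined as exactly zero where the logarithm's argument is non-positive,
with the analytic Gaussian limit used for |b| < 10⁻⁸. This form is
standard for retinal-protein absorption bands, which are near-symmetric
in energy rather than in wavelength; its mode is exactly at ν_max where
it equals A_max, which keeps reported positions interpretable. Band
fitting (`fit_bands()`) therefore works in wavenumber and reports both
cm⁻¹ and nm.

A pigment spectrum is modeled as main band + β-band + scattering
baseline $c\,(\lambda/550\,\text{nm})^{-4}$. The Rayleigh-like λ⁻⁴ term
represents residual scatter of detergent-solubilized samples; 550 nm is
an arbitrary reference that only rescales $c$. Multi-band fits have
local minima, so the fitter runs 5 seeded, jittered restarts and keeps
the lowest-residual solution. The default window is 400–710 nm,
matching the measured range; the 280-nm protein band and vibronic fine
structure are out of scope. How many components to use for extracting a
pure pigment spectrum is a user decision; the synthetic truth uses one
main band plus one β-band, and two components recover it exactly in the
tests.

## The N⇌O quasi-equilibrium state

With band shapes fixed, the third-state spectrum is linear in the
N-like fraction f, which therefore has a closed-form least-squares
solution, clipped to [0, 1] with a boundary flag (`decompose_p3()`).
The β-band is frozen to the unphotolyzed-state decomposition and never
refit — the underlying assumption is that the chromophore's secondary
band is unchanged between intermediates.

For a concentration series, `fit_shared_bands()` alternates between the
closed-form fractions (bands fixed) and a Levenberg-Marquardt refit of
the eight band parameters (fractions fixed), stopping when no fraction
moves by more than 10⁻⁴ or after 50 rounds. Block coordinate descent is
simple, monotone in the stacked residual, and reproducible. Its main
failure mode is a series whose fractions barely vary: the two bands are
then only weakly identified individually (any rotation of the pair that
preserves the observed mixtures fits equally well). At least three
distinct concentrations are required, and a flat series is caught
downstream by the release-constant fit's no-transition guard.

## Titration fits

The Hill model $y = a + b\,x^n/(x^n + K_d^n)$ is fitted by
Levenberg-Marquardt over $(a, b, \log_{10} K_d, n)$. Fitting $K_d$ in
log space keeps it positive and scale-free; the Hill coefficient is
bounded to [0.3, 5] to exclude pathological step-like fits. Standard
errors come from the curvature at the optimum ($K_d$ via the delta
method). The release-constant fit (`release_constant()`) stacks the
N-like and O-like fraction curves with shared $(a, b, K_d, n)$ and the
complementarity constraint $f_O = 1 - f_N$ built into the model; the
Hill coefficient of release is shared between the two branches but not
tied to the uptake fit's n.

Flat curves are rejected with a *no-transition* error. The naive rule
"amplitude below 3× the noise" fails here, because on flat noisy data
the optimizer absorbs noise into a sharp pseudo-step whose fitted
amplitude can reach several times the point noise. Instead the package
uses an F-test of the Hill model against the constant model
(α = 0.01): flat data give F ≈ 1 and are rejected; any real transition
at workable signal-to-noise gives F ≫ 10.

The Henderson-Hasselbalch fit (`fit_pka()`) models the alkaline rise of
the 380-nm deprotonated-Schiff-base band as
$\Delta A = s/(1+10^{pK_a - pH})$ with the amplitude scale s fitted, so
raw (un-normalized) data are accepted. The fitted curve crosses $s/2$
exactly at the pKa by construction. Decreasing ΔA with pH violates the
sign convention and errors; a pH window that does not bracket the
transition triggers a poorly-constrained warning, and a pKa outside
4–14 a sanity warning.

## The synthetic-data generator

`rmhr_scenario()` fixes the study conditions all generators share: four
time constants (0.105, 0.483, 2.14, 23.5 ms), state maxima 510, 510,
{520, 590} mixture, 540 nm, an unphotolyzed-state maximum titrating
from 550 nm (unbound) to 542 nm (saturated) with $K_{d,int}$ = 7.6 mM
and n = 1.2, a release constant of 308 mM, and Schiff-base pKa 7.3 (low
salt) / 10 (high salt). Sample peak OD is 0.5. Band shapes (FWHM
3500 cm⁻¹, skew 0.2) and the β-band (25 000 cm⁻¹, 15% of the main-band
amplitude) are generator conventions — published characterizations of
such pumps report the maxima but not the band widths or skews.

Noise defaults: 0.3 nm on fitted absorption maxima, 5×10⁻⁴ ΔOD on flash
traces (consistent with 30-flash averaging at this OD), 10⁻³ OD on
spectra, 0.02 on normalized ΔA, and 0.005 on fraction observables — the
last is not an independent dial but the propagated uncertainty of a
fraction estimated by the linear decomposition from spectra carrying
10⁻³ OD noise.

Conventions worth knowing:

* Difference spectra are expressed **per unit photolyzed population**
  ($\Delta\varepsilon_i$ = state band − P₀ band at full scale), so that
  adding the P₀ spectrum to a fitted difference spectrum recovers the
  pure state spectrum. Analyses of real data with partial photolysis
  must scale their difference spectra to full conversion before
  reconstruction, as is standard practice.
* The time grid is log-spaced at 30 points/decade over 10 μs – 388 ms
  (139 points), matching flash-photolysis acquisition over 4.6 decades.
* For concentration titrations the generator records the Na₂SO₄
  concentration (0–1.333 M) that would hold ionic strength at 4 M; it
  is metadata only and enters no fit, since sulfate is not a substrate.
* Every generator attaches its generating truth, so recovery tests
  never re-derive it, and all noise is seeded: identical
  scenario + seed gives bit-identical output.

What the generator does **not** emulate: correlated baseline drift,
wavelength-dependent variance, shot-noise statistics of flash
averaging, photoselection, or temperature effects. Noise is i.i.d.
Gaussian throughout. Passing recovery tests therefore demonstrates the
estimators are correct and well-conditioned at realistic noise levels —
not that they are robust to structured instrumental artifacts.

## Measurement preparation

`load_flash_dataset()` reproduces the two standard preparation steps:
rows recorded before the laser pulse (t ≤ 0) define a per-wavelength
baseline that is subtracted and dropped, and rows earlier than the
artifact cutoff (default 10 μs, where laser scattering contaminates the
signal) are discarded — a hard trim, not a down-weighting. CSV writers
emit 17-significant-digit floats so doubles round-trip exactly.

## Problem sizes and statistical expectations

The shipped tests and the acceptance script run the full pipeline at
the native measurement size (32 wavelengths × 139 time points; 12-point
titrations; 8-spectrum concentration series), each stage in well under a
minute. Repeat-seed simulation at these designs shows: all four time
constants recover with median error below 5% at 5×10⁻⁴ ΔOD noise; the
release constant recovers within a few percent via the decomposition
route; and the uptake-constant fit has a sampling SD of about 1.2 mM
around an unbiased center — so individual seeds scatter across the
±1.7 mM band that a single measurement of this design supports, and its
median relative error is ≈11–12%, a floor set by the design
(12 points, 0.3 nm noise on an 8-nm amplitude), not by the optimizer.

## Known limitations

* Only irreversible sequential schemes: no branched or reversible
  target analysis, and no SVD-based rank analysis. The sequential
  assumption is itself the resolution of rotational ambiguity.
* Close time constants (ratio < 1.01) are flagged as ill-conditioned;
  components closer than the noise allows merge, and the selection
  criterion will (correctly) report fewer exponents than the generating
  truth.
* The fitted τ standard errors condition on the selected model; model
  uncertainty in the exponent count is not propagated.
* Band decomposition assumes the skewed-Gaussian family; strongly
  vibronically structured spectra need a different band model.
* No activity-coefficient corrections at molar ionic strengths, and no
  thermodynamic linkage between the pKa and Cl⁻ binding — the two
  titrations are treated independently.
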