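# rhodofit

Photocycle kinetics and spectral decomposition for light-driven
ion-pumping rhodopsins.

Microbial rhodopsins that pump ions (H⁺, Na⁺, Cl⁻) traverse a cyclic
sequence of spectrally distinct intermediates after absorbing a photon.
Time-resolved flash photolysis records this photocycle as a
wavelength × time matrix of absorbance differences; equilibrium UV-Vis
titrations characterize substrate binding to the resting state and the
protonation state of the retinal Schiff base. `rhodofit` implements the
complete analysis chain for such measurements, aimed at spectroscopists
characterizing chloride-pumping rhodopsins (halorhodopsin-like pumps),
and ships a synthetic-data module so every stage can be validated by
parameter recovery against a known ground truth.

## The models

**Sequential photocycle.** Flash-induced absorbance differences are
modeled by an irreversible first-order chain
P₀ → P₁ → … → Pₙ → P₀ with time constants τ₁…τₙ. The occupancy of each
kinetic state has the exact Bateman closed form, so the noiseless signal
is a sum of exponentials

ΔA(λ, t) = Σᵢ Aᵢ(λ) e^(−t/τᵢ),

and the amplitude spectra Aᵢ(λ) are linked to the state difference
spectra Δεᵢ(λ) = spectrum(Pᵢ) − spectrum(P₀) by an exact triangular
linear map (`amplitudes_from_states()` / `states_from_amplitudes()`).
`fit_global()` fits all wavelengths simultaneously with shared τᵢ by
separable (variable-projection) least squares;
`select_n_exponents()` chooses the number of components from the
reduction in residual standard deviation; `reconstruct_states()` adds
the unphotolyzed-state spectrum to each Δεᵢ to give the absolute
intermediate spectra.

**Band shapes.** Absorption bands are skewed Gaussians (Fraser-Suzuki
form) in wavenumber,

A(ν) = A_max · exp{ −ln2 · [ln(1 + 2b(ν − ν_max)/Δν) / b]² },

with position ν_max, FWHM Δν and skew b (`skewed_gaussian_band()`,
`fit_bands()`). A pigment spectrum is a main visible band plus the
chromophore β-band plus an optional λ⁻⁴ scattering baseline.

**N⇌O quasi-equilibrium.** In chloride pumps one kinetic state is a
rapid mixture of a Cl⁻-bound (N-like, blue) and Cl⁻-released (O-like,
red) intermediate. With fixed band shapes its spectrum is

Abs(P₃, λ) = f·Abs(N, λ) + (1−f)·Abs(O, λ) + Abs(β, λ),

and the N-like fraction f is the single Cl⁻-dependent parameter
(`decompose_p3()`, closed-form; `fit_shared_bands()` for a whole
concentration series with shared band shapes).

**Titrations.** Ligand binding follows the Hill equation
y = a + b·xⁿ/(xⁿ + K_dⁿ) (`fit_hill()`); fitting the f(Cl⁻) curves
jointly yields the release constant K_d,rel and its fold-ratio to the
uptake constant K_d,int (`release_constant()`). Schiff-base deprotonation
follows Henderson-Hasselbalch, ΔA = s/(1 + 10^(pKa − pH))
(`fit_pka()`).

## Worked example

The default scenario emulates a marine-bacterial chloride pump: a
four-state photocycle (τ = 0.105, 0.483, 2.14, 23.5 ms), intermediates
peaking at 510, 510, {520/590 mixture}, 540 nm, uptake constant 7.6 mM
(Hill n 1.2), release constant 308 mM, Schiff-base pKa 7.3 at low salt.

```r
library(rhodofit)
sc  <- rmhr_scenario()
sim <- make_flash_dataset(sc, seed = 42)          # 32 wavelengths x 139 times
sel <- select_n_exponents(sim$dataset, max_n = 6)
fit <- fit_global(sim$dataset, sel$n_selected)
st  <- reconstruct_states(fit, sim$truth$p0_spectrum)
print(fit)
print(st)
```

```
<global_fit_result: 4 exponents, residual SD 0.000497 dOD>
  tau_ms   se_ms
  0.1053 0.00155
  0.4842 0.00265
  2.1430 0.00677
 23.9000 0.25400
<state_spectra_set: P0 + 4 states; lambda_max(P0) = 542.0 nm>
   P1    P2    P3    P4
509.9 510.1 524.7 540.0
```

All four time constants come back within 2% of the generating truth and
the reconstructed state maxima sit on the generating band positions
(P₃ peaks between 520 and 590 nm because it is an 80/20 N/O mixture at
1 M Cl⁻). The equilibrium side:

```r
hill <- fit_hill(make_titration(sc, "lambda_max", n_points = 12, seed = 43))
ser  <- make_p3_series(sc, seed = 44)
sb   <- fit_shared_bands(ser, beta = ser$beta)
rel  <- release_constant(sb$fractions, kd_int_mM = hill$Kd)
pka  <- fit_pka(make_titration(sc, "deltaA_380", n_points = 10, seed = 45))
print(hill); print(rel); print(pka)
```

```
<hill_fit: Kd = 7.398 +/- 1.6 mM, n = 1.13 +/- 0.2, a = 550, b = -8.077 (rsd 0.279)>
<hill_fit: Kd = 304.9 +/- 1.4 mM, n = 1.19 +/- 0.0053, a = -0.01515, b = 1.017 (rsd 0.000565)>
  release/uptake Kd fold-ratio: 41.2
<pka_fit: pKa = 7.342 +/- 0.018 (scale 1.01, rsd 0.0119)>
```

The uptake constant (7.4 mM), release constant (305 mM, ~41-fold
larger) and pKa (7.34) recover their generating values; `fit_shared_bands`
locates the N-like and O-like bands at 520.0 and 589.8 nm. Collect
everything with `photocycle_report()` / `write_report_json()`.

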