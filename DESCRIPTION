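Package: rhodofit
Title: Photocycle Kinetics and Spectral Decomposition for Ion-Pumping
    Rhodopsins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the spectroscopic characterization of microbial
    ion-pumping rhodopsins from UV-Vis and time-resolved flash-photolysis
    data. Provides global multi-exponential fitting of
    wavelength-by-time absorbance-difference matrices under an
    irreversible sequential photocycle model, exact algebra linking
    exponential amplitudes to kinetic-state difference spectra,
    reconstruction of absolute intermediate-state spectra,
    skewed-Gaussian (Fraser-Suzuki) band decomposition in wavenumber,
    decomposition of a quasi-equilibrium N/O mixture state into its
    chloride-dependent fractions, and Hill and Henderson-Hasselbalch
    titration fits for ligand-binding constants and Schiff-base pKa.
    A synthetic-data module generates all supported input kinds from
    known ground truths so every analysis stage can be validated by
    parameter recovery.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
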