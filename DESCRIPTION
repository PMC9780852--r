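Package: focalcbs
Title: Focal-Point Assembly and Complete-Basis-Set Extrapolation of
    Intermolecular Interaction Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composing CCSD(T)-quality complete-basis-set (CBS)
    intermolecular interaction energies from tabulated absolute electronic
    energies: counterpoise correction of supermolecular differences,
    two-point CBS extrapolation kernels for the mean-field, MP2-correlation
    and post-MP2 energy components (including refit exponents for the
    aug-cc-pVDZ/aug-cc-pVTZ pair), a three-point mixed Gaussian/exponential
    extrapolation, composite focal-point schemes, nonlinear least-squares
    refitting of extrapolation exponents against reference energies,
    bookkeeping and classification of DFT-SAPT energy decompositions, and
    the regression/deviation statistics used to certify agreement between
    interaction-energy data sets.  A seeded synthetic-data generator
    emulates basis-set convergence so every operation is testable without
    external quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
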