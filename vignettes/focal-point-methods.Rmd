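---
title: "Focal-point CBS interaction energies: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal-point CBS interaction energies: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalcbs)
```

## The model

The interaction energy of a dimer at fixed monomer geometries is the
supermolecular difference ΔE = E(dimer) − E(monomer A) − E(monomer B),
negative when the complex is bound. Two systematic errors dominate finite
calculations of ΔE: basis-set superposition error, removed here by the
counterpoise recipe (both monomers evaluated in the full dimer basis), and
basis-set incompleteness, removed by extrapolating over the cardinal number
X of the correlation-consistent basis family (X = 2, 3, 4, 5 for the
augmented double- through quintuple-zeta sets).

The package decomposes every counterpoise-corrected ΔE into three parts
that converge at very different rates and are therefore treated with
different models:

* the **mean-field (Hartree–Fock) part**, which converges roughly
  exponentially, modelled as `E(X) = E_CBS + A·exp(α√X)` with α < 0;
* the **MP2-correlation part**, which converges as an inverse power,
  `E(X) = E_CBS + A·X^(−β)` with β > 0 (β = 3 is the textbook cubic rule);
* the **post-MP2 correction** — CCSD(T) correlation minus MP2
  correlation — extrapolated as the difference of a γ-extrapolated
  CCSD(T)-correlation term and a β-extrapolated MP2-correlation term.

Each two-point kernel inverts its model exactly through two cardinals:
writing d(X) for the decay factor, `E_CBS = (d_hi·e_lo − d_lo·e_hi) /
(d_hi − d_lo)`. Consequently the kernels have *zero* residual error on
data that follow their model; all real extrapolation error comes from
model violation, and that is how the synthetic generator parameterises
difficulty (below).

Three composite schemes ship with the package, ordered by cost of the
underlying quantum-chemical data:

| scheme | data needed | treatment |
|---|---|---|
| `canonical_a5z` | a5Z (HF, MP2), aTZ (post-MP2) | no extrapolation; the reference recipe |
| `focal_atz_aqz` | aTZ + aQZ, all components | HF taken at aQZ; both correlation parts cubic-extrapolated |
| `fit_adz_atz` | aDZ + aTZ, all components | all three parts extrapolated with refit exponents |

plus a `three_point` cross-check that extrapolates *total* fragment
energies with the mixed Gaussian/exponential form
`E(X) = E_CBS + B·e^{−(X−1)} + C·e^{−(X−1)²}` over three consecutive
cardinals. With the two exponential factors fixed, this is an exact 3×3
linear solve, not a nonlinear fit; the test suite verifies it against an
independent Levenberg–Marquardt solver.

## Parameters that matter

* **α = −4.473, β = 2.796, γ = 2.741** (dimensionless; `fit_params()`
  defaults). These are the exponents calibrated for the (aDZ, aTZ) pair
  against quintuple-zeta-quality reference energies; they replace the
  conventional α ≈ −4…−5 and β = γ = 3 when only the two smallest bases
  are affordable. They are ordinary arguments, not constants — any user
  value passing the sign constraints (α < 0, β > 0, γ > 0) is accepted.
* **1 hartree = 2625.499639 kJ/mol.** The conversion is pinned to this
  CODATA-derived factor so that round-trips are bit-reproducible across
  machines.
* **Cardinal mapping aDZ = 2 … a5Z = 5**, the standard correlation-
  consistent convention; the data model stores the integer only.
* **Classification thresholds (0.5, 1.5)** on the dispersion-to-
  polarization ratio |E_disp|/|E_pol|: below 0.5 electrostatics-dominated,
  above 1.5 dispersion-dominated, mixed in between. On the packaged
  18-dimer benchmark table the three groups occupy the ranges ≤ 0.36,
  0.69–1.09 and ≥ 1.76, so the defaults sit comfortably inside both gaps;
  they are arguments, not constants.
* **SAPT rounding guards**: a reported total further than 0.25 kJ/mol from
  its component sum draws a warning (the packaged table, printed to one
  decimal, stays within 0.1); a negative exchange component warns but is
  kept, since the user may legitimately hold non-equilibrium geometries.

## The exponent refits

`fit_alpha()`, `fit_beta()` and `fit_gamma()` reproduce the calibration
procedure: the exponent minimises the unweighted sum of squared
differences between the two-point extrapolation of low-cardinal energies
and a per-observation reference value. Design choices:

* **Minimiser**: Levenberg–Marquardt (`minpack.lm::nls.lm`), one free
  parameter, 200-iteration cap, parameter tolerance 1e−12. Convergence is
  reported, never assumed; a non-converged fit warns and still returns its
  best value. Box bounds keep the exponent in its physically meaningful
  sign half-line.
* **Starting points**: α from −4, β and γ from 3 — the conventional
  exponents. The test suite cross-checks every randomized fit against a
  dense grid search (resolution 1e−4), so the quoted minima are not an
  artefact of the starting point.
* **Degenerate designs**: when every low/high energy pair is numerically
  constant (already-converged data), the residuals carry no information
  about the exponent; the fit is flagged `degenerate` with a warning
  rather than returning an arbitrary number silently.
* **Reference semantics for γ**: the γ fit takes the reference post-MP2
  value per observation as user data and is agnostic about its provenance.
  The natural self-consistent choice — and the one the synthetic recovery
  tests use — is a CBS-quality post-MP2 reference, because asking the
  CBS-extrapolating functional form to match a *finite-basis* reference
  drives γ towards the degenerate large-exponent limit on model-consistent
  data. Residuals may be formed at the interaction level (kJ/mol) or on
  absolute correlation energies (hartree); the kernels are linear in
  energy, so the choice only sets the unit of `rss`.
* **Reporting**: full precision plus a 4-significant-digit rounding
  (`value_rounded`), the precision at which such exponents are customarily
  quoted.

## The synthetic-data generator

`generate_system()` forward-generates the full grid of absolute energies
(3 fragments × 3 method components × requested cardinals) from a
`system_spec()`: planted CBS interaction components (kJ/mol), monomer
baselines and amplitudes (hartree), per-component decay laws, and
interaction-level amplitudes that set how unconverged the interaction
components themselves are at finite X. Because the dimer's amplitude is
the monomer sum plus the interaction amplitude, counterpoise assembly
followed by extrapolation with the generating exponents reproduces the
planted components *exactly* at zero noise — the round-trip property the
test suite asserts at 1e−9 kJ/mol.

`generate_benchmark()` scales this to a collection: planted totals drawn
uniformly from a stated range (default 47 systems over −89…−2 kJ/mol,
matching the spread of published benchmark collections of small-to-medium
noncovalent dimers), component splits drawn from ranges typical of bound
dimers (MP2 correlation 50–110 % of the total, post-MP2 3–12 %), and SAPT
decompositions constructed to land in an assigned interaction class while
summing exactly to the planted total. Two knobs create realistic
difficulty:

* `noise_sd` — additive Gaussian noise on every absolute energy (hartree),
  emulating numerical thresholds of real programs; its propagation into
  composite totals is verified against a first-order (delta-method)
  prediction.
* `model_violation` — per-system relative perturbation of the decay
  exponents, emulating the fact that real components do not follow any
  single convergence model exactly. This, not noise, is what limits cheap
  extrapolation schemes in practice.

All randomness flows through explicit integer seeds (`withr::with_seed`);
no global RNG state is touched or left behind.

What the generator does **not** emulate: geometries and electronic
structure (there is no physics linking a planted ΔE to a plausible
molecule), correlated errors between components from a shared SCF, basis-
set effects that are not monotone in X, and local-correlation truncation
error that grows with system size. Passing round-trip tests therefore
demonstrates the correctness of the assembly/extrapolation algebra, not
the real-data accuracy of any exponent set.

## Numerical choices and degenerate inputs

* **Ill-conditioning guard**: a two-point kernel whose weights differ by
  less than 1e−12 (relative) raises a classed error instead of returning a
  cancellation-dominated number; degenerate cardinal pairs (x_lo ≥ x_hi)
  are rejected outright.
* **Steep-decay limit**: as α → −∞ the mean-field kernel smoothly
  approaches the higher-cardinal energy (the model says the point is
  converged), verified to 1e−6 at α = −50.
* **Incomplete data**: a missing (fragment, component, cardinal) record
  aborts with an error naming the absent triple; monomer records outside
  the dimer basis are treated as missing for counterpoise purposes, not
  silently substituted.
* **Symmetric dimers** are stored as two monomer records with equal
  energies; no deduplication is attempted in the data model.
* **Regression statistics** use the two-parameter adjusted R² formula
  `1 − (1 − R²)(n − 1)/(n − 2)` and n − 2 residual degrees of freedom;
  relative deviations are always quoted against the reference vector.

## Problem sizes

The shipped test suite runs entirely on synthetic data built at run time:
kernel-exactness sweeps use a few hundred random instances, the
three-point-vs-solver comparison 1,000 instances, exponent-recovery
problems 58 observations (with 1e−5 hartree reference noise), and the
end-to-end benchmark regression 47 systems — sizes chosen to mirror the
calibration sets this methodology is typically built on while keeping the
whole suite in the tens of seconds on one CPU.

## Known limitations

* The package never computes energies; garbage tables in, garbage CBS
  limits out. Only schema-level validation is performed.
* The refit exponents are calibrated for the (aDZ, aTZ) pair; the kernels
  accept any cardinal pair, but applying (aDZ, aTZ)-calibrated exponents
  to other pairs is the user's responsibility.
* The dispersion-to-polarization ratio is undefined at E_pol = 0 and
  ambiguous for repulsive-electrostatics complexes (|E_disp|/|E_pol|
  ignores the sign of E_pol); classification of such systems should not be
  over-interpreted.
* The three-point scheme reports only a total (its parts are not defined),
  and the mixed Gaussian/exponential exponents are fixed by construction,
  not refittable.
* Monomer deformation energy is out of scope: geometries are assumed
  rigid, so ΔE is the pure supermolecular difference.
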