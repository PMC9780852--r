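## Seeded synthetic-data generator.
##
## Emulates the basis-set convergence structure the focal-point schemes
## assume: for every fragment, the mean-field component decays
## exponentially in sqrt(X) towards its CBS value, and the correlation
## components decay as inverse powers of X.  Planted interaction components
## (kJ/mol at the CBS limit) and per-component interaction amplitudes (the
## finite-basis incompleteness of the interaction energy itself) are split
## into absolute fragment energies, so counterpoise assembly followed by
## the matching extrapolation recovers the planted values exactly at zero
## noise.  Optional additive Gaussian noise on absolute energies (hartree)
## and a "model violation" knob (per-system perturbation of the decay
## exponents) emulate what actually limits the cheap scheme on real data.

#' Specify one synthetic dimer system
#'
#' Defines the planted CBS interaction components, the decay model and the
#' fragment baselines of a synthetic system.  Energies are in hartree
#' except the planted interaction components and interaction amplitudes
#' (kJ/mol).  Monomer amplitudes are the finite-basis errors of the
#' monomer energies; interaction amplitudes (`int_amp_*`) the additional
#' incompleteness of the dimer relative to the monomer sum, which is what
#' the extrapolation kernels act on after counterpoise assembly.
#'
#' @param system_id System label.
#' @param de_hf,de_mp2corr,de_postmp2 Planted CBS interaction components
#'   (kJ/mol; negative = binding).
#' @param alpha,beta,gamma Decay exponents of the mean-field,
#'   MP2-correlation and CCSD(T)-correlation components.
#' @param mono_hf,mono_mp2,mono_post Named length-2 vectors (`A`, `B`):
#'   monomer CBS baselines (hartree) for the mean-field energy, the MP2
#'   correlation energy, and the post-MP2 part of the correlation energy.
#' @param amp_hf,amp_mp2,amp_ccsdt Named length-2 vectors (`A`, `B`):
#'   monomer decay amplitudes (hartree, positive = converging from above).
#' @param int_amp_hf,int_amp_mp2,int_amp_ccsdt Interaction-level decay
#'   amplitudes (kJ/mol).
#' @param noise_sd Standard deviation of additive Gaussian noise on every
#'   absolute energy (hartree); requires `seed` when positive.
#' @param seed Integer seed for the noise stream (no global state is
#'   touched).
#' @return A list of class `"system_spec"`.
#' @export
system_spec <- function(system_id = "synthetic",
                        de_hf = -20, de_mp2corr = -15, de_postmp2 = -3,
                        alpha = -4.473, beta = 2.796, gamma = 2.741,
                        mono_hf   = c(A = -155.0, B = -76.0),
                        mono_mp2  = c(A = -0.60,  B = -0.25),
                        mono_post = c(A = -0.020, B = -0.008),
                        amp_hf    = c(A = 0.60,  B = 0.40),
                        amp_mp2   = c(A = 0.30,  B = 0.15),
                        amp_ccsdt = c(A = 0.33,  B = 0.17),
                        int_amp_hf = 0.5, int_amp_mp2 = 4.0,
                        int_amp_ccsdt = 4.8,
                        noise_sd = 0, seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    rlang::abort("`noise_sd` must be >= 0.", class = "focalcbs_invalid_params")
  }
  if (noise_sd > 0 && is.null(seed)) {
    rlang::abort("a `seed` is required when `noise_sd` > 0.",
                 class = "focalcbs_invalid_params")
  }
  if (!(alpha < 0 && beta > 0 && gamma > 0)) {
    rlang::abort("need alpha < 0, beta > 0, gamma > 0.",
                 class = "focalcbs_invalid_params")
  }
  for (v in list(mono_hf, mono_mp2, mono_post, amp_hf, amp_mp2, amp_ccsdt)) {
    if (!all(c("A", "B") %in% names(v)) || any(!is.finite(v))) {
      rlang::abort("fragment vectors must be finite with names A and B.",
                   class = "focalcbs_invalid_params")
    }
  }
  structure(
    list(system_id = system_id,
         de_hf = de_hf, de_mp2corr = de_mp2corr, de_postmp2 = de_postmp2,
         alpha = alpha, beta = beta, gamma = gamma,
         mono_hf = mono_hf, mono_mp2 = mono_mp2, mono_post = mono_post,
         amp_hf = amp_hf, amp_mp2 = amp_mp2, amp_ccsdt = amp_ccsdt,
         int_amp_hf = int_amp_hf, int_amp_mp2 = int_amp_mp2,
         int_amp_ccsdt = int_amp_ccsdt,
         noise_sd = noise_sd, seed = seed),
    class = "system_spec")
}

.decay <- function(component, x, spec) {
  switch(component,
         HF         = exp(spec$alpha * sqrt(x)),
         MP2_corr   = x^(-spec$beta),
         CCSDT_corr = x^(-spec$gamma))
}

## CBS value and decay amplitude (both hartree) for one fragment/component.
.frag_model <- function(spec, fragment, component) {
  pick <- function(v) switch(fragment, monomer_A = v[["A"]],
                             monomer_B = v[["B"]], dimer = sum(v))
  base <- switch(component,
    HF         = pick(spec$mono_hf),
    MP2_corr   = pick(spec$mono_mp2),
    CCSDT_corr = pick(spec$mono_mp2) + pick(spec$mono_post))
  amp <- switch(component,
    HF         = pick(spec$amp_hf),
    MP2_corr   = pick(spec$amp_mp2),
    CCSDT_corr = pick(spec$amp_ccsdt))
  if (fragment == "dimer") {
    de <- switch(component,
      HF         = spec$de_hf,
      MP2_corr   = spec$de_mp2corr,
      CCSDT_corr = spec$de_mp2corr + spec$de_postmp2)
    int_amp <- switch(component,
      HF         = spec$int_amp_hf,
      MP2_corr   = spec$int_amp_mp2,
      CCSDT_corr = spec$int_amp_ccsdt)
    base <- base + kjmol_to_hartree(de)
    amp  <- amp + kjmol_to_hartree(int_amp)
  }
  c(cbs = base, amp = amp)
}

#' Generate the absolute-energy table of one synthetic system
#'
#' Emits the full grid of 3 fragments x 3 method components x requested
#' cardinals, with monomers in the dimer basis.  At `noise_sd = 0`,
#' counterpoise assembly plus extrapolation with the generating exponents
#' reproduces the planted CBS interaction components exactly; generation
#' is reproducible per seed.
#'
#' @param spec A [system_spec()].
#' @param cardinals Integer vector of basis cardinals (subset of 2:5).
#' @return A validated energy table.
#' @export
generate_system <- function(spec, cardinals = 2:5) {
  if (!inherits(spec, "system_spec")) {
    rlang::abort("`spec` must be a system_spec.",
                 class = "focalcbs_invalid_params")
  }
  if (!all(cardinals %in% CARDINALS)) {
    rlang::abort("cardinals must lie in {2, 3, 4, 5}.",
                 class = "focalcbs_invalid_params")
  }
  grid <- expand.grid(fragment = FRAGMENTS, component = COMPONENTS,
                      cardinal = sort(as.integer(cardinals)),
                      stringsAsFactors = FALSE)
  energy <- mapply(function(frag, comp, card) {
    fm <- .frag_model(spec, frag, comp)
    fm[["cbs"]] + fm[["amp"]] * .decay(comp, card, spec)
  }, grid$fragment, grid$component, grid$cardinal)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
      stats::rnorm(nrow(grid), 0, spec$noise_sd))
    energy <- energy + noise
  }
  energy_table(
    system_id      = spec$system_id,
    fragment       = grid$fragment,
    component      = grid$component,
    cardinal       = grid$cardinal,
    basis_context  = "dimer_basis",
    energy_hartree = energy,
    provenance     = "synthetic")
}

#' Planted CBS interaction components of a synthetic system
#'
#' @param spec A [system_spec()].
#' @return A one-row tibble: `system_id`, `dE_HF`, `dE_MP2corr`,
#'   `dE_postMP2`, `dE_total` (kJ/mol).
#' @export
planted_components <- function(spec) {
  tibble::tibble(
    system_id  = spec$system_id,
    dE_HF      = spec$de_hf,
    dE_MP2corr = spec$de_mp2corr,
    dE_postMP2 = spec$de_postmp2,
    dE_total   = spec$de_hf + spec$de_mp2corr + spec$de_postmp2)
}

#' Finite-basis residual of the canonical composite on a synthetic system
#'
#' The canonical scheme takes quintuple-zeta mean-field and MP2 components
#' and the triple-zeta post-MP2 component without extrapolation, so on
#' model-consistent data it misses the planted CBS total by the decayed
#' interaction amplitudes.  This returns that residual (kJ/mol), i.e.
#' `compose_canonical(total) - planted total` at zero noise.
#'
#' @param spec A [system_spec()].
#' @return Residual in kJ/mol.
#' @export
canonical_residual <- function(spec) {
  spec$int_amp_hf * exp(spec$alpha * sqrt(5)) +
    spec$int_amp_mp2 * 5^(-spec$beta) +
    (spec$int_amp_ccsdt * 3^(-spec$gamma) -
       spec$int_amp_mp2 * 3^(-spec$beta))
}

#' Specify a synthetic benchmark collection
#'
#' @param n_systems Number of dimer systems.
#' @param de_range Interval (kJ/mol, negative) from which planted total
#'   interaction energies are drawn uniformly; the benchmark emulating the
#'   reference study uses 47 systems spanning about -89 to -2 kJ/mol.
#' @param class_mix Fractions (summing to 1, order: electrostatics-
#'   dominated, mixed, dispersion-dominated) of interaction classes.
#' @param model_violation Relative scale of per-system Gaussian
#'   perturbation of the decay exponents (0 = model-consistent data).
#' @param noise_sd Additive noise on absolute energies (hartree).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(n_systems = 47, de_range = c(-89, -2),
                           class_mix = c(electrostatics_dominated = 1/3,
                                         mixed = 1/3,
                                         dispersion_dominated = 1/3),
                           model_violation = 0, noise_sd = 0, seed = 1) {
  if (length(de_range) != 2 || !all(is.finite(de_range)) ||
      de_range[1] >= de_range[2]) {
    rlang::abort("`de_range` must be a non-empty increasing interval.",
                 class = "focalcbs_invalid_params")
  }
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    rlang::abort("`class_mix` fractions must be non-negative and sum to 1.",
                 class = "focalcbs_invalid_params")
  }
  if (n_systems < 1) {
    rlang::abort("`n_systems` must be >= 1.",
                 class = "focalcbs_invalid_params")
  }
  structure(
    list(n_systems = as.integer(n_systems), de_range = de_range,
         class_mix = class_mix, model_violation = model_violation,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "benchmark_spec")
}

.CLASSES <- c("electrostatics_dominated", "mixed", "dispersion_dominated")

## SAPT components consistent with a target class under the (0.5, 1.5)
## thresholds, summing exactly to the planted total.
.sapt_for_class <- function(de_total, class) {
  r <- switch(class,
    electrostatics_dominated = stats::runif(1, 0.20, 0.45),
    mixed                    = stats::runif(1, 0.70, 1.30),
    dispersion_dominated     = stats::runif(1, 1.80, 4.00))
  m <- 1.5 * abs(de_total) / (1 + r)
  c(e_pol  = -m,
    e_exch = de_total + m * (1.2 + r),
    e_ind  = -0.2 * m,
    e_disp = -r * m)
}

#' Generate a synthetic benchmark collection
#'
#' Draws planted CBS interaction components for `n_systems` dimers, builds
#' the per-system energy tables, SAPT decompositions consistent with each
#' system's assigned interaction class, and a truth table of planted
#' values.  With `model_violation = 0` and `noise_sd = 0` the fitted
#' (aDZ, aTZ) scheme run with the generating exponents reproduces the
#' truth exactly.
#'
#' @param spec A [benchmark_spec()].
#' @param cardinals Basis cardinals to emit (default 2:5).
#' @return A list: `energies` (energy table for all systems), `sapt`
#'   (SAPT table with `group_label`), `truth` (planted components and
#'   totals), `specs` (the per-system [system_spec()]s).
#' @export
generate_benchmark <- function(spec, cardinals = 2:5) {
  if (!inherits(spec, "benchmark_spec")) {
    rlang::abort("`spec` must be a benchmark_spec.",
                 class = "focalcbs_invalid_params")
  }
  n <- spec$n_systems
  ## fixed class counts honouring the mix as closely as possible
  counts <- diff(round(cumsum(c(0, spec$class_mix)) * n))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  classes <- rep(.CLASSES, times = counts)

  withr::with_seed(spec$seed, {
    specs <- vector("list", n)
    sapt_rows <- vector("list", n)
    for (i in seq_len(n)) {
      de_total <- stats::runif(1, spec$de_range[1], spec$de_range[2])
      f_mp2    <- stats::runif(1, 0.50, 1.10)
      f_post   <- stats::runif(1, 0.03, 0.12)
      de_mp2   <- f_mp2 * de_total
      de_post  <- f_post * de_total
      de_hf    <- de_total - de_mp2 - de_post
      mv       <- spec$model_violation
      perturb  <- function(v) v * (1 + mv * stats::rnorm(1))
      specs[[i]] <- system_spec(
        system_id   = sprintf("synth_%02d", i),
        de_hf = de_hf, de_mp2corr = de_mp2, de_postmp2 = de_post,
        alpha = min(perturb(-4.473), -0.5),
        beta  = max(perturb(2.796), 0.5),
        gamma = max(perturb(2.741), 0.5),
        mono_hf   = c(A = -stats::runif(1, 50, 300),
                      B = -stats::runif(1, 50, 300)),
        mono_mp2  = c(A = -stats::runif(1, 0.3, 1.2),
                      B = -stats::runif(1, 0.2, 0.8)),
        mono_post = c(A = -stats::runif(1, 0.005, 0.04),
                      B = -stats::runif(1, 0.003, 0.02)),
        amp_hf    = c(A = stats::runif(1, 0.2, 1.0),
                      B = stats::runif(1, 0.2, 1.0)),
        amp_mp2   = c(A = stats::runif(1, 0.1, 0.4),
                      B = stats::runif(1, 0.1, 0.4)),
        amp_ccsdt = c(A = stats::runif(1, 0.1, 0.45),
                      B = stats::runif(1, 0.1, 0.45)),
        int_amp_hf    = stats::runif(1, 0.2, 1.0),
        int_amp_mp2   = stats::runif(1, 2, 6),
        int_amp_ccsdt = stats::runif(1, 2, 7),
        noise_sd = spec$noise_sd,
        seed = if (spec$noise_sd > 0) sample.int(.Machine$integer.max, 1)
               else NULL)
      sapt_rows[[i]] <- c(.sapt_for_class(de_total, classes[[i]]))
    }
  })

  energies <- dplyr::bind_rows(lapply(specs, generate_system,
                                      cardinals = cardinals))
  sapt <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    row <- sapt_rows[[i]]
    tibble::tibble(system_id = specs[[i]]$system_id,
                   e_pol = row[["e_pol"]], e_exch = row[["e_exch"]],
                   e_ind = row[["e_ind"]], e_disp = row[["e_disp"]],
                   e_total = sum(row), group_label = classes[[i]])
  }))
  truth <- dplyr::bind_rows(lapply(specs, planted_components))
  truth$group_label <- classes
  list(energies = energies, sapt = sapt_table(sapt), truth = truth,
       specs = specs)
}
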