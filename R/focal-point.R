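## Composite focal-point interaction-energy schemes.
##
## Each scheme adds a mean-field part, an MP2-correlation part and a
## post-MP2 part, all taken from counterpoise-corrected interaction-energy
## components (the arithmetic is identical to working on absolute energies,
## by linearity, and keeps the schemes applicable when only interaction
## components are archived):
##
##   canonical_a5z : dE_HF(a5Z) + dE_MP2corr(a5Z) + dE_postMP2(aTZ),
##                   no extrapolation — the canonical reference recipe.
##   focal_atz_aqz : dE_HF(aQZ) unextrapolated + cubic two-point
##                   extrapolation (X^3 weights) of the correlation parts
##                   over (aTZ, aQZ).
##   fit_adz_atz   : all three parts extrapolated from (aDZ, aTZ) with the
##                   refit exponents alpha/beta/gamma.
##   three_point   : cross-check scheme — the mixed Gaussian/exponential
##                   three-point extrapolation applied to total energies
##                   per fragment, then counterpoise-combined.

.components_at <- function(comp, card, scheme) {
  row <- comp[comp$cardinal == card, , drop = FALSE]
  if (nrow(row) != 1) {
    rlang::abort(
      sprintf("system '%s': scheme '%s' needs components at cardinal %d.",
              comp$system_id[[1]], scheme, card),
      class = "focalcbs_incomplete_data")
  }
  row
}

.composite_row <- function(system_id, scheme, hf, mp2, post) {
  tibble::tibble(
    system_id       = system_id,
    scheme          = scheme,
    dE_HF_part      = hf,
    dE_MP2_part     = mp2,
    dE_postMP2_part = post,
    dE_total        = hf + mp2 + post
  )
}

.per_system <- function(components, f) {
  dplyr::bind_rows(lapply(split(components, components$system_id), f))
}

#' Canonical focal-point interaction energy
#'
#' The reference composite: quintuple-zeta mean-field and MP2-correlation
#' interaction components plus the triple-zeta post-MP2 correction, with no
#' extrapolation.
#'
#' @param components A component table from [assemble_components()]
#'   containing cardinals 5 and 3 for each system.
#' @return A tibble with one row per system: the three parts and their sum
#'   `dE_total` (kJ/mol, negative = binding).
#' @export
compose_canonical <- function(components) {
  .per_system(components, function(comp) {
    c5 <- .components_at(comp, 5L, "canonical_a5z")
    c3 <- .components_at(comp, 3L, "canonical_a5z")
    .composite_row(comp$system_id[[1]], "canonical_a5z",
                   c5$dE_HF, c5$dE_MP2corr, c3$dE_postMP2)
  })
}

#' Focal-point interaction energy from (aTZ, aQZ) data
#'
#' The quadruple-zeta mean-field component is taken as converged
#' (unextrapolated); the MP2-correlation and post-MP2 components are
#' extrapolated over cardinals (3, 4) with the standard cubic two-point
#' rule (`beta = 3`).
#'
#' @param components A component table containing cardinals 3 and 4.
#' @return A tibble with one row per system (parts and total, kJ/mol).
#' @export
compose_focal <- function(components) {
  .per_system(components, function(comp) {
    c3 <- .components_at(comp, 3L, "focal_atz_aqz")
    c4 <- .components_at(comp, 4L, "focal_atz_aqz")
    .composite_row(
      comp$system_id[[1]], "focal_atz_aqz",
      c4$dE_HF,
      corr_two_point(c3$dE_MP2corr, c4$dE_MP2corr, 3, 4, beta = 3),
      corr_two_point(c3$dE_postMP2, c4$dE_postMP2, 3, 4, beta = 3))
  })
}

#' Fitted focal-point interaction energy from (aDZ, aTZ) data
#'
#' The cheap scheme: every part is extrapolated to the CBS limit from the
#' two smallest augmented bases, the mean-field part with the exponential
#' model (exponent `alpha`), the MP2-correlation part with the
#' inverse-power model (`beta`), and the post-MP2 part as the difference
#' of CCSD(T)- and MP2-correlation extrapolations (`gamma` and `beta`).
#'
#' @param components A component table containing cardinals 2 and 3.
#' @param params An [fit_params()] object; defaults to the refit exponents
#'   (-4.473, 2.796, 2.741).
#' @return A tibble with one row per system (parts and total, kJ/mol).
#' @export
compose_fitted <- function(components, params = fit_params()) {
  if (!inherits(params, "fit_params")) {
    params <- do.call(fit_params, as.list(params))
  }
  .per_system(components, function(comp) {
    c2 <- .components_at(comp, 2L, "fit_adz_atz")
    c3 <- .components_at(comp, 3L, "fit_adz_atz")
    ## post-MP2 via the gamma/beta difference needs the CCSD(T)-correlation
    ## components, which are dE_MP2corr + dE_postMP2 by definition.
    .composite_row(
      comp$system_id[[1]], "fit_adz_atz",
      hf_two_point(c2$dE_HF, c3$dE_HF, 2, 3, params$alpha),
      corr_two_point(c2$dE_MP2corr, c3$dE_MP2corr, 2, 3, params$beta),
      post_mp2_two_point(
        c2$dE_MP2corr + c2$dE_postMP2, c3$dE_MP2corr + c3$dE_postMP2,
        c2$dE_MP2corr, c3$dE_MP2corr, 2, 3,
        beta = params$beta, gamma = params$gamma))
  })
}

#' Three-point cross-check interaction energy
#'
#' Extrapolates the total energy (mean-field plus CCSD(T) correlation) of
#' each fragment with the mixed Gaussian/exponential three-point form over
#' three consecutive cardinals, then forms the counterpoise-corrected
#' difference of the CBS limits.  Serves as an independent cross-check of
#' the two-point focal-point schemes; the composite parts are not defined
#' for this route and are reported as `NA`.
#'
#' @param tab An energy table with all fragments and components at
#'   cardinals `x_start, x_start+1, x_start+2`.
#' @param x_start First cardinal of the series (default 3: aTZ/aQZ/a5Z).
#' @return A tibble with one row per system; only `dE_total` is populated.
#' @export
compose_three_point <- function(tab, x_start = 3) {
  tab   <- validate_energy_table(tab)
  cards <- x_start + 0:2
  dplyr::bind_rows(lapply(split(tab, tab$system_id), function(sys) {
    sid  <- sys$system_id[[1]]
    cbs  <- vapply(FRAGMENTS, function(frag) {
      tot <- vapply(cards, function(card) {
        .lookup_energy(sys, frag, "HF", card, sid) +
          .lookup_energy(sys, frag, "CCSDT_corr", card, sid)
      }, numeric(1))
      mixed_three_point(tot[[1]], tot[[2]], tot[[3]], x_start)$e_cbs
    }, numeric(1))
    tibble::tibble(
      system_id       = sid,
      scheme          = "three_point",
      dE_HF_part      = NA_real_,
      dE_MP2_part     = NA_real_,
      dE_postMP2_part = NA_real_,
      dE_total        = cp_interaction(cbs[["dimer"]],
                                       cbs[["monomer_A"]],
                                       cbs[["monomer_B"]])
    )
  }))
}
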