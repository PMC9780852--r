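## Bookkeeping over DFT-SAPT energy decompositions.
##
## A decomposition carries four components in kJ/mol: electrostatic /
## polarization (e_pol), exchange repulsion (e_exch), induction (e_ind) and
## dispersion (e_disp), plus the reported total.  The dispersion-to-
## polarization ratio |e_disp| / |e_pol| drives a three-way classification
## of the interaction character.

#' Construct / validate a SAPT decomposition table
#'
#' @param tab A data frame with columns `system_id`, `e_pol`, `e_exch`,
#'   `e_ind`, `e_disp` and optionally `e_total` (kJ/mol) and `group_label`.
#' @param total_tol Rounding guard: warn when a reported `e_total` differs
#'   from the component sum by more than this (default 0.25 kJ/mol).
#' @return The validated tibble.  Negative exchange components draw a
#'   warning (unphysical at equilibrium separations) but are kept.
#' @export
sapt_table <- function(tab, total_tol = 0.25) {
  need <- c("system_id", "e_pol", "e_exch", "e_ind", "e_disp")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    rlang::abort(paste0("SAPT table lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "focalcbs_invalid_record")
  }
  comp <- as.matrix(tab[c("e_pol", "e_exch", "e_ind", "e_disp")])
  if (any(!is.finite(comp))) {
    rlang::abort("SAPT components must be finite.",
                 class = "focalcbs_invalid_record")
  }
  if (any(tab$e_exch < 0)) {
    rlang::warn("negative exchange component(s): unphysical for equilibrium dimers.",
                class = "focalcbs_sapt_warning")
  }
  if ("e_total" %in% names(tab)) {
    off <- abs(tab$e_total - rowSums(comp))
    if (any(off > total_tol, na.rm = TRUE)) {
      rlang::warn(sprintf(
        "reported e_total differs from component sum by up to %.3g kJ/mol.",
        max(off, na.rm = TRUE)), class = "focalcbs_sapt_warning")
    }
  }
  tibble::as_tibble(tab)
}

#' Read a SAPT component table from CSV
#'
#' Schema: `system_id`, `e_pol`, `e_exch`, `e_ind`, `e_disp`, optionally
#' `e_total` and `group_label` (all energies kJ/mol).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_sapt_table <- function(path) {
  sapt_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Total SAPT interaction energy
#'
#' Sum of the four components: `e_pol + e_exch + e_ind + e_disp`.
#'
#' @param d A SAPT decomposition table (or any data frame with the four
#'   component columns).
#' @return Numeric vector of totals (kJ/mol), one per row.
#' @examples
#' sapt_total(data.frame(e_pol = -6.5, e_exch = 18.9, e_ind = -1.9, e_disp = -17.3))
#' @export
sapt_total <- function(d) {
  d <- sapt_table(d, total_tol = Inf)
  d$e_pol + d$e_exch + d$e_ind + d$e_disp
}

#' Dispersion-to-polarization ratio
#'
#' `|e_disp| / |e_pol|`: the descriptor separating electrostatics-dominated
#' from dispersion-dominated binding.  Undefined for `e_pol = 0`.
#'
#' @param d A SAPT decomposition table.
#' @return Numeric vector of ratios (dimensionless).
#' @export
disp_pol_ratio <- function(d) {
  d <- sapt_table(d, total_tol = Inf)
  if (any(d$e_pol == 0)) {
    rlang::abort("dispersion-to-polarization ratio undefined for e_pol = 0.",
                 class = "focalcbs_undefined_ratio")
  }
  abs(d$e_disp) / abs(d$e_pol)
}

#' Classify the interaction character of a dimer
#'
#' Three-way classification on the dispersion-to-polarization ratio:
#' below `thresholds[1]` the binding is electrostatics-dominated, above
#' `thresholds[2]` dispersion-dominated, in between mixed.  The default
#' thresholds (0.5, 1.5) separate the three benchmark groups cleanly
#' (observed group ranges: <= 0.36, 0.69-1.09, >= 1.76).
#'
#' @param d A SAPT decomposition table.
#' @param thresholds Length-2 increasing numeric vector.
#' @return Character vector in `{"electrostatics_dominated", "mixed",
#'   "dispersion_dominated"}`.
#' @export
classify_interaction <- function(d, thresholds = c(0.5, 1.5)) {
  if (length(thresholds) != 2 || !all(is.finite(thresholds)) ||
      thresholds[1] >= thresholds[2]) {
    rlang::abort("`thresholds` must be two increasing finite numbers.",
                 class = "focalcbs_invalid_params")
  }
  r <- disp_pol_ratio(d)
  dplyr::case_when(
    r < thresholds[1] ~ "electrostatics_dominated",
    r > thresholds[2] ~ "dispersion_dominated",
    TRUE              ~ "mixed"
  )
}

#' Compare SAPT totals to supermolecular interaction energies
#'
#' @param d A SAPT decomposition table.
#' @param de_ref Reference supermolecular interaction energies (kJ/mol),
#'   one per row of `d`.
#' @return A tibble with `system_id`, `sapt_total`, `de_ref`, `abs_dev`
#'   (kJ/mol) and `rel_dev` (percent of `|de_ref|`; `NA` where the
#'   reference is zero).
#' @export
compare_to_supermolecular <- function(d, de_ref) {
  tot <- sapt_total(d)
  if (length(de_ref) != length(tot)) {
    rlang::abort("`de_ref` must have one value per SAPT row.",
                 class = "focalcbs_invalid_record")
  }
  abs_dev <- abs(tot - de_ref)
  tibble::tibble(
    system_id  = d$system_id,
    sapt_total = tot,
    de_ref     = de_ref,
    abs_dev    = abs_dev,
    rel_dev    = ifelse(de_ref == 0, NA_real_, 100 * abs_dev / abs(de_ref))
  )
}

#' Packaged benchmark SAPT decompositions
#'
#' The DFT-SAPT/CBS component energies for the benchmark dimer collections
#' shipped with the package: the 18-dimer three-group suite (six
#' electrostatics-dominated, six mixed, six dispersion-dominated), seven
#' stacked furan-toluene configurations, two miscellaneous dimers, two
#' poly(3-hydroxybutyrate) chain-pair models and three large complexes
#' (coronene dimer, guanine trimer, guanine-cytosine tetramer).  `de_best`
#' holds the best supermolecular estimate of the interaction energy where
#' available, `de_best_unc` its published uncertainty.
#'
#' @return A tibble with the SAPT schema plus `set`, `group_label`,
#'   `de_best`, `de_best_unc`.
#' @export
sapt_benchmark <- function() {
  path <- system.file("extdata", "sapt_components.csv", package = "focalcbs",
                      mustWork = TRUE)
  sapt_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Packaged CBS interaction energies for large complexes
#'
#' Magnitudes of the CBS-extrapolated interaction energies (kJ/mol,
#' `minus_de` = -interaction energy, so larger = more strongly bound) for
#' five large complexes under three methods: the fitted (aDZ, aTZ) scheme,
#' the (aTZ, aQZ) focal-point scheme, and DFT-SAPT.
#'
#' @return A long tibble with columns `system_id`, `method`, `minus_de`.
#' @export
cbs_benchmark <- function() {
  path <- system.file("extdata", "cbs_large_complexes.csv",
                      package = "focalcbs", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
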