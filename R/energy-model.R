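## Normalised data model for absolute electronic energies and
## counterpoise-corrected interaction-energy components.
##
## An energy table holds one row per absolute energy, tagged by system,
## fragment role (dimer / monomer_A / monomer_B), method component
## (HF / MP2_corr / CCSDT_corr), basis cardinal number X (2 = aDZ ... 5 = a5Z)
## and basis context (monomers evaluated in the full dimer basis carry
## basis_context = "dimer_basis"; counterpoise correction requires it).

FRAGMENTS      <- c("dimer", "monomer_A", "monomer_B")
COMPONENTS     <- c("HF", "MP2_corr", "CCSDT_corr")
BASIS_CONTEXTS <- c("dimer_basis", "own_basis")
CARDINALS      <- 2:5

#' Construct a validated energy table
#'
#' Builds the tabular data model for absolute electronic energies: one row
#' per (system, fragment, method component, basis cardinal).  Monomer rows
#' destined for counterpoise correction must be evaluated in the dimer
#' basis (`basis_context = "dimer_basis"`).
#'
#' @param system_id Character, system labels.
#' @param fragment One of `"dimer"`, `"monomer_A"`, `"monomer_B"`.
#' @param component One of `"HF"`, `"MP2_corr"`, `"CCSDT_corr"` (correlation
#'   components are correlation energies, i.e. total minus mean-field).
#' @param cardinal Integer basis cardinal number: 2 (aDZ), 3 (aTZ),
#'   4 (aQZ) or 5 (a5Z).
#' @param basis_context `"dimer_basis"` or `"own_basis"`.
#' @param energy_hartree Finite numeric, absolute energy in hartree.
#' @param provenance Free-text metadata (program, local-correlation settings).
#' @return A tibble with the seven schema columns.
#' @export
energy_table <- function(system_id, fragment, component, cardinal,
                         basis_context, energy_hartree, provenance = "") {
  tab <- tibble::tibble(
    system_id      = as.character(system_id),
    fragment       = as.character(fragment),
    component      = as.character(component),
    cardinal       = as.integer(cardinal),
    basis_context  = as.character(basis_context),
    energy_hartree = as.numeric(energy_hartree),
    provenance     = as.character(provenance)
  )
  validate_energy_table(tab)
}

#' Validate an energy table against the schema
#'
#' @param tab A data frame with the energy-table columns.
#' @return The table, invisibly coerced to a tibble, if valid.
#' @export
validate_energy_table <- function(tab) {
  need <- c("system_id", "fragment", "component", "cardinal",
            "basis_context", "energy_hartree")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    rlang::abort(paste0("energy table lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "focalcbs_invalid_record")
  }
  if (!all(tab$fragment %in% FRAGMENTS)) {
    rlang::abort("fragment must be one of dimer, monomer_A, monomer_B.",
                 class = "focalcbs_invalid_record")
  }
  if (!all(tab$component %in% COMPONENTS)) {
    rlang::abort("component must be one of HF, MP2_corr, CCSDT_corr.",
                 class = "focalcbs_invalid_record")
  }
  if (!all(tab$cardinal %in% CARDINALS)) {
    rlang::abort("cardinal must be in {2, 3, 4, 5}.",
                 class = "focalcbs_invalid_record")
  }
  if (!all(tab$basis_context %in% BASIS_CONTEXTS)) {
    rlang::abort("basis_context must be dimer_basis or own_basis.",
                 class = "focalcbs_invalid_record")
  }
  if (any(!is.finite(tab$energy_hartree))) {
    rlang::abort("energy_hartree must be finite.",
                 class = "focalcbs_invalid_record")
  }
  tibble::as_tibble(tab)
}

#' Read an energy table from CSV
#'
#' Expects the documented schema: columns `system_id`, `fragment`,
#' `component`, `cardinal`, `basis_context`, `energy_hartree` and optionally
#' `provenance`; UTF-8, header row, '.' decimal separator.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_energy_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"provenance" %in% names(tab)) tab$provenance <- ""
  validate_energy_table(tab)
}

#' Counterpoise-corrected interaction energy
#'
#' Supermolecular difference with both monomers evaluated in the full dimer
#' basis, which cancels the basis set superposition error.  All three inputs
#' must share one system, one method component and one basis cardinal.
#' Negative values mean attraction (binding).
#'
#' @param e_dimer Dimer absolute energy (hartree).
#' @param e_mon_a,e_mon_b Monomer absolute energies in the dimer basis
#'   (hartree).
#' @return Interaction energy in kJ/mol.
#' @examples
#' cp_interaction(-2.01, -1.0, -1.0)
#' @export
cp_interaction <- function(e_dimer, e_mon_a, e_mon_b) {
  hartree_to_kjmol(e_dimer - e_mon_a - e_mon_b)
}

## Pull the unique energy for (fragment, component, cardinal) out of one
## system's records, insisting on the dimer-basis context for monomers.
.lookup_energy <- function(tab, frag, comp, card, system_id) {
  sel <- tab$fragment == frag & tab$component == comp & tab$cardinal == card
  if (frag != "dimer") sel <- sel & tab$basis_context == "dimer_basis"
  hit <- tab$energy_hartree[sel]
  if (length(hit) == 0) {
    rlang::abort(
      sprintf("system '%s': missing record (%s, %s, cardinal %d)%s",
              system_id, frag, comp, card,
              if (frag == "dimer") "" else " in the dimer basis"),
      class = "focalcbs_incomplete_data")
  }
  if (length(hit) > 1) {
    rlang::abort(
      sprintf("system '%s': duplicated record (%s, %s, cardinal %d)",
              system_id, frag, comp, card),
      class = "focalcbs_invalid_record")
  }
  hit
}

#' Assemble counterpoise-corrected interaction-energy components
#'
#' For every basis cardinal present in a system's records, forms the three
#' interaction-energy components used by the focal-point schemes: the
#' mean-field part `dE_HF`, the MP2-correlation part `dE_MP2corr`, and the
#' post-MP2 correction `dE_postMP2` (CCSD(T)-correlation minus
#' MP2-correlation interaction components).  All nine records
#' (3 fragments x 3 components) must exist at each cardinal; a missing
#' record raises an incomplete-data error naming the absent triple.
#'
#' @param tab An energy table (one or more systems).
#' @return A tibble with columns `system_id`, `cardinal`, `dE_HF`,
#'   `dE_MP2corr`, `dE_postMP2` (all kJ/mol), one row per system x cardinal.
#' @export
assemble_components <- function(tab) {
  tab <- validate_energy_table(tab)
  out <- lapply(split(tab, tab$system_id), function(sys) {
    sid   <- sys$system_id[[1]]
    cards <- sort(unique(sys$cardinal))
    rows  <- lapply(cards, function(card) {
      de <- vapply(COMPONENTS, function(comp) {
        cp_interaction(
          .lookup_energy(sys, "dimer",     comp, card, sid),
          .lookup_energy(sys, "monomer_A", comp, card, sid),
          .lookup_energy(sys, "monomer_B", comp, card, sid))
      }, numeric(1))
      tibble::tibble(
        system_id  = sid,
        cardinal   = card,
        dE_HF      = de[["HF"]],
        dE_MP2corr = de[["MP2_corr"]],
        dE_postMP2 = de[["CCSDT_corr"]] - de[["MP2_corr"]]
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}
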