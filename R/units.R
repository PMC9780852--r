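#' @keywords internal
"_PACKAGE"

## 1 hartree in kJ/mol (CODATA-derived); all interaction energies in this
## package are reported in kJ/mol, all absolute electronic energies in hartree.
HARTREE_KJMOL <- 2625.499639

#' Convert hartree to kJ/mol
#'
#' Exact linear conversion using 1 hartree = 2625.499639 kJ/mol.
#'
#' @param e Numeric vector of energies in hartree.
#' @return Numeric vector in kJ/mol.
#' @examples
#' hartree_to_kjmol(-0.01)
#' @export
hartree_to_kjmol <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e))) {
    rlang::abort("`e` must be finite numeric (hartree).",
                 class = "focalcbs_invalid_record")
  }
  e * HARTREE_KJMOL
}

#' Convert kJ/mol to hartree
#'
#' @param e Numeric vector of energies in kJ/mol.
#' @return Numeric vector in hartree.
#' @export
kjmol_to_hartree <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e))) {
    rlang::abort("`e` must be finite numeric (kJ/mol).",
                 class = "focalcbs_invalid_record")
  }
  e / HARTREE_KJMOL
}
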