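## Two- and three-point complete-basis-set extrapolation kernels.
##
## Mean-field (HF) energies converge as E(X) = E_CBS + A * exp(alpha * sqrt(X))
## with alpha < 0; correlation energies as E(X) = E_CBS + A * X^(-beta) with
## beta > 0.  Each two-point kernel inverts its model exactly through two
## cardinals, so on model-consistent data the extrapolation has no residual
## error.  Relative weight differences below 1e-12 are rejected rather than
## silently returning a catastrophic cancellation.

.ILL_COND_TOL <- 1e-12

.check_pair <- function(x_lo, x_hi) {
  if (!is.numeric(x_lo) || !is.numeric(x_hi) || x_lo >= x_hi) {
    rlang::abort("need x_lo < x_hi (distinct basis cardinals).",
                 class = "focalcbs_degenerate_extrapolation")
  }
}

## Generic two-point inversion: d_lo, d_hi are the model decay factors at
## the two cardinals (E(X) = E_CBS + A * d(X)), so
## E_CBS = (d_hi * e_lo - d_lo * e_hi) / (d_hi - d_lo).
.two_point <- function(e_lo, e_hi, d_lo, d_hi) {
  denom <- d_hi - d_lo
  if (!is.finite(denom) ||
      abs(denom) <= .ILL_COND_TOL * max(abs(d_lo), abs(d_hi))) {
    rlang::abort(
      "extrapolation weights are (nearly) equal; result would be dominated by cancellation.",
      class = "focalcbs_ill_conditioned")
  }
  (d_hi * e_lo - d_lo * e_hi) / denom
}

#' Two-point CBS extrapolation of mean-field energies
#'
#' Extrapolates Hartree-Fock (mean-field) energies using the exponential
#' model `E(X) = E_CBS + A * exp(alpha * sqrt(X))`, yielding
#' `[exp(alpha*sqrt(x_hi))*e_lo - exp(alpha*sqrt(x_lo))*e_hi] /
#'  [exp(alpha*sqrt(x_hi)) - exp(alpha*sqrt(x_lo))]`.
#'
#' @param e_lo,e_hi Energies (hartree or kJ/mol; the kernel is linear) at
#'   the lower and higher cardinal.
#' @param x_lo,x_hi Basis cardinal numbers, `x_lo < x_hi`.
#' @param alpha Negative decay exponent; the refit value for the
#'   (aDZ, aTZ) pair is -4.473 (see [fit_params()]).
#' @return The CBS-limit energy of the model through both points.
#' @export
hf_two_point <- function(e_lo, e_hi, x_lo, x_hi, alpha) {
  .check_pair(x_lo, x_hi)
  if (!is.numeric(alpha) || !is.finite(alpha) || alpha >= 0) {
    rlang::abort("`alpha` must be finite and negative (decaying mean-field model).",
                 class = "focalcbs_invalid_params")
  }
  .two_point(e_lo, e_hi, exp(alpha * sqrt(x_lo)), exp(alpha * sqrt(x_hi)))
}

#' Two-point CBS extrapolation of correlation energies
#'
#' Extrapolates correlation energies using the inverse-power model
#' `E(X) = E_CBS + A * X^(-beta)`, yielding
#' `(x_lo^beta * e_lo - x_hi^beta * e_hi) / (x_lo^beta - x_hi^beta)`
#' (equivalently written with the decay factors `X^(-beta)` as weights).
#' With `beta = 3` this is the standard cubic two-point rule.
#'
#' @inheritParams hf_two_point
#' @param beta Positive decay exponent; the refit value for the MP2
#'   correlation component on the (aDZ, aTZ) pair is 2.796.
#' @return The CBS-limit energy of the model through both points.
#' @export
corr_two_point <- function(e_lo, e_hi, x_lo, x_hi, beta) {
  .check_pair(x_lo, x_hi)
  if (!is.numeric(beta) || !is.finite(beta) || beta <= 0) {
    rlang::abort("`beta` must be finite and positive (decaying correlation model).",
                 class = "focalcbs_invalid_params")
  }
  .two_point(e_lo, e_hi, x_lo^(-beta), x_hi^(-beta))
}

#' Two-point CBS extrapolation of the post-MP2 correction
#'
#' The post-MP2 correction (CCSD(T) correlation minus MP2 correlation) is
#' extrapolated as the difference of two inverse-power extrapolations: the
#' CCSD(T)-correlation pair with exponent `gamma` minus the MP2-correlation
#' pair with exponent `beta`.  With `beta == gamma` this reduces to the
#' single-exponent rule applied to the differences directly.
#'
#' @param e_ccsdt_lo,e_ccsdt_hi CCSD(T) correlation energies at the two
#'   cardinals.
#' @param e_mp2_lo,e_mp2_hi MP2 correlation energies at the two cardinals.
#' @inheritParams hf_two_point
#' @param beta Exponent for the MP2-correlation extrapolation (refit: 2.796).
#' @param gamma Exponent for the CCSD(T)-correlation extrapolation
#'   (refit: 2.741).
#' @return The CBS-limit post-MP2 correction.
#' @export
post_mp2_two_point <- function(e_ccsdt_lo, e_ccsdt_hi, e_mp2_lo, e_mp2_hi,
                               x_lo, x_hi, beta, gamma) {
  corr_two_point(e_ccsdt_lo, e_ccsdt_hi, x_lo, x_hi, gamma) -
    corr_two_point(e_mp2_lo, e_mp2_hi, x_lo, x_hi, beta)
}

#' Three-point mixed Gaussian/exponential CBS extrapolation
#'
#' Solves exactly (a 3x3 linear system) the mixed Gaussian/exponential
#' model `E(X) = E_CBS + B * exp(-(X-1)) + C * exp(-(X-1)^2)` through three
#' consecutive cardinals `x_start, x_start+1, x_start+2`.  The exponential
#' factors are fixed, so the solution is analytic and the forward model
#' reproduces the three inputs to machine precision.
#'
#' @param e_x,e_x1,e_x2 Energies at the three consecutive cardinals.
#' @param x_start First cardinal (>= 2); the aTZ/aQZ/a5Z series uses 3.
#' @return A list with `e_cbs`, `b_coef` and `c_coef`.
#' @export
mixed_three_point <- function(e_x, e_x1, e_x2, x_start = 3) {
  if (!is.numeric(x_start) || x_start < 2) {
    rlang::abort("`x_start` must be a cardinal >= 2.",
                 class = "focalcbs_invalid_params")
  }
  xs <- x_start + 0:2
  m  <- cbind(1, exp(-(xs - 1)), exp(-(xs - 1)^2))
  sol <- solve(m, c(e_x, e_x1, e_x2))
  list(e_cbs = sol[[1]], b_coef = sol[[2]], c_coef = sol[[3]])
}

#' Extrapolation exponents for the fitted focal-point scheme
#'
#' Bundles the three decay exponents governing the cheap (aDZ, aTZ)
#' focal-point scheme: `alpha` for the mean-field exponential model,
#' `beta` for the MP2-correlation inverse-power model and `gamma` for the
#' CCSD(T)-correlation term inside the post-MP2 extrapolation.  Defaults
#' are the values refit against quintuple-zeta reference energies
#' (-4.473, 2.796, 2.741).
#'
#' @param alpha Negative mean-field exponent.
#' @param beta Positive MP2-correlation exponent.
#' @param gamma Positive CCSD(T)-correlation exponent.
#' @return A validated list of class `"fit_params"`.
#' @export
fit_params <- function(alpha = -4.473, beta = 2.796, gamma = 2.741) {
  ok <- is.numeric(alpha) && is.finite(alpha) && alpha < 0 &&
        is.numeric(beta)  && is.finite(beta)  && beta  > 0 &&
        is.numeric(gamma) && is.finite(gamma) && gamma > 0
  if (!ok) {
    rlang::abort("need alpha < 0, beta > 0, gamma > 0, all finite.",
                 class = "focalcbs_invalid_params")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "fit_params")
}
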