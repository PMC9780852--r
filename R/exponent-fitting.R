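## Refitting the extrapolation exponents by nonlinear least squares.
##
## Each fit is a one-parameter Levenberg-Marquardt problem: the exponent
## minimises the unweighted sum of squared differences between the
## two-point extrapolation of low-cardinal energies and a reference value,
## one residual per observation.  Residual units follow the inputs
## (hartree for absolute-energy fits, kJ/mol for interaction-level fits);
## the kernels are linear in the energies so the minimiser is unaffected
## by the unit choice as long as it is consistent.

.fit_result <- function(value, rss, n_obs, converged, degenerate = FALSE) {
  structure(
    list(value         = value,
         value_rounded = signif(value, 4),
         rss           = rss,
         n_obs         = n_obs,
         converged     = converged,
         degenerate    = degenerate),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("exponent fit: %.10g (rounded %.4g), rss = %.6g, n = %d, %s%s\n",
              x$value, x$value_rounded, x$rss, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) ", rank-deficient" else ""))
  invisible(x)
}

.check_obs <- function(obs, cols) {
  miss <- setdiff(cols, names(obs))
  if (length(miss) > 0) {
    rlang::abort(paste0("observations lack column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "focalcbs_invalid_record")
  }
  if (nrow(obs) < 1 || any(!is.finite(as.matrix(obs[cols])))) {
    rlang::abort("observations must be non-empty with finite values.",
                 class = "focalcbs_invalid_record")
  }
  obs
}

## Degenerate design: if every low/high pair is (numerically) constant the
## extrapolation equals the constant for any exponent and the residuals
## carry no information about it.
.is_rank_deficient <- function(e_lo, e_hi) {
  scale <- max(1, abs(e_lo), abs(e_hi))
  all(abs(e_lo - e_hi) <= 1e-12 * scale)
}

.lm_fit_1d <- function(resid_fun, start, lower, upper) {
  fit <- minpack.lm::nls.lm(
    par     = list(p = start),
    lower   = lower, upper = upper,
    fn      = function(par) resid_fun(par$p),
    control = minpack.lm::nls.lm.control(
      maxiter = 200, ptol = 1e-12, ftol = 1e-14))
  value     <- fit$par$p
  ## 1-3: ftol/ptol met; 4: gradient orthogonal to residuals within gtol
  converged <- fit$info %in% 1:4
  if (!converged) {
    rlang::warn(sprintf(
      "exponent fit did not converge (%s); best value %.6g returned.",
      fit$message, value), class = "focalcbs_fit_not_converged")
  }
  .fit_result(value, sum(resid_fun(value)^2), length(resid_fun(value)),
              converged)
}

#' Fit the mean-field extrapolation exponent
#'
#' Finds the exponent `alpha` of the exponential mean-field model that
#' minimises, in the least-squares sense, the differences between
#' two-point extrapolations of low-cardinal Hartree-Fock energies and
#' reference (e.g. quintuple-zeta) values.
#'
#' @param obs A data frame with columns `e_lo`, `e_hi` (energies at the two
#'   low cardinals) and `ref` (the reference value), one row per
#'   observation (system x fragment).
#' @param x_lo,x_hi The cardinals of `e_lo`/`e_hi` (default 2 and 3).
#' @param start Starting value (default -4, the conventional exponent's
#'   neighbourhood).
#' @return A `fit_result`: `value`, `value_rounded` (4 significant digits),
#'   `rss`, `n_obs`, `converged`, `degenerate`.
#' @export
fit_alpha <- function(obs, x_lo = 2, x_hi = 3, start = -4) {
  obs <- .check_obs(obs, c("e_lo", "e_hi", "ref"))
  if (.is_rank_deficient(obs$e_lo, obs$e_hi)) {
    rlang::warn("observations already converged; any exponent fits (rank-deficient).",
                class = "focalcbs_fit_degenerate")
    return(.fit_result(start, sum((obs$e_lo - obs$ref)^2), nrow(obs),
                       converged = FALSE, degenerate = TRUE))
  }
  .lm_fit_1d(
    function(a) hf_two_point(obs$e_lo, obs$e_hi, x_lo, x_hi, a) - obs$ref,
    start, lower = -60, upper = -1e-8)
}

#' Fit the MP2-correlation extrapolation exponent
#'
#' As [fit_alpha()], but for the inverse-power correlation model: the
#' exponent `beta` minimises differences between two-point extrapolations
#' of low-cardinal MP2 correlation energies and reference values.
#'
#' @inheritParams fit_alpha
#' @param start Starting value (default 3, the conventional cubic rule).
#' @return A `fit_result`.
#' @export
fit_beta <- function(obs, x_lo = 2, x_hi = 3, start = 3) {
  obs <- .check_obs(obs, c("e_lo", "e_hi", "ref"))
  if (.is_rank_deficient(obs$e_lo, obs$e_hi)) {
    rlang::warn("observations already converged; any exponent fits (rank-deficient).",
                class = "focalcbs_fit_degenerate")
    return(.fit_result(start, sum((obs$e_lo - obs$ref)^2), nrow(obs),
                       converged = FALSE, degenerate = TRUE))
  }
  .lm_fit_1d(
    function(b) corr_two_point(obs$e_lo, obs$e_hi, x_lo, x_hi, b) - obs$ref,
    start, lower = 1e-8, upper = 60)
}

#' Fit the post-MP2 extrapolation exponent
#'
#' Fits the exponent `gamma` of the CCSD(T)-correlation term inside the
#' post-MP2 extrapolation, holding the MP2 exponent `beta` fixed: `gamma`
#' minimises differences between the extrapolated post-MP2 correction
#' (CCSD(T)-correlation extrapolated with `gamma` minus MP2-correlation
#' extrapolated with `beta`) and a reference post-MP2 value supplied per
#' observation.
#'
#' @param obs A data frame with columns `e_ccsdt_lo`, `e_ccsdt_hi`,
#'   `e_mp2_lo`, `e_mp2_hi` (correlation energies at the two cardinals) and
#'   `ref` (reference post-MP2 value).
#' @param beta The fixed MP2-correlation exponent (> 0); the refit value is
#'   2.796.
#' @inheritParams fit_alpha
#' @param start Starting value (default 3).
#' @return A `fit_result`.
#' @export
fit_gamma <- function(obs, beta, x_lo = 2, x_hi = 3, start = 3) {
  if (missing(beta) || !is.numeric(beta) || !is.finite(beta) || beta <= 0) {
    rlang::abort("`beta` must be a fixed positive exponent.",
                 class = "focalcbs_invalid_params")
  }
  obs <- .check_obs(obs, c("e_ccsdt_lo", "e_ccsdt_hi",
                           "e_mp2_lo", "e_mp2_hi", "ref"))
  if (.is_rank_deficient(obs$e_ccsdt_lo, obs$e_ccsdt_hi)) {
    rlang::warn("observations already converged; any exponent fits (rank-deficient).",
                class = "focalcbs_fit_degenerate")
    return(.fit_result(start, 0, nrow(obs), converged = FALSE,
                       degenerate = TRUE))
  }
  .lm_fit_1d(
    function(g) {
      post_mp2_two_point(obs$e_ccsdt_lo, obs$e_ccsdt_hi,
                         obs$e_mp2_lo, obs$e_mp2_hi,
                         x_lo, x_hi, beta = beta, gamma = g) - obs$ref
    },
    start, lower = 1e-8, upper = 60)
}
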