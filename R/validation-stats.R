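## Regression and deviation statistics for comparing two interaction-energy
## vectors (a candidate scheme against a reference).

#' Ordinary least-squares regression between two energy vectors
#'
#' Fits `y = slope * x + intercept` by OLS (via [stats::lm()]) and reports
#' the adjusted R-squared, `1 - (1 - R^2) * (n - 1) / (n - 2)`, and the
#' residual standard deviation `sqrt(RSS / (n - 2))`.
#'
#' @param xs Reference energies (kJ/mol).
#' @param ys Candidate energies (kJ/mol), same length (>= 3).
#' @return A list: `slope`, `intercept`, `adj_r2`, `resid_sd`, `n`.
#' @export
regress <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3) {
    rlang::abort("need two equal-length vectors of length >= 3.",
                 class = "focalcbs_invalid_record")
  }
  if (stats::sd(xs) == 0) {
    rlang::abort("`xs` is constant: regression is degenerate.",
                 class = "focalcbs_degenerate_regression")
  }
  fit <- stats::lm(ys ~ xs)
  ## exact data trip summary.lm's "essentially perfect fit" warning; a
  ## zero-residual comparison is a legitimate input here
  sm  <- suppressWarnings(summary(fit))
  list(slope     = unname(stats::coef(fit)[["xs"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       adj_r2    = sm$adj.r.squared,
       resid_sd  = sm$sigma,
       n         = length(xs))
}

#' Deviation statistics between two energy vectors
#'
#' Mean absolute deviation, root-mean-square deviation and the worst
#' offenders in absolute and relative terms.  Relative deviations are
#' percentages of the reference `|x|`; entries with `x = 0` are skipped for
#' the relative part.
#'
#' @param xs Reference energies (kJ/mol).
#' @param ys Candidate energies (kJ/mol), same length (>= 1).
#' @param ids Optional labels, one per entry.
#' @return A list: `mad`, `rmsd` (kJ/mol), `max_abs_dev`, `max_abs_id`,
#'   `max_rel_dev` (percent), `max_rel_id`, `n`.
#' @export
deviations <- function(xs, ys, ids = NULL) {
  n <- length(xs)
  if (n == 0 || length(ys) != n) {
    rlang::abort("need two equal-length non-empty vectors.",
                 class = "focalcbs_invalid_record")
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d     <- abs(ys - xs)
  i_abs <- which.max(d)
  ok    <- xs != 0
  rel   <- ifelse(ok, 100 * d / abs(xs), NA_real_)
  i_rel <- if (any(ok)) which.max(replace(rel, !ok, -Inf)) else NA_integer_
  list(mad         = mean(d),
       rmsd        = sqrt(mean(d^2)),
       max_abs_dev = d[[i_abs]],
       max_abs_id  = ids[[i_abs]],
       max_rel_dev = if (is.na(i_rel)) NA_real_ else rel[[i_rel]],
       max_rel_id  = if (is.na(i_rel)) NA_character_ else ids[[i_rel]],
       n           = n)
}

#' Full deviation report between two energy vectors
#'
#' Convenience wrapper combining [regress()] and [deviations()] into one
#' flat list (the regression fields are `NA` when fewer than three points
#' are supplied).
#'
#' @inheritParams deviations
#' @return A list with the union of the [regress()] and [deviations()]
#'   fields.
#' @export
deviation_report <- function(xs, ys, ids = NULL) {
  dev <- deviations(xs, ys, ids)
  reg <- if (length(xs) >= 3 && stats::sd(xs) > 0) {
    regress(xs, ys)[c("slope", "intercept", "adj_r2", "resid_sd")]
  } else {
    list(slope = NA_real_, intercept = NA_real_,
         adj_r2 = NA_real_, resid_sd = NA_real_)
  }
  c(reg, dev)
}
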