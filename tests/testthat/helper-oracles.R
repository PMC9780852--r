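# Independent oracles used across the suite.  Each is deliberately coded
# on a different path from the package implementation it checks.

# Dense grid-search minimiser for one-parameter least-squares exponent
# problems.  `coef_fun(p)` must return c(c_lo, c_hi) such that the model
# prediction is c_lo * e_lo + c_hi * e_hi; the whole grid is evaluated as
# one matrix product.
grid_search_exponent <- function(grid, coef_fun, e_lo, e_hi, ref) {
  coefs <- t(vapply(grid, coef_fun, numeric(2)))          # |grid| x 2
  pred  <- coefs %*% rbind(e_lo, e_hi)                    # |grid| x n_obs
  rss   <- rowSums((pred - matrix(ref, nrow(pred), length(ref),
                                  byrow = TRUE))^2)
  grid[which.min(rss)]
}

# Extrapolation coefficients (weights on e_lo, e_hi) for the two models.
hf_coefs <- function(alpha, x_lo = 2, x_hi = 3) {
  d_lo <- exp(alpha * sqrt(x_lo)); d_hi <- exp(alpha * sqrt(x_hi))
  c(d_hi, -d_lo) / (d_hi - d_lo)
}
corr_coefs <- function(beta, x_lo = 2, x_hi = 3) {
  d_lo <- x_lo^(-beta); d_hi <- x_hi^(-beta)
  c(d_hi, -d_lo) / (d_hi - d_lo)
}

# The standard cubic two-point rule, written independently in its usual
# X^3 arrangement.
cubic_rule <- function(e_lo, e_hi, x_lo, x_hi) {
  (x_hi^3 * e_hi - x_lo^3 * e_lo) / (x_hi^3 - x_lo^3)
}

# Closed-form OLS via sums (normal equations), independent of stats::lm.
ols_closed_form <- function(x, y) {
  n  <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope     <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - slope * x - intercept
  r2  <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       resid_sd = sqrt(sum(res^2) / (n - 2)))
}

# General-purpose nonlinear least-squares solve of the three-point mixed
# Gaussian/exponential equations (oracle for the analytic linear solve).
three_point_nls <- function(e_x, e_x1, e_x2, x_start) {
  xs <- x_start + 0:2
  ys <- c(e_x, e_x1, e_x2)
  fit <- minpack.lm::nls.lm(
    par = list(a = mean(ys), b = 0, c = 0),
    fn  = function(p) {
      p$a + p$b * exp(-(xs - 1)) + p$c * exp(-(xs - 1)^2) - ys
    },
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-15,
                                         ftol = 1e-15))
  list(e_cbs = fit$par$a, b_coef = fit$par$b, c_coef = fit$par$c)
}

# Forward convergence models (used to manufacture model-consistent data).
hf_model   <- function(e_cbs, a, alpha, x) e_cbs + a * exp(alpha * sqrt(x))
corr_model <- function(e_cbs, a, beta, x)  e_cbs + a * x^(-beta)

# A complete component table with identical rows at the given cardinals
# (already-converged data).
constant_components <- function(system_id, de_hf, de_mp2, de_post,
                                cardinals) {
  tibble::tibble(system_id = system_id, cardinal = as.integer(cardinals),
                 dE_HF = de_hf, dE_MP2corr = de_mp2, dE_postMP2 = de_post)
}
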