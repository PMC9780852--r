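test_that("noiseless exponent fits recover the generating value exactly", {
  # mean-field: single zero-residual observation
  e2 <- hf_model(-100, 0.8, -4.473, 2)
  e3 <- hf_model(-100, 0.8, -4.473, 3)
  fa <- fit_alpha(data.frame(e_lo = e2, e_hi = e3, ref = -100))
  expect_true(fa$converged)
  expect_equal(fa$value, -4.473, tolerance = 1e-6)
  expect_equal(fa$value_rounded, signif(fa$value, 4))
  # correlation: single zero-residual observation
  fb <- fit_beta(data.frame(e_lo = corr_model(-1, 0.2, 2.796, 2),
                            e_hi = corr_model(-1, 0.2, 2.796, 3),
                            ref = -1))
  expect_true(fb$converged)
  expect_equal(fb$value, 2.796, tolerance = 1e-6)
  # post-MP2: zero-residual construction with beta held fixed
  obs <- data.frame(e_ccsdt_lo = corr_model(-1.2, 0.25, 2.741, 2),
                    e_ccsdt_hi = corr_model(-1.2, 0.25, 2.741, 3),
                    e_mp2_lo   = corr_model(-1.1, 0.20, 2.796, 2),
                    e_mp2_hi   = corr_model(-1.1, 0.20, 2.796, 3),
                    ref        = -0.1)
  fg <- fit_gamma(obs, beta = 2.796)
  expect_true(fg$converged)
  expect_equal(fg$value, 2.741, tolerance = 1e-6)
})

test_that("noiseless multi-system fits recover any planted exponent", {
  set.seed(41)
  for (planted in c(-3.2, -5.5)) {
    a  <- runif(20, 0.1, 1)
    cbs <- runif(20, -300, -50)
    obs <- data.frame(e_lo = hf_model(cbs, a, planted, 2),
                      e_hi = hf_model(cbs, a, planted, 3), ref = cbs)
    expect_equal(fit_alpha(obs)$value, planted, tolerance = 1e-6)
  }
  for (planted in c(2.3, 3.4)) {
    a  <- runif(20, 0.1, 0.5)
    cbs <- runif(20, -3, -0.5)
    obs <- data.frame(e_lo = corr_model(cbs, a, planted, 2),
                      e_hi = corr_model(cbs, a, planted, 3), ref = cbs)
    expect_equal(fit_beta(obs)$value, planted, tolerance = 1e-6)
  }
})

test_that("noisy 58-observation fits recover the planted exponents near the grid-search optimum", {
  set.seed(42)
  n <- 58
  # mean-field problem: planted alpha = -4.5, sigma = 1e-5 hartree on refs
  a   <- runif(n, 0.1, 1)
  cbs <- runif(n, -300, -50)
  obs_a <- data.frame(e_lo = hf_model(cbs, a, -4.5, 2),
                      e_hi = hf_model(cbs, a, -4.5, 3),
                      ref  = cbs + rnorm(n, 0, 1e-5))
  fa <- fit_alpha(obs_a)
  expect_true(fa$converged)
  expect_equal(fa$value, -4.5, tolerance = 0.05)
  ga <- grid_search_exponent(seq(-10, -1, by = 1e-4), hf_coefs,
                             obs_a$e_lo, obs_a$e_hi, obs_a$ref)
  expect_equal(fa$value, ga, tolerance = 2e-4)

  # correlation problem: planted beta = 2.8
  amp  <- runif(n, 0.1, 0.5)
  cbs2 <- runif(n, -3, -0.5)
  obs_b <- data.frame(e_lo = corr_model(cbs2, amp, 2.8, 2),
                      e_hi = corr_model(cbs2, amp, 2.8, 3),
                      ref  = cbs2 + rnorm(n, 0, 1e-5))
  fb <- fit_beta(obs_b)
  expect_equal(fb$value, 2.8, tolerance = 0.05)
  gb <- grid_search_exponent(seq(1, 6, by = 1e-4), corr_coefs,
                             obs_b$e_lo, obs_b$e_hi, obs_b$ref)
  expect_equal(fb$value, gb, tolerance = 2e-4)
})

test_that("the noisy post-MP2 fit recovers gamma with beta held fixed", {
  set.seed(43)
  n <- 22
  amp_c <- runif(n, 0.1, 0.45)
  amp_m <- runif(n, 0.1, 0.40)
  cbs_c <- runif(n, -3.2, -0.6)
  cbs_m <- runif(n, -3.0, -0.5)
  obs <- data.frame(
    e_ccsdt_lo = corr_model(cbs_c, amp_c, 2.7, 2),
    e_ccsdt_hi = corr_model(cbs_c, amp_c, 2.7, 3),
    e_mp2_lo   = corr_model(cbs_m, amp_m, 2.796, 2),
    e_mp2_hi   = corr_model(cbs_m, amp_m, 2.796, 3),
    ref        = (cbs_c - cbs_m) + rnorm(n, 0, 1e-5))
  fg <- fit_gamma(obs, beta = 2.796)
  expect_true(fg$converged)
  expect_equal(fg$value, 2.7, tolerance = 0.1)
  # grid oracle: gamma coefficients act on the CCSD(T) pair; the fixed-beta
  # MP2 extrapolation is a constant offset absorbed into the reference
  mp2_cbs <- corr_two_point(obs$e_mp2_lo, obs$e_mp2_hi, 2, 3, 2.796)
  gg <- grid_search_exponent(seq(1, 6, by = 1e-4), corr_coefs,
                             obs$e_ccsdt_lo, obs$e_ccsdt_hi,
                             obs$ref + mp2_cbs)
  expect_equal(fg$value, gg, tolerance = 2e-4)
})

test_that("conflicting observations settle on the grid-search minimum", {
  # two observations whose implied exponents disagree
  e_lo1 <- hf_model(-100, 0.5, -4.0, 2); e_hi1 <- hf_model(-100, 0.5, -4.0, 3)
  e_lo2 <- hf_model(-150, 0.7, -5.0, 2); e_hi2 <- hf_model(-150, 0.7, -5.0, 3)
  obs <- data.frame(e_lo = c(e_lo1, e_lo2), e_hi = c(e_hi1, e_hi2),
                    ref = c(-100, -150))
  fa <- fit_alpha(obs)
  ga <- grid_search_exponent(seq(-10, -1, by = 1e-4), hf_coefs,
                             obs$e_lo, obs$e_hi, obs$ref)
  expect_equal(fa$value, ga, tolerance = 1e-4)
  expect_gt(fa$rss, 0)
})

test_that("degenerate and invalid fit problems are flagged, not silently accepted", {
  # already-converged observations: any exponent fits
  obs <- data.frame(e_lo = c(-1, -2), e_hi = c(-1, -2), ref = c(-1, -2))
  expect_warning(fb <- fit_beta(obs), class = "focalcbs_fit_degenerate")
  expect_true(fb$degenerate)
  expect_false(fb$converged)
  # invalid fixed beta
  gobs <- data.frame(e_ccsdt_lo = -1.2, e_ccsdt_hi = -1.1,
                     e_mp2_lo = -1.1, e_mp2_hi = -1.05, ref = -0.1)
  expect_error(fit_gamma(gobs, beta = 0), class = "focalcbs_invalid_params")
  expect_error(fit_alpha(data.frame(e_lo = 1)),
               class = "focalcbs_invalid_record")
})

test_that("fits are order-invariant and the gamma fit is shift-invariant", {
  set.seed(44)
  n <- 12
  amp <- runif(n, 0.1, 0.5); cbs <- runif(n, -3, -0.5)
  obs <- data.frame(e_lo = corr_model(cbs, amp, 2.9, 2),
                    e_hi = corr_model(cbs, amp, 2.9, 3),
                    ref  = cbs + rnorm(n, 0, 1e-5))
  perm <- sample(n)
  expect_equal(fit_beta(obs)$value, fit_beta(obs[perm, ])$value,
               tolerance = 1e-10)
  # a global energy shift applied to every record of one system cancels in
  # the post-MP2 differences
  gobs <- data.frame(
    e_ccsdt_lo = corr_model(cbs, amp * 1.1, 2.7, 2),
    e_ccsdt_hi = corr_model(cbs, amp * 1.1, 2.7, 3),
    e_mp2_lo   = corr_model(cbs, amp, 2.796, 2),
    e_mp2_hi   = corr_model(cbs, amp, 2.796, 3),
    ref        = rep(-0.1, n))
  shift <- rnorm(n, 0, 5)
  gobs_shifted <- gobs
  for (col in c("e_ccsdt_lo", "e_ccsdt_hi", "e_mp2_lo", "e_mp2_hi")) {
    gobs_shifted[[col]] <- gobs_shifted[[col]] + shift
  }
  expect_equal(fit_gamma(gobs, beta = 2.796)$value,
               fit_gamma(gobs_shifted, beta = 2.796)$value,
               tolerance = 1e-7)
})
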