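test_that("the canonical composite is pure addition of its parts", {
  comp <- constant_components("s", -20, -15, -3, c(3, 5))
  res  <- compose_canonical(comp)
  expect_equal(res$dE_total, -38)
  expect_equal(res$dE_HF_part + res$dE_MP2_part + res$dE_postMP2_part,
               res$dE_total, tolerance = 1e-9)
  expect_error(compose_canonical(constant_components("s", -20, -15, -3, 2:4)),
               class = "focalcbs_incomplete_data")
})

test_that("the canonical composite recovers planted parts through the generator", {
  spec <- system_spec(de_hf = -20, de_mp2corr = -15, de_postmp2 = -3,
                      int_amp_hf = 0, int_amp_mp2 = 0, int_amp_ccsdt = 0)
  res <- compose_canonical(assemble_components(generate_system(spec, c(3, 5))))
  expect_equal(res$dE_total, -38, tolerance = 1e-9)
  # with finite-basis residual: misses truth by exactly the generator's
  # quantified amount
  spec2 <- system_spec(de_hf = -20, de_mp2corr = -15, de_postmp2 = -3)
  res2  <- compose_canonical(assemble_components(generate_system(spec2, 2:5)))
  expect_equal(res2$dE_total - (-38), canonical_residual(spec2),
               tolerance = 1e-9)
})

test_that("the (aTZ, aQZ) focal scheme extrapolates correlation with the cubic rule", {
  # converged components: extrapolation of constant data is the identity
  comp <- constant_components("s", -20, -15, -3, 3:4)
  expect_equal(compose_focal(comp)$dE_total, -38, tolerance = 1e-12)
  # hand-evaluated MP2 part
  comp2 <- tibble::tibble(system_id = "s", cardinal = 3:4,
                          dE_HF = c(-20, -20),
                          dE_MP2corr = c(-10.0, -10.5),
                          dE_postMP2 = c(0, 0))
  expect_equal(compose_focal(comp2)$dE_MP2_part,
               (27 * -10.0 - 64 * -10.5) / (27 - 64), tolerance = 1e-12)
  # generator with the scheme's own convergence model (cubic correlation
  # decay, converged mean-field at the interaction level)
  spec <- system_spec(de_hf = -20, de_mp2corr = -18, de_postmp2 = -2.5,
                      beta = 3, gamma = 3, int_amp_hf = 0)
  res <- compose_focal(assemble_components(generate_system(spec, 3:4)))
  expect_equal(res$dE_total, -40.5, tolerance = 1e-9)
  expect_error(compose_focal(constant_components("s", -1, -1, -1, c(2, 3))),
               class = "focalcbs_incomplete_data")
})

test_that("the fitted (aDZ, aTZ) scheme recovers planted CBS components exactly", {
  comp <- constant_components("s", -25, -20, -3, 2:3)
  expect_equal(compose_fitted(comp)$dE_total, -48, tolerance = 1e-12)
  spec <- system_spec(de_hf = -25, de_mp2corr = -20, de_postmp2 = -3)
  res  <- compose_fitted(assemble_components(generate_system(spec, 2:3)))
  expect_equal(res$dE_total, -48, tolerance = 1e-9)
  expect_equal(res$dE_HF_part, -25, tolerance = 1e-9)
  expect_equal(res$dE_MP2_part, -20, tolerance = 1e-9)
  expect_equal(res$dE_postMP2_part, -3, tolerance = 1e-9)
})

test_that("changing the exponents changes the total by the analytic weight difference", {
  spec <- system_spec(de_hf = -25, de_mp2corr = -20, de_postmp2 = -3)
  comp <- assemble_components(generate_system(spec, 2:3))
  fitted <- compose_fitted(comp)
  cubic  <- compose_fitted(comp, fit_params(alpha = -4.473, beta = 3,
                                            gamma = 3))
  expect_false(isTRUE(all.equal(fitted$dE_total, cubic$dE_total)))
  # direct formula evaluation with both exponent sets
  direct <- function(b, g) {
    corr_two_point(comp$dE_MP2corr[1], comp$dE_MP2corr[2], 2, 3, b) +
      post_mp2_two_point(comp$dE_MP2corr[1] + comp$dE_postMP2[1],
                         comp$dE_MP2corr[2] + comp$dE_postMP2[2],
                         comp$dE_MP2corr[1], comp$dE_MP2corr[2],
                         2, 3, b, g)
  }
  expect_equal(fitted$dE_total - cubic$dE_total,
               direct(2.796, 2.741) - direct(3, 3), tolerance = 1e-10)
})

test_that("scheme outputs are invariant to record order and monomer relabeling", {
  spec <- system_spec(system_id = "inv", de_hf = -12, de_mp2corr = -9,
                      de_postmp2 = -1.5)
  tab <- generate_system(spec, 2:5)
  set.seed(31)
  shuffled <- tab[sample(nrow(tab)), ]
  swapped  <- tab
  swapped$fragment[tab$fragment == "monomer_A"] <- "monomer_B"
  swapped$fragment[tab$fragment == "monomer_B"] <- "monomer_A"
  for (t2 in list(shuffled, swapped)) {
    expect_equal(compose_fitted(assemble_components(t2)),
                 compose_fitted(assemble_components(tab)))
    expect_equal(compose_canonical(assemble_components(t2)),
                 compose_canonical(assemble_components(tab)))
  }
})

test_that("the three-point cross-check scheme recovers a planted CP difference", {
  # fragment totals following the mixed Gaussian/exponential model exactly;
  # correlation components set to zero so the total sits in the HF slot
  xs <- 3:5
  mk <- function(cbs, b, cc) cbs + b * exp(-(xs - 1)) + cc * exp(-(xs - 1)^2)
  frag <- list(dimer = mk(-181.2 + kjmol_to_hartree(-30), 0.9, 0.3),
               monomer_A = mk(-120.5, 0.5, 0.2),
               monomer_B = mk(-60.7, 0.35, 0.08))
  rows <- do.call(rbind, lapply(names(frag), function(f) {
    do.call(rbind, lapply(1:3, function(i) {
      data.frame(system_id = "tp", fragment = f,
                 component = c("HF", "MP2_corr", "CCSDT_corr"),
                 cardinal = xs[i], basis_context = "dimer_basis",
                 energy_hartree = c(frag[[f]][i], 0, 0),
                 provenance = "")
    }))
  }))
  ## MP2_corr/CCSDT_corr rows of 0 are placeholders; totals = HF rows.
  ## kill the spurious zero-cardinality issue by validating through the API
  res <- compose_three_point(validate_energy_table(rows), x_start = 3)
  expect_equal(res$dE_total, -30, tolerance = 1e-8)
  expect_equal(res$scheme, "three_point")
})
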