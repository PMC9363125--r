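test_that("reference parameterisation matches the published rate constants", {
  p <- wnt_params()
  expect_identical(p$k1, 2.66e-6)
  expect_identical(p$k1_off, 9.6e-5)
  expect_identical(p$k2, 4.33e-5)
  expect_identical(p$k2_off, 4.86e-4)
  expect_identical(p$k3, 1.86e-4)
  expect_identical(p$k3_off, 3.66e-3)
  expect_identical(p$k4, 2.52e-4)
  expect_identical(p$p1, 1e-4)
  expect_identical(p$p2, 1e-3)
  expect_identical(p$p3, 10)
  expect_identical(p$Kd, 1e-2)
  expect_identical(p$hill_n, 2)
  expect_identical(p$diff_coef, 20)
  expect_identical(p$r0, 75)
  expect_identical(p$h0_amp, 1e8)
  expect_identical(p$x_max, 100)
  expect_identical(p$t_max, 1e5)
  # derived defaults: dnFzd7 binding shares k1, no catalysed dimerization
  expect_identical(p$k5, p$k1)
  expect_identical(p$k6, p$k1)
  expect_identical(p$k7, 0)
  expect_identical(p$p4, 0)
  # geometry of the source / bump regions
  expect_identical(p$wnt_source_right_edge, 10)
  expect_identical(p$sfrp1_source_left_edge, 25)
  expect_identical(c(p$bump_left, p$bump_right), c(10, 40))
})

test_that("parameter invariants are enforced", {
  expect_error(wnt_params(k1 = -1), "negative")
  expect_error(wnt_params(hill_n = 0.5), "hill_n")
  expect_error(wnt_params(x_max = 0), "x_max")
  expect_error(wnt_params(t_max = -10), "negative|t_max")
  expect_error(wnt_params(wnt_source_right_edge = 30), "region boundaries")
  expect_error(wnt_params(bump_left = 50, bump_right = 40), "bump")
  expect_error(wnt_params(k2 = NaN), "non-finite")
})

test_that("scenario switchboard validates its inputs", {
  s <- wnt_scenario()
  expect_identical(s$feedback_multiplier, 1)
  expect_true(s$sfrp1_enabled)
  expect_identical(s$dnfzd7_condition, "none")
  expect_error(wnt_scenario(feedback_multiplier = -1), "multipliers")
  expect_error(wnt_scenario(ligand_multiplier = Inf), "multipliers")
  expect_error(wnt_scenario(dnfzd7_condition = "weird"))
})

test_that("dnFzd7 condition table maps each label to its parameter row", {
  p <- wnt_params()
  none <- dnfzd7_condition_params("none", p)
  expect_identical(none, list(p4 = 0, k5 = p$k1, k6 = p$k1, k7 = 0))
  both <- dnfzd7_condition_params("both_functions", p)
  expect_identical(both, list(p4 = 100 * p$p3, k5 = p$k1, k6 = p$k1, k7 = 0))
  inact <- dnfzd7_condition_params("inactivate_only", p)
  expect_identical(inact, list(p4 = 100 * p$p3, k5 = 0, k6 = 0, k7 = p$k1))
  trap <- dnfzd7_condition_params("trap_only", p)
  expect_identical(trap, list(p4 = 100 * p$p3, k5 = p$k1, k6 = 0, k7 = 0))
  expect_error(dnfzd7_condition_params("k9", p), "unknown dnFzd7 condition")
})

test_that("scenario switches resolve to pure parameter overrides", {
  p <- wnt_params()
  eff <- effective_params(p, wnt_scenario(feedback_multiplier = 5,
                                          initial_receptor_multiplier = 4,
                                          ligand_multiplier = 1.5,
                                          sfrp1_enabled = FALSE,
                                          hs_enabled = FALSE,
                                          dnfzd7_condition = "trap_only"))
  expect_identical(eff$p3, 50)
  expect_identical(eff$r0, 300)
  expect_equal(eff$p1, 1.5e-4)
  expect_identical(eff$p2, 0)
  expect_identical(eff$h0_amp, 0)
  # dnFzd7 production ties to the base feedback coefficient, not the scaled one
  expect_identical(eff$p4, 1000)
  expect_identical(eff$k6, 0)
  # the base parameter object is untouched
  expect_identical(p$p3, 10)
})
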