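fixtures <- make_fixture_scenarios()
by_name <- function(nm) fixtures[[which(vapply(fixtures, `[[`, "", "name") == nm)]]

test_that("the fixture battery covers the required degenerate systems", {
  expect_gte(length(fixtures), 5)
  nms <- vapply(fixtures, `[[`, "", "name")
  expect_identical(anyDuplicated(nms), 0L)
  expect_true(all(c("no_ligand", "no_antagonist", "closed_ws",
                    "stiff_hs", "default_miniature") %in% nms))
  expect_identical(by_name("no_ligand")$scenario$ligand_multiplier, 0)
  for (f in fixtures) {
    expect_s3_class(f$params, "wnt_params")   # constructor enforces invariants
    expect_s3_class(f$scenario, "wnt_scenario")
    expect_gte(f$n_cells, 20)
  }
})

test_that("the explicit oracle refuses unstable steps and stiff fixtures", {
  expect_error(explicit_reference_simulate(by_name("oracle_mini"), dt = 10),
               "stability guard")
  expect_error(explicit_reference_simulate(by_name("stiff_hs")),
               "not explicit-integrable")
  expect_error(explicit_reference_simulate(by_name("oracle_mini"), dt = -1),
               "dt")
})

test_that("closed well-mixed Wnt/sFRP1 binding relaxes to the mass-action equilibrium", {
  f <- by_name("closed_ws")
  er <- explicit_reference_simulate(f)
  last <- er$states[f$n_time_samples, , ]
  # the field stays spatially uniform in a well-mixed closed system
  expect_lt(diff(range(last[, "WS"])), 1e-10)
  ratio <- last[1, "WS"] / (last[1, "W"] * last[1, "S"])
  K_eq <- wnt_params()$k2 / wnt_params()$k2_off   # ~0.0891 per nM
  expect_lt(abs(ratio - K_eq) / K_eq, 5e-3)
  # total Wnt and sFRP1 moieties are conserved in the closed system
  mb <- mass_balance_report(er)
  expect_true(all(mb$wnt_resid_rel < 1e-3))
  expect_lt(max(abs(mb$sfrp1_total - mb$sfrp1_total[1])) / mb$sfrp1_total[1],
            1e-3)
})

test_that("mass-balance report tracks every moiety against its closed form", {
  tr <- simulate_fixture(by_name("stiff_hs"))
  mb <- mass_balance_report(tr)
  expect_true(all(mb$hs_max_dev_rel < 1e-6))
  expect_true(all(mb$wnt_resid_rel[-1] < 1e-4))
  expect_true(all(mb$fzd_resid_rel < 1e-4))
  # no-ligand fixture: Wnt moiety identically absent
  mb0 <- mass_balance_report(simulate_fixture(by_name("no_ligand")))
  expect_true(all(mb0$wnt_total == 0))
})

test_that("dnFzd7 moiety grows exactly with the production integral", {
  f <- by_name("default_miniature")
  sc <- wnt_scenario(dnfzd7_condition = "trap_only")
  g <- discretize_domain(100, f$n_cells)
  tr <- simulate_trajectory(sc, f$params, g, n_time_samples = 11)
  mb <- mass_balance_report(tr)
  expect_gt(mb$dnfzd7_total[11], 0)
  expect_true(all(mb$dnfzd7_resid_rel < 1e-4))
})
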