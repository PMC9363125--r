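p <- wnt_params()
zero_state <- stats::setNames(numeric(14), wnt_species())

test_that("an empty field only produces ligand and antagonist in their regions", {
  g <- discretize_domain(100, 50)
  M <- matrix(0, 50, 14, dimnames = list(NULL, wnt_species()))
  d <- reaction_rhs(M, g$cell_centers, p)
  expect_equal(d[, "W"], p$p1 * as.numeric(g$cell_centers <= 10))
  expect_equal(d[, "S"], p$p2 * as.numeric(g$cell_centers >= 25))
  for (sp in setdiff(wnt_species(), c("W", "S")))
    expect_true(all(d[, sp] == 0))
})

test_that("ligand-receptor binding follows the two-receptor stoichiometry", {
  s <- zero_state; s["W"] <- 1; s["R"] <- 75
  d <- reaction_rhs(s, x = 20, params = p)
  expect_equal(d[["WR2"]], 2.66e-6 * 1 * 75^2)   # ~1.496e-2 nM/s
  expect_equal(d[["R"]], -2 * 2.66e-6 * 75^2)    # two receptors consumed
  expect_equal(d[["W"]], -2.66e-6 * 75^2)
  expect_equal(d[["omega"]], 0)
})

test_that("internalization drives signal accumulation and receptor feedback", {
  s <- zero_state; s["WR2"] <- 1
  d <- reaction_rhs(s, x = 20, params = p)
  expect_equal(d[["omega"]], 2.52e-4)
  # feedback production p3 k4 plus the two receptors returned by dissociation
  expect_equal(d[["R"]], 10 * 2.52e-4 + 2 * 9.6e-5)
  expect_equal(d[["W"]], 9.6e-5)
  expect_equal(d[["WR2"]], -(9.6e-5 + 2.52e-4))
})

test_that("silent networks are exactly at rest", {
  pq <- wnt_params(p1 = 0, p2 = 0)
  g <- discretize_domain(100, 20)
  M <- matrix(0, 20, 14)
  d <- reaction_rhs(M, g$cell_centers, pq)
  expect_identical(unname(d), matrix(0, 20, 14))
})

test_that("Wnt-catalysed dimerization and dnFzd7 stoichiometry", {
  pin <- do.call(wnt_params,
                 c(list(), dnfzd7_condition_params("inactivate_only", p)))
  s <- zero_state; s["W"] <- 1; s["R"] <- 2; s["Dn"] <- 3
  d <- reaction_rhs(s, x = 20, params = pin)
  expect_equal(d[["RD"]], pin$k7 * 1 * 2 * 3)
  expect_equal(d[["D2"]], pin$k7 * 1 * 9)
  # Dn is consumed once per heterodimer and twice per homodimer
  expect_equal(d[["Dn"]], -pin$k7 * 6 - 2 * pin$k7 * 9)
  expect_equal(d[["WD2"]], 0)  # trap function deleted in this condition
  # dimer dissociation returns both monomers
  s2 <- zero_state; s2["WD2"] <- 1; s2["D2"] <- 1
  d2 <- reaction_rhs(s2, x = 20, params = p)
  expect_equal(d2[["Dn"]], 2 * p$k1_off + 2 * p$k1_off)
  expect_equal(d2[["W"]], p$k1_off)
})

test_that("corrupt states are rejected with the offending species named", {
  s <- zero_state; s["SH"] <- -0.5
  expect_error(reaction_rhs(s, 20, p), "negative concentration.*SH")
  s2 <- zero_state; s2["WS"] <- NaN
  expect_error(reaction_rhs(s2, 20, p), "non-finite.*WS")
  expect_error(reaction_rhs(zero_state[1:10], 20, p), "14")
})
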