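# structural checks run at desk scale; the full-scale directional claims live
# in the acceptance suite
pm <- mini_params()
gm <- mini_grid()

test_that("feedback sweep runs the factorial and tabulates widths", {
  ex <- run_feedback_sweep(pm, gm, feedback_multipliers = c(0, 1),
                           initial_receptor_multipliers = 1,
                           thresholds = c(0.01, 0.05),
                           n_time_samples = 11)
  expect_s3_class(ex, "wnt_experiment")
  expect_length(ex$runs, 2)
  expect_identical(nrow(ex$tables$widths), 4L)
  expect_true(all(c("id", "feedback", "threshold", "width", "edge") %in%
                    names(ex$tables$widths)))
  # every run is traceable to its scenario
  ids <- vapply(ex$runs, `[[`, "", "id")
  expect_true(all(ex$tables$widths$id %in% ids))
  expect_error(run_feedback_sweep(pm, gm, feedback_multipliers = numeric(0)),
               "non-empty")
})

test_that("experiments are pure functions of their configuration", {
  a <- run_feedback_sweep(pm, gm, feedback_multipliers = 1,
                          initial_receptor_multipliers = 1,
                          n_time_samples = 11)
  b <- run_feedback_sweep(pm, gm, feedback_multipliers = 1,
                          initial_receptor_multipliers = 1,
                          n_time_samples = 11)
  expect_identical(a$tables$widths, b$tables$widths)
  expect_identical(a$runs[[1]]$trajectory$states, b$runs[[1]]$trajectory$states)
})

test_that("robustness experiment contrasts exactly two ligand levels", {
  expect_error(run_robustness_experiment(pm, gm, ligand_multipliers = c(1, 1.2, 1.5)),
               "exactly two")
  ex <- run_robustness_experiment(pm, gm, ligand_multipliers = c(1, 1),
                                  feedback_multipliers = 1,
                                  initial_receptor_multipliers = 1,
                                  n_time_samples = 11)
  expect_true(all(ex$tables$shifts$shift == 0))
  expect_identical(ex$tables$max_shift$max_shift, 0)
})

test_that("dnFzd7 experiment always carries the no-production reference", {
  ex <- run_dnfzd7_experiment(pm, gm, conditions = c("none", "trap_only"),
                              n_time_samples = 11)
  expect_length(ex$runs, 2)
  d0 <- subset(ex$tables$delta_vs_none, condition == "none")
  expect_true(all(d0$delta_omega == 0))
  dt <- subset(ex$tables$delta_vs_none, condition == "trap_only")
  expect_true(any(dt$delta_omega != 0))
})

test_that("antagonist contrast reports widths and steadiness, and off means off", {
  ex <- run_sfrp1_hs_experiment(pm, gm, threshold = 0.01,
                                n_time_samples = 11)
  expect_identical(nrow(ex$tables$summary), 2L)
  expect_true(all(c("width", "time_to_steady", "threshold_crossed") %in%
                    names(ex$tables$summary)))
  off <- ex$runs$both_off$trajectory
  for (sp in c("S", "WS", "SH", "WSH", "H"))
    expect_true(all(off$states[, , sp] == 0))
  exm <- run_sfrp1_hs_experiment(pm, gm, include_mixed = TRUE,
                                 threshold = 0.01, n_time_samples = 11)
  expect_identical(nrow(exm$tables$summary), 4L)
})
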