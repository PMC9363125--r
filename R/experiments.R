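#' Default edge threshold for signal-activity metrics
#'
#' The model prints no canonical threshold for the signal-active edge, so
#' edge-based claims are evaluated as threshold sweeps wherever possible.
#' Where a single level is needed (summary tables, steadiness times) the
#' package uses 1 nM: one tenth of the natural concentration scale
#' `c* = p1 * t_max = 10 nM`, i.e. a mid-gradient level comparable to the
#' dashed-line choice in the figures this reproduces.
#'
#' @return Threshold, nM.
#' @export
default_edge_threshold <- function() 1

new_experiment <- function(name, runs, tables, params, grid, solver) {
  structure(list(name = name, runs = runs, tables = tables,
                 provenance = list(params = params, grid = grid,
                                   solver = solver,
                                   package_version =
                                     as.character(utils::packageVersion("wntgrad")))),
            class = "wnt_experiment")
}

#' @export
print.wnt_experiment <- function(x, ...) {
  cat("<wnt_experiment>", x$name, "-", length(x$runs), "runs; tables:",
      paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

run_one <- function(id, scenario, params, grid, n_time_samples, rtol, atol) {
  traj <- tryCatch(
    simulate_trajectory(scenario, params, grid,
                        n_time_samples = n_time_samples,
                        rtol = rtol, atol = atol),
    error = function(e) stop("scenario '", id, "': ", conditionMessage(e)))
  list(id = id, scenario = scenario, trajectory = traj)
}

#' Feedback-strength / initial-receptor sweep
#'
#' Full factorial over receptor feedback multipliers and initial-receptor
#' multipliers (defaults: feedback 0 / 1 / 5 - none, normal, strong; initial
#' receptor 1 / 4), with no dnFzd7 and the antagonist / HS switches taken
#' from `base_scenario`. Tabulates the final omega profiles and the
#' signal-active width at each requested threshold.
#'
#' @param params base [wnt_params()].
#' @param grid a `wnt_grid`.
#' @param feedback_multipliers,initial_receptor_multipliers numeric vectors
#'   of levels (>= 0, non-empty).
#' @param thresholds thresholds for the width table (nM).
#' @param base_scenario scenario template supplying the sFRP1 / HS switches.
#' @param n_time_samples,rtol,atol passed to [simulate_trajectory()].
#' @return A `wnt_experiment` with tables `widths` (scenario id, multipliers,
#'   threshold, width) and `final_omega` (long format).
#' @export
run_feedback_sweep <- function(params = wnt_params(),
                               grid = discretize_domain(),
                               feedback_multipliers = c(0, 1, 5),
                               initial_receptor_multipliers = c(1, 4),
                               thresholds = default_edge_threshold(),
                               base_scenario = wnt_scenario(),
                               n_time_samples = 101,
                               rtol = 1e-6, atol = 1e-9) {
  if (length(feedback_multipliers) == 0 ||
      length(initial_receptor_multipliers) == 0)
    stop("multiplier lists must be non-empty")
  levels <- expand.grid(feedback = feedback_multipliers,
                        initial = initial_receptor_multipliers)
  runs <- lapply(seq_len(nrow(levels)), function(i) {
    sc <- wnt_scenario(feedback_multiplier = levels$feedback[i],
                       initial_receptor_multiplier = levels$initial[i],
                       ligand_multiplier = base_scenario$ligand_multiplier,
                       sfrp1_enabled = base_scenario$sfrp1_enabled,
                       hs_enabled = base_scenario$hs_enabled)
    run_one(sprintf("feedback_%g_initial_%g", levels$feedback[i],
                    levels$initial[i]),
            sc, params, grid, n_time_samples, rtol, atol)
  })
  widths <- do.call(rbind, lapply(runs, function(r) {
    om <- omega_profile(r$trajectory)
    do.call(rbind, lapply(thresholds, function(th)
      data.frame(id = r$id,
                 feedback = r$scenario$feedback_multiplier,
                 initial = r$scenario$initial_receptor_multiplier,
                 threshold = th,
                 width = active_region_width(om, th, grid),
                 edge = edge_position(om, th, grid))))
  }))
  final_omega <- do.call(rbind, lapply(runs, function(r)
    data.frame(id = r$id, x_um = grid$cell_centers,
               omega = omega_profile(r$trajectory))))
  new_experiment("feedback_sweep", runs,
                 list(widths = widths, final_omega = final_omega),
                 params, grid, list(n_time_samples = n_time_samples,
                                    rtol = rtol, atol = atol))
}

#' Robustness of the edge to a ligand-production change
#'
#' For each (feedback, initial receptor) combination, runs the model at two
#' ligand production levels (default 1.0 and 1.5, i.e. a 50 percent increase)
#' and tabulates the threshold-swept [edge_shift()]. Small shifts indicate a
#' boundary position robust to variation in Wnt production.
#'
#' @inheritParams run_feedback_sweep
#' @param ligand_multipliers exactly two ligand production multipliers.
#' @param thresholds optional explicit threshold sweep passed to
#'   [edge_shift()].
#' @return A `wnt_experiment`; table `shifts` has one row per (combination,
#'   threshold) and table `max_shift` the max-over-thresholds summary.
#' @export
run_robustness_experiment <- function(params = wnt_params(),
                                      grid = discretize_domain(),
                                      ligand_multipliers = c(1, 1.5),
                                      thresholds = NULL,
                                      feedback_multipliers = c(0, 1),
                                      initial_receptor_multipliers = c(1, 4),
                                      base_scenario = wnt_scenario(),
                                      n_time_samples = 101,
                                      rtol = 1e-6, atol = 1e-9) {
  if (length(ligand_multipliers) != 2)
    stop("ligand_multipliers must contain exactly two levels")
  combos <- expand.grid(feedback = feedback_multipliers,
                        initial = initial_receptor_multipliers)
  runs <- list(); shifts <- list(); max_shift <- list()
  for (i in seq_len(nrow(combos))) {
    pair <- lapply(ligand_multipliers, function(lm) {
      sc <- wnt_scenario(feedback_multiplier = combos$feedback[i],
                         initial_receptor_multiplier = combos$initial[i],
                         ligand_multiplier = lm,
                         sfrp1_enabled = base_scenario$sfrp1_enabled,
                         hs_enabled = base_scenario$hs_enabled)
      run_one(sprintf("feedback_%g_initial_%g_ligand_%g",
                      combos$feedback[i], combos$initial[i], lm),
              sc, params, grid, n_time_samples, rtol, atol)
    })
    runs <- c(runs, pair)
    sh <- edge_shift(pair[[1]]$trajectory, pair[[2]]$trajectory, thresholds)
    sh$feedback <- combos$feedback[i]
    sh$initial <- combos$initial[i]
    shifts[[i]] <- sh
    max_shift[[i]] <- data.frame(feedback = combos$feedback[i],
                                 initial = combos$initial[i],
                                 max_shift = max(sh$shift))
  }
  new_experiment("robustness", runs,
                 list(shifts = do.call(rbind, shifts),
                      max_shift = do.call(rbind, max_shift)),
                 params, grid, list(n_time_samples = n_time_samples,
                                    rtol = rtol, atol = atol))
}

#' Dissection of the two dominant-negative Fzd7 functions
#'
#' Runs the four dnFzd7 conditions (no production; both functions; only
#' 'inactivate-Fzd7'; only 'trap-Wnt') with an otherwise default scenario and
#' tabulates the final omega profiles and their differences against the
#' no-dnFzd7 condition.
#'
#' @inheritParams run_feedback_sweep
#' @param conditions subset of the four condition labels (the no-dnFzd7
#'   reference `"none"` is always included).
#' @return A `wnt_experiment` with tables `final_omega` and `delta_vs_none`.
#' @export
run_dnfzd7_experiment <- function(params = wnt_params(),
                                  grid = discretize_domain(),
                                  conditions = c("none", "both_functions",
                                                 "inactivate_only", "trap_only"),
                                  base_scenario = wnt_scenario(),
                                  n_time_samples = 101,
                                  rtol = 1e-6, atol = 1e-9) {
  conditions <- union("none", conditions)
  runs <- lapply(conditions, function(cond) {
    sc <- wnt_scenario(feedback_multiplier = base_scenario$feedback_multiplier,
                       initial_receptor_multiplier =
                         base_scenario$initial_receptor_multiplier,
                       ligand_multiplier = base_scenario$ligand_multiplier,
                       sfrp1_enabled = base_scenario$sfrp1_enabled,
                       hs_enabled = base_scenario$hs_enabled,
                       dnfzd7_condition = cond)
    run_one(paste0("dnfzd7_", cond), sc, params, grid,
            n_time_samples, rtol, atol)
  })
  names(runs) <- conditions
  om_none <- omega_profile(runs[["none"]]$trajectory)
  final_omega <- do.call(rbind, lapply(runs, function(r)
    data.frame(condition = r$scenario$dnfzd7_condition,
               x_um = grid$cell_centers, omega = omega_profile(r$trajectory))))
  delta <- do.call(rbind, lapply(runs, function(r)
    data.frame(condition = r$scenario$dnfzd7_condition,
               x_um = grid$cell_centers,
               delta_omega = omega_profile(r$trajectory) - om_none)))
  new_experiment("dnfzd7", runs,
                 list(final_omega = final_omega, delta_vs_none = delta),
                 params, grid, list(n_time_samples = n_time_samples,
                                    rtol = rtol, atol = atol))
}

#' Contrast of sFRP1 and N-acetyl heparan sulfate contributions
#'
#' Runs the model with the antagonist system fully on (sFRP1 + HS) and fully
#' off, optionally also the two mixed cases, at configurable feedback /
#' initial-receptor levels. Tabulates kymographs, signal-active widths at the
#' default threshold, and the time for the edge to become steady.
#'
#' @inheritParams run_feedback_sweep
#' @param include_mixed also run sFRP1-without-HS and HS-without-sFRP1
#'   (mechanism-dissection extras beyond the on/off contrast).
#' @param threshold threshold for widths and steadiness times (nM).
#' @param epsilon steadiness tolerance for [time_to_steady_edge()], um.
#' @return A `wnt_experiment` with tables `summary` (width, edge,
#'   time_to_steady per scenario) and per-run kymographs in `runs`.
#' @export
run_sfrp1_hs_experiment <- function(params = wnt_params(),
                                    grid = discretize_domain(),
                                    include_mixed = FALSE,
                                    threshold = default_edge_threshold(),
                                    epsilon = 1,
                                    base_scenario = wnt_scenario(),
                                    n_time_samples = 101,
                                    rtol = 1e-6, atol = 1e-9) {
  cases <- list(both_on = c(TRUE, TRUE), both_off = c(FALSE, FALSE))
  if (include_mixed)
    cases <- c(cases, list(sfrp1_only = c(TRUE, FALSE),
                           hs_only = c(FALSE, TRUE)))
  runs <- lapply(names(cases), function(nm) {
    sw <- cases[[nm]]
    sc <- wnt_scenario(feedback_multiplier = base_scenario$feedback_multiplier,
                       initial_receptor_multiplier =
                         base_scenario$initial_receptor_multiplier,
                       ligand_multiplier = base_scenario$ligand_multiplier,
                       sfrp1_enabled = sw[1], hs_enabled = sw[2])
    run_one(nm, sc, params, grid, n_time_samples, rtol, atol)
  })
  names(runs) <- names(cases)
  summary <- do.call(rbind, lapply(runs, function(r) {
    om <- omega_profile(r$trajectory)
    tse <- time_to_steady_edge(r$trajectory, threshold, epsilon)
    data.frame(id = r$id,
               sfrp1 = r$scenario$sfrp1_enabled, hs = r$scenario$hs_enabled,
               threshold = threshold,
               width = active_region_width(om, threshold, grid),
               edge = edge_position(om, threshold, grid),
               time_to_steady = as.numeric(tse),
               threshold_crossed = attr(tse, "threshold_crossed"))
  }))
  new_experiment("sfrp1_hs", runs, list(summary = summary),
                 params, grid, list(n_time_samples = n_time_samples,
                                    rtol = rtol, atol = atol,
                                    threshold = threshold, epsilon = epsilon))
}
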