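#' Deterministic desk-scale fixtures
#'
#' Reduced-cost scenario configurations used to validate the solver and the
#' metrics: short horizons, coarse grids and - where the explicit reference
#' integrator is involved - a softened heparan-sulfate amplitude (1e3 nM
#' instead of 1e8 nM), since explicit integration at the full HS binding rate
#' `k3 * h0_amp ~ 2e4 s^-1` is infeasible over any useful horizon. Fixtures
#' are seed-free and fully deterministic.
#'
#' Returned fixtures:
#' * `no_ligand`: ligand production off; every Wnt-containing species and
#'   omega must stay identically zero, R stays at its initial profile.
#' * `no_antagonist`: sFRP1 and HS off; all S/H-containing species stay zero.
#' * `closed_ws`: closed well-mixed Wnt + sFRP1 binding system (uniform
#'   initial W and S, all production off); relaxes to the binding equilibrium
#'   `[WS]/([W][S]) = k2 / k2_off`.
#' * `oracle_mini`: softened miniature of the default scenario (25 cells,
#'   t_max = 1e3 s, HS 1e3 nM) - the oracle-equivalence workhorse.
#' * `stiff_hs`: full-stiffness HS (1e8 nM) on a coarse short run; validated
#'   through conservation laws only (`oracle_feasible = FALSE`).
#' * `default_miniature`: the default scenario at 50 cells and t_max = 1e4 s,
#'   full stiffness; the conservation-suite fixture.
#'
#' @return List of `wnt_fixture` objects with fields `name`, `params`,
#'   `scenario`, `n_cells`, `n_time_samples`, `oracle_dt` (suggested explicit
#'   step, s), `oracle_feasible`, `initial_uniform` (optional named
#'   concentrations overriding the standard initial state), `description`.
#' @export
make_fixture_scenarios <- function() {
  fx <- function(name, params, scenario, n_cells, oracle_dt, oracle_feasible,
                 initial_uniform = NULL, n_time_samples = 11,
                 description = "") {
    structure(list(name = name, params = params, scenario = scenario,
                   n_cells = n_cells, n_time_samples = n_time_samples,
                   oracle_dt = oracle_dt, oracle_feasible = oracle_feasible,
                   initial_uniform = initial_uniform,
                   description = description),
              class = "wnt_fixture")
  }
  list(
    fx("no_ligand", wnt_params(t_max = 2e3, h0_amp = 1e3),
       wnt_scenario(ligand_multiplier = 0),
       n_cells = 25, oracle_dt = 0.02, oracle_feasible = TRUE,
       description = "no Wnt source: signal stays zero, sFRP1 partitions onto HS"),
    fx("no_antagonist", wnt_params(t_max = 2e3),
       wnt_scenario(sfrp1_enabled = FALSE, hs_enabled = FALSE),
       n_cells = 25, oracle_dt = 0.02, oracle_feasible = TRUE,
       description = "ligand/receptor subsystem only"),
    fx("closed_ws", wnt_params(t_max = 1e4),
       wnt_scenario(ligand_multiplier = 0, initial_receptor_multiplier = 0,
                    sfrp1_enabled = FALSE, hs_enabled = FALSE),
       n_cells = 20, oracle_dt = 0.05, oracle_feasible = TRUE,
       initial_uniform = c(W = 10, S = 10),
       description = "closed well-mixed W+S binding; relaxes to k2/k2_off"),
    fx("oracle_mini", wnt_params(t_max = 1e3, h0_amp = 1e3), wnt_scenario(),
       n_cells = 25, oracle_dt = 0.02, oracle_feasible = TRUE,
       description = "softened miniature of the default scenario"),
    fx("stiff_hs", wnt_params(t_max = 1e4), wnt_scenario(),
       n_cells = 25, oracle_dt = NA_real_, oracle_feasible = FALSE,
       description = "full-stiffness HS; conservation-law validation only"),
    fx("default_miniature", wnt_params(t_max = 1e4), wnt_scenario(),
       n_cells = 50, oracle_dt = NA_real_, oracle_feasible = FALSE,
       n_time_samples = 21,
       description = "default scenario at desk scale; conservation suite")
  )
}

#' @export
print.wnt_fixture <- function(x, ...) {
  cat("<wnt_fixture>", x$name, "-", x$description, "\n")
  invisible(x)
}

fixture_grid <- function(fixture) {
  discretize_domain(fixture$params$x_max, fixture$n_cells)
}

fixture_state0 <- function(fixture, grid) {
  eff <- effective_params(fixture$params, fixture$scenario)
  M <- initial_state(eff, grid, wnt_scenario())
  if (!is.null(fixture$initial_uniform))
    for (sp in names(fixture$initial_uniform))
      M[, sp] <- fixture$initial_uniform[[sp]]
  M
}

#' Run a fixture through the main stiff solver
#'
#' @param fixture a `wnt_fixture`.
#' @param rtol,atol solver tolerances.
#' @return A `wnt_trajectory`.
#' @export
simulate_fixture <- function(fixture, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(fixture, "wnt_fixture"))
  grid <- fixture_grid(fixture)
  simulate_trajectory(fixture$scenario, fixture$params, grid,
                      n_time_samples = fixture$n_time_samples,
                      rtol = rtol, atol = atol,
                      state0 = fixture_state0(fixture, grid))
}

#' Independent fixed-step explicit reference integrator
#'
#' Forward-Euler transcription of the reaction network and the zero-flux
#' diffusion stencil, written independently of the stiff solver path (no
#' shared right-hand-side code) and used as the oracle against which
#' [simulate_trajectory()] is validated on softened fixtures. A stability
#' guard rejects steps too large for the fixture's fastest rate or for the
#' explicit diffusion limit.
#'
#' @param fixture a `wnt_fixture` with `oracle_feasible = TRUE`.
#' @param dt fixed step, s (default: the fixture's `oracle_dt`).
#' @return A `wnt_trajectory` (diagnostics record the method as
#'   `"forward_euler"`).
#' @export
explicit_reference_simulate <- function(fixture, dt = fixture$oracle_dt) {
  stopifnot(inherits(fixture, "wnt_fixture"))
  if (!isTRUE(fixture$oracle_feasible))
    stop("fixture '", fixture$name,
         "' is not explicit-integrable (full-stiffness HS)")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  grid <- fixture_grid(fixture)
  p <- effective_params(fixture$params, fixture$scenario)
  n <- grid$n_cells; dx <- grid$cell_width
  x <- grid$cell_centers
  M <- fixture_state0(fixture, grid)

  # stability guard: dt * (fastest first-order rate) must stay below 0.1
  conc_scale <- p$p1 * p$t_max + p$p2 * p$t_max +
    if (is.null(fixture$initial_uniform)) 0 else sum(fixture$initial_uniform)
  r_max <- 2 * max(M[, "R"]) + p$p3 * conc_scale
  rate_bound <- max(2 * p$diff_coef / dx^2,
                    p$k3 * max(M[, "H"]) + p$k3_off,
                    p$k2 * conc_scale + p$k2_off,
                    p$k1 * r_max^2, p$k1_off, p$k4)
  if (dt * rate_bound >= 0.1)
    stop("explicit stability guard violated: dt * max rate = ",
         format(dt * rate_bound), " >= 0.1 (reduce dt or soften the fixture)")

  save_times <- seq(0, p$t_max, length.out = fixture$n_time_samples)
  n_steps <- ceiling(p$t_max / dt)
  dt <- p$t_max / n_steps           # land exactly on t_max
  save_idx <- round(save_times / dt)
  states <- array(0, dim = c(length(save_times), n, N_SPECIES),
                  dimnames = list(NULL, NULL, wnt_species()))
  states[1, , ] <- M

  fx <- as.numeric(x <= p$wnt_source_right_edge)
  gx <- as.numeric(x >= p$sfrp1_source_left_edge)
  si <- 2L
  for (s in seq_len(n_steps)) {
    W <- M[, 1]; S <- M[, 2]; WS <- M[, 3]; H <- M[, 4]; SH <- M[, 5]
    WSH <- M[, 6]; R <- M[, 7]; WR2 <- M[, 8]; Dn <- M[, 9]; RD <- M[, 10]
    D2 <- M[, 11]; WD2 <- M[, 12]; WRD <- M[, 13]; om <- M[, 14]
    lap <- function(c) {
      (c(c[1], c[-n]) - 2 * c + c(c[-1], c[n])) / dx^2
    }
    assoc_wr  <- p$k1 * W * R * R;    dis_wr  <- p$k1_off * WR2
    assoc_ws  <- p$k2 * W * S;        dis_ws  <- p$k2_off * WS
    assoc_wsh <- p$k2 * W * SH;       dis_wsh <- p$k2_off * WSH
    assoc_sh  <- p$k3 * S * H;        dis_sh  <- p$k3_off * SH
    assoc_wsh2 <- p$k3 * WS * H;      dis_wsh2 <- p$k3_off * WSH
    assoc_wd2 <- p$k5 * W * Dn * Dn;  dis_wd2 <- p$k1_off * WD2
    assoc_wrd <- p$k6 * W * R * Dn;   dis_wrd <- p$k1_off * WRD
    assoc_rd  <- p$k7 * W * R * Dn;   dis_rd  <- p$k1_off * RD
    assoc_d2  <- p$k7 * W * Dn * Dn;  dis_d2  <- p$k1_off * D2
    endo <- p$k4 * WR2
    hill <- 1 / ((om / p$Kd)^p$hill_n + 1)
    M <- cbind(
      W + dt * (p$diff_coef * lap(W) - assoc_wr + dis_wr - assoc_ws + dis_ws -
                  assoc_wsh + dis_wsh - assoc_wd2 + dis_wd2 -
                  assoc_wrd + dis_wrd + p$p1 * fx),
      S + dt * (p$diff_coef * lap(S) - assoc_ws + dis_ws - assoc_sh + dis_sh +
                  p$p2 * hill * gx),
      WS + dt * (p$diff_coef * lap(WS) + assoc_ws - dis_ws -
                   assoc_wsh2 + dis_wsh2),
      H + dt * (-assoc_sh + dis_sh - assoc_wsh2 + dis_wsh2),
      SH + dt * (-assoc_wsh + dis_wsh + assoc_sh - dis_sh),
      WSH + dt * (assoc_wsh - dis_wsh + assoc_wsh2 - dis_wsh2),
      R + dt * (-2 * assoc_wr + 2 * dis_wr - assoc_wrd + dis_wrd -
                  assoc_rd + dis_rd + p$p3 * endo),
      WR2 + dt * (assoc_wr - dis_wr - endo),
      Dn + dt * (-2 * assoc_wd2 + 2 * dis_wd2 - assoc_wrd + dis_wrd -
                   assoc_rd + dis_rd - 2 * assoc_d2 + 2 * dis_d2 +
                   p$p4 * endo),
      RD + dt * (assoc_rd - dis_rd),
      D2 + dt * (assoc_d2 - dis_d2),
      WD2 + dt * (assoc_wd2 - dis_wd2),
      WRD + dt * (assoc_wrd - dis_wrd),
      om + dt * endo)
    if (si <= length(save_idx) && s == save_idx[si]) {
      states[si, , ] <- M
      si <- si + 1L
    }
  }
  colnames(M) <- wnt_species()
  traj <- list(times = save_times, states = states, grid = grid,
               scenario = fixture$scenario, params = fixture$params,
               eff_params = p,
               diagnostics = list(method = "forward_euler", dt = dt,
                                  n_steps = n_steps))
  class(traj) <- "wnt_trajectory"
  traj
}

#' Conservation / mass-balance report for a trajectory
#'
#' Integrated totals of each conserved moiety against their closed-form
#' expectations from the network stoichiometry:
#' * Wnt moiety `W + WS + WSH + WR2 + WD2 + WRD + omega` grows exactly with
#'   the production integral `p1 * (discrete source width) * t` (omega books
#'   the internalized ligand, so the sum is conservative);
#' * Fzd7 moiety `R + 2 WR2 + RD + WRD` changes only through feedback
#'   production minus internalization, i.e. by `(p3 - 2) * integral(omega)`;
#' * dnFzd7 moiety `Dn + RD + 2 D2 + 2 WD2 + WRD` grows by
#'   `p4 * integral(omega)` (no removal);
#' * per-cell HS moiety `H + SH + WSH` is time-invariant;
#' * total sFRP1 moiety `S + WS + SH + WSH` is non-decreasing.
#'
#' The source width is the measure of grid cells whose centres lie in the
#' production region (equal to the nominal 10 um whenever the cell width
#' divides 10 um, e.g. on the default and miniature grids).
#'
#' @param traj a `wnt_trajectory`.
#' @return `data.frame` with one row per saved time: totals (nM um),
#'   expectations and relative residuals for Wnt / Fzd7 / dnFzd7, the total
#'   sFRP1 moiety, and the maximum relative per-cell HS deviation.
#' @export
mass_balance_report <- function(traj) {
  stopifnot(inherits(traj, "wnt_trajectory"))
  p <- traj$eff_params
  g <- traj$grid
  dx <- g$cell_width
  src_width <- sum(g$cell_centers <= p$wnt_source_right_edge) * dx
  S0 <- traj$states[1, , ]
  hs0 <- S0[, "H"] + S0[, "SH"] + S0[, "WSH"]
  tot <- function(M, sp) sum(M[, sp]) * dx
  wnt_t <- function(M) sum(M[, c("W", "WS", "WSH", "WR2", "WD2", "WRD",
                                 "omega")]) * dx
  fzd_t <- function(M) sum(M[, "R"] + 2 * M[, "WR2"] + M[, "RD"] +
                             M[, "WRD"]) * dx
  dn_t <- function(M) sum(M[, "Dn"] + M[, "RD"] + 2 * M[, "D2"] +
                            2 * M[, "WD2"] + M[, "WRD"]) * dx
  sfrp_t <- function(M) sum(M[, c("S", "WS", "SH", "WSH")]) * dx
  wnt0 <- wnt_t(S0); fzd0 <- fzd_t(S0); dn0 <- dn_t(S0)
  rows <- lapply(seq_along(traj$times), function(i) {
    M <- traj$states[i, , ]
    t <- traj$times[i]
    om_int <- tot(M, "omega")
    wnt <- wnt_t(M)
    wnt_exp <- wnt0 + p$p1 * src_width * t
    fzd <- fzd_t(M)
    fzd_exp <- fzd0 + (p$p3 - 2) * om_int
    dn <- dn_t(M)
    dn_exp <- dn0 + p$p4 * om_int
    rel <- function(a, b) if (abs(b) > 0) abs(a - b) / abs(b) else abs(a - b)
    data.frame(
      time = t,
      wnt_total = wnt, wnt_expected = wnt_exp,
      wnt_resid_rel = rel(wnt, wnt_exp),
      fzd_total = fzd, fzd_expected = fzd_exp,
      fzd_resid_rel = rel(fzd, fzd_exp),
      dnfzd7_total = dn, dnfzd7_expected = dn_exp,
      dnfzd7_resid_rel = rel(dn, dn_exp),
      sfrp1_total = sfrp_t(M),
      hs_max_dev_rel = max(abs(M[, "H"] + M[, "SH"] + M[, "WSH"] - hs0) /
                             pmax(hs0, 1)))
  })
  do.call(rbind, rows)
}
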