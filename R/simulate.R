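#' Initial state of the field
#'
#' All concentrations start at zero except the receptor and N-acetyl HS
#' bumps. The scenario's initial-receptor multiplier and HS switch are
#' honoured via the profile functions.
#'
#' @param params a [wnt_params()].
#' @param grid a [discretize_domain()] grid.
#' @param scenario a [wnt_scenario()].
#' @return `n_cells x 14` matrix, columns named as [wnt_species()].
#' @export
initial_state <- function(params = wnt_params(), grid = discretize_domain(),
                          scenario = wnt_scenario()) {
  M <- matrix(0, nrow = grid$n_cells, ncol = N_SPECIES,
              dimnames = list(NULL, wnt_species()))
  M[, "R"] <- initial_receptor_profile(grid$cell_centers, params, scenario)
  M[, "H"] <- initial_hs_profile(grid$cell_centers, params, scenario)
  M
}

#' Simulate the Wnt6 gradient model
#'
#' Integrates the full method-of-lines system (14 state components per grid
#' cell: 13 species plus the cumulative signalling activity omega) from the
#' standard initial conditions to `t_max`, using the implicit multistep BDF
#' solver of \pkg{deSolve} (`vode`) with an internally generated banded
#' Jacobian. The system is severely stiff: with the default HS amplitude the
#' fastest binding rate `k3 * h0_amp` is of order 1e4 s^-1 while the horizon
#' is 1e5 s, ruling out explicit schemes.
#'
#' The flattened solver state is ordered cell-major (the 14 components of a
#' cell are adjacent, cells in increasing x), which makes the Jacobian banded
#' with half-bandwidth 14: reactions couple only within a cell and diffusion
#' only to the same species in neighbouring cells. Saved trajectories are
#' re-shaped to a `[time, cell, species]` array, so this ordering is
#' invisible to callers.
#'
#' Mass-action kinetics preserve non-negativity in exact arithmetic; small
#' negative solver excursions (above `-1000 * atol`) are clipped to zero in
#' the saved states only, while larger violations abort with a solver error.
#'
#' @param scenario a [wnt_scenario()].
#' @param params base [wnt_params()]; scenario switches are applied via
#'   [effective_params()].
#' @param grid a [discretize_domain()] grid (default 200 cells, 0.5 um).
#' @param n_time_samples number of uniformly spaced save times including
#'   t = 0 and t = t_max (default 101).
#' @param rtol,atol relative / absolute solver tolerances (defaults 1e-6 and
#'   1e-9 nM).
#' @param state0 optional initial state matrix (`n_cells x 14`) overriding
#'   [initial_state()]; used by desk-scale fixtures (e.g. closed well-mixed
#'   binding systems).
#' @return Object of class `wnt_trajectory`: list with `times` (s), `states`
#'   (`n_times x n_cells x 14` array, species dimension named), `grid`,
#'   `scenario`, `params` (base), `eff_params` (resolved), and `diagnostics`
#'   (solver steps, tolerances, most negative raw state).
#' @examples
#' \donttest{
#' tr <- simulate_trajectory(wnt_scenario(), wnt_params(t_max = 1e4),
#'                           discretize_domain(100, 50))
#' dim(tr$states)
#' }
#' @export
simulate_trajectory <- function(scenario = wnt_scenario(),
                                params = wnt_params(),
                                grid = discretize_domain(),
                                n_time_samples = 101,
                                rtol = 1e-6, atol = 1e-9,
                                state0 = NULL) {
  stopifnot(inherits(grid, "wnt_grid"))
  n_time_samples <- as.integer(n_time_samples)
  if (is.na(n_time_samples) || n_time_samples < 2)
    stop("n_time_samples must be >= 2")
  eff <- effective_params(params, scenario)
  if (is.null(state0)) {
    state0 <- initial_state(eff, grid, wnt_scenario())  # eff already scaled
  } else {
    state0 <- as.matrix(state0)
    if (!all(dim(state0) == c(grid$n_cells, N_SPECIES)))
      stop("state0 must be an n_cells x 14 matrix")
  }
  n <- grid$n_cells
  dx2 <- grid$cell_width^2
  x <- grid$cell_centers
  Dc <- eff$diff_coef

  rhs_mol <- function(t, y, parms) {
    M <- matrix(y, nrow = N_SPECIES)        # species x cells
    Mt <- t(M)
    dM <- reaction_rhs_raw(Mt, x, eff)
    for (j in 1:3) {                        # W, S, WS diffuse
      cj <- Mt[, j]
      left <- c(cj[1L], cj[-n]); right <- c(cj[-1L], cj[n])
      dM[, j] <- dM[, j] + Dc * (left - 2 * cj + right) / dx2
    }
    list(as.vector(t(dM)))
  }

  times <- seq(0, eff$t_max, length.out = n_time_samples)
  out <- deSolve::ode(y = as.vector(t(state0)), times = times, func = rhs_mol,
                      parms = NULL, method = "vode", jactype = "bandint",
                      bandup = N_SPECIES, banddown = N_SPECIES,
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (is.null(istate) || istate[1] < 0)
    stop("stiff integrator failed (istate = ",
         if (is.null(istate)) "NULL" else istate[1], ")")
  Y <- unclass(out)[, -1, drop = FALSE]
  if (any(!is.finite(Y))) stop("non-finite values in integrated state")
  min_raw <- min(Y)
  if (min_raw < -1000 * atol)
    stop("negative concentration ", format(min_raw),
         " below solver credibility floor (-1000 * atol); ",
         "the run is not trustworthy")
  Y[Y < 0] <- 0
  states <- array(0, dim = c(n_time_samples, n, N_SPECIES),
                  dimnames = list(NULL, NULL, wnt_species()))
  for (i in seq_len(n_time_samples))
    states[i, , ] <- t(matrix(Y[i, ], nrow = N_SPECIES))

  traj <- list(times = times, states = states, grid = grid,
               scenario = scenario, params = params, eff_params = eff,
               diagnostics = list(n_steps = istate[3], rtol = rtol, atol = atol,
                                  n_time_samples = n_time_samples,
                                  min_raw_state = min_raw))
  class(traj) <- "wnt_trajectory"
  traj
}

#' @export
print.wnt_trajectory <- function(x, ...) {
  cat("<wnt_trajectory>", length(x$times), "times x", x$grid$n_cells,
      "cells x", N_SPECIES, "components; t in [0,",
      format(max(x$times)), "] s\n")
  print(x$scenario)
  om <- x$states[length(x$times), , "omega"]
  cat("  final omega: max", format(max(om), digits = 4), "nM at x =",
      format(x$grid$cell_centers[which.max(om)]), "um\n")
  invisible(x)
}

#' Extract the omega profile at a saved time
#'
#' @param traj a `wnt_trajectory`.
#' @param time_index index into `traj$times` (default: the final time).
#' @return Numeric vector over grid cells, nM.
#' @export
omega_profile <- function(traj, time_index = length(traj$times)) {
  stopifnot(inherits(traj, "wnt_trajectory"))
  traj$states[time_index, , "omega"]
}
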