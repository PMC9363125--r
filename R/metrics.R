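#' Edge of the Wnt-signal-active region
#'
#' The signal-active region is the set of positions where the cumulative
#' signalling activity omega meets a threshold; its edge is the outermost
#' (rightmost, i.e. farthest from the epidermal Wnt source at x = 0) boundary.
#' The edge is located by linear interpolation between the last cell centre
#' with `omega >= threshold` and its right neighbour. Sentinels: 0 when the
#' profile is everywhere below the threshold, `x_max` when everywhere above
#' (or when the last cell itself is above).
#'
#' @param omega_profile omega over grid cells (nM).
#' @param threshold activity threshold (nM), > 0.
#' @param grid a `wnt_grid`, or a numeric vector of cell-centre positions
#'   (um) of the same length as `omega_profile`.
#' @param x_max domain width used for the everywhere-active sentinel; taken
#'   from `grid` when a `wnt_grid` is given.
#' @return Edge position, um.
#' @examples
#' edge_position(c(10, 6, 2), 4, grid = c(0, 50, 100), x_max = 100)
#' @export
edge_position <- function(omega_profile, threshold, grid, x_max = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")
  if (inherits(grid, "wnt_grid")) {
    centers <- grid$cell_centers
    if (is.null(x_max)) x_max <- grid$x_max
  } else {
    centers <- as.numeric(grid)
    if (is.null(x_max)) x_max <- max(centers)
  }
  n <- length(centers)
  stopifnot(length(omega_profile) == n)
  above <- omega_profile >= threshold
  if (!any(above)) return(0)
  i <- max(which(above))
  if (i == n) return(x_max)
  # interpolate the crossing between centre i and its right neighbour
  centers[i] + (omega_profile[i] - threshold) /
    (omega_profile[i] - omega_profile[i + 1]) * (centers[i + 1] - centers[i])
}

#' Width of the Wnt-signal-active region
#'
#' Total measure of the super-threshold set of the piecewise-linear
#' interpolant of the omega profile through the cell centres (constant
#' extension from the first / last centre to the domain boundaries). For the
#' monotone-decreasing profiles this model produces when signal reaches the
#' domain edge, the width equals [edge_position()]; for non-monotone profiles
#' (e.g. a receptor bump detached from the source) every super-threshold
#' interval contributes.
#'
#' @inheritParams edge_position
#' @return Width, um.
#' @export
active_region_width <- function(omega_profile, threshold, grid, x_max = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")
  if (inherits(grid, "wnt_grid")) {
    centers <- grid$cell_centers
    if (is.null(x_max)) x_max <- grid$x_max
  } else {
    centers <- as.numeric(grid)
    if (is.null(x_max)) x_max <- max(centers)
  }
  n <- length(centers)
  stopifnot(length(omega_profile) == n)
  # piecewise-linear nodes, padded with flat ends covering [0, x_max]
  xs <- c(min(0, centers[1]), centers, x_max)
  ys <- c(omega_profile[1], omega_profile, omega_profile[n])
  width <- 0
  for (k in seq_len(length(xs) - 1)) {
    x0 <- xs[k]; x1 <- xs[k + 1]
    if (x1 <= x0) next
    y0 <- ys[k]; y1 <- ys[k + 1]
    if (y0 >= threshold && y1 >= threshold) {
      width <- width + (x1 - x0)
    } else if (y0 >= threshold || y1 >= threshold) {
      frac <- (max(y0, y1) - threshold) / abs(y1 - y0)
      width <- width + frac * (x1 - x0)
    }
  }
  width
}

#' Edge shift between two trajectories across a threshold sweep
#'
#' Robustness statistic for perturbations of ligand production: for each
#' threshold, the absolute difference of the final-time edge positions of the
#' two trajectories. "All possible thresholds" is realised as a dense sweep;
#' by default 200 log-spaced levels between `1e-3 * max(omega)` and
#' `max(omega)` of the base run.
#'
#' @param traj_base,traj_perturbed `wnt_trajectory` objects sharing grid and
#'   times.
#' @param thresholds optional threshold vector (nM); default as above.
#' @return `data.frame` with columns `threshold`, `edge_base`,
#'   `edge_perturbed`, `shift` (um).
#' @export
edge_shift <- function(traj_base, traj_perturbed, thresholds = NULL) {
  stopifnot(inherits(traj_base, "wnt_trajectory"),
            inherits(traj_perturbed, "wnt_trajectory"))
  if (!isTRUE(all.equal(traj_base$grid$cell_centers,
                        traj_perturbed$grid$cell_centers)) ||
      !isTRUE(all.equal(traj_base$times, traj_perturbed$times)))
    stop("trajectories must share grid and sample times")
  om_b <- omega_profile(traj_base)
  om_p <- omega_profile(traj_perturbed)
  if (is.null(thresholds)) {
    top <- max(om_b)
    if (top <= 0) stop("base trajectory has no signal; cannot build sweep")
    thresholds <- top * exp(seq(log(1e-3), 0, length.out = 200))
    # the top level must equal max(omega) exactly: rounding it above the
    # maximum would flip the base edge to the nowhere-active sentinel and
    # poison the max-shift statistic
    thresholds[length(thresholds)] <- top
  }
  g <- traj_base$grid
  eb <- vapply(thresholds, function(th) edge_position(om_b, th, g), numeric(1))
  ep <- vapply(thresholds, function(th) edge_position(om_p, th, g), numeric(1))
  data.frame(threshold = thresholds, edge_base = eb, edge_perturbed = ep,
             shift = abs(ep - eb))
}

#' Kymograph of signalling activity
#'
#' Space-time matrix of omega: row i is the omega profile at `times[i]`, rows
#' ordered top-to-bottom by increasing time (the conventional kymograph
#' orientation), columns ordered by cell-centre position.
#'
#' @param traj a `wnt_trajectory` with at least 2 saved times.
#' @return Numeric matrix `n_times x n_cells` with times as rownames and
#'   cell centres as colnames.
#' @export
kymograph <- function(traj) {
  stopifnot(inherits(traj, "wnt_trajectory"))
  if (length(traj$times) < 2)
    stop("kymograph needs a trajectory with at least 2 time samples")
  K <- traj$states[, , "omega"]
  dimnames(K) <- list(format(traj$times, trim = TRUE),
                      format(traj$grid$cell_centers, trim = TRUE))
  K
}

#' Time until the signal-active edge becomes steady
#'
#' The earliest saved time t0 such that the edge position at the given
#' threshold stays within `epsilon` of its final value for every saved time
#' `>= t0`. This quantifies the "verticality" of the threshold contour in the
#' kymograph: a system that quickly reaches a steady boundary has a small
#' value. If the threshold is never crossed at the final time the function
#' returns `t_max` with attribute `threshold_crossed = FALSE`.
#'
#' @param traj a `wnt_trajectory`.
#' @param threshold activity threshold (nM).
#' @param epsilon steadiness tolerance (um); default 1 um, two grid cells at
#'   the default resolution.
#' @return Time (s), with attribute `threshold_crossed`.
#' @export
time_to_steady_edge <- function(traj, threshold, epsilon = 1) {
  stopifnot(inherits(traj, "wnt_trajectory"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("epsilon must be a single positive number")
  g <- traj$grid
  edges <- vapply(seq_along(traj$times), function(i)
    edge_position(omega_profile(traj, i), threshold, g), numeric(1))
  final <- edges[length(edges)]
  if (max(omega_profile(traj)) < threshold) {
    out <- traj$times[length(traj$times)]
    attr(out, "threshold_crossed") <- FALSE
    return(out)
  }
  ok <- abs(edges - final) <= epsilon
  # earliest index from which ok holds for all later samples
  stable_from <- which(rev(cumprod(rev(ok))) == 1)[1]
  out <- traj$times[stable_from]
  attr(out, "threshold_crossed") <- TRUE
  out
}

#' Edge trace over time for a set of thresholds
#'
#' @param traj a `wnt_trajectory`.
#' @param thresholds vector of activity thresholds (nM).
#' @return Object of class `wnt_edge_trace`: list with `thresholds`, `times`
#'   and an `edge_positions` matrix indexed (threshold, time).
#' @export
edge_trace <- function(traj, thresholds) {
  stopifnot(inherits(traj, "wnt_trajectory"), length(thresholds) >= 1)
  g <- traj$grid
  M <- vapply(seq_along(traj$times), function(i) {
    om <- omega_profile(traj, i)
    vapply(thresholds, function(th) edge_position(om, th, g), numeric(1))
  }, numeric(length(thresholds)))
  M <- matrix(M, nrow = length(thresholds))
  et <- list(thresholds = thresholds, times = traj$times, edge_positions = M)
  class(et) <- "wnt_edge_trace"
  et
}
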