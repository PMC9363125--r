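#' Spatial production and initial-condition profiles
#'
#' The ligand and antagonist sources and the initial receptor / heparan
#' sulfate distributions of the cardiogenic-mesoderm field. Positions are in
#' micrometres from the embryo surface; `x` may be a vector. All profiles
#' reject positions outside `[0, x_max]`.
#'
#' @name spatial_profiles
NULL

check_domain <- function(x, params) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("position x must be finite numeric")
  if (any(x < 0 | x > params$x_max))
    stop("position x out of domain [0, ", params$x_max, "]")
  invisible(x)
}

#' @describeIn spatial_profiles Wnt6 production indicator f(x): 1 in the
#'   epidermal source region `x <= wnt_source_right_edge` (default 0-10 um),
#'   0 beyond it.
#' @param x position(s), um.
#' @param params a [wnt_params()] object.
#' @export
wnt_production_profile <- function(x, params = wnt_params()) {
  check_domain(x, params)
  as.numeric(x <= params$wnt_source_right_edge)
}

#' @describeIn spatial_profiles sFRP1 production indicator g(x): 0 before the
#'   myocardial source region, 1 for `x >= sfrp1_source_left_edge`
#'   (default 25-100 um).
#' @export
sfrp1_production_profile <- function(x, params = wnt_params()) {
  check_domain(x, params)
  as.numeric(x >= params$sfrp1_source_left_edge)
}

# shared sinusoidal bump on bump_left < x < bump_right, peak value 2 at centre
receptor_bump <- function(x, params) {
  hw <- (params$bump_right - params$bump_left) / 2
  inside <- x > params$bump_left & x < params$bump_right
  ifelse(inside,
         sin(pi * (x - params$bump_left) / hw - pi / 2) + 1,
         0)
}

#' @describeIn spatial_profiles initial receptor concentration R0(x):
#'   a sinusoidal bump `m * r0 * (sin(pi (x - 10)/15 - pi/2) + 1)` supported on
#'   10 um < x < 40 um (defaults), peaking at `2 * m * r0` at x = 25 um, where
#'   `m` is the scenario's initial-receptor multiplier.
#' @param scenario a [wnt_scenario()] supplying multipliers / switches.
#' @export
initial_receptor_profile <- function(x, params = wnt_params(),
                                     scenario = wnt_scenario()) {
  check_domain(x, params)
  scenario$initial_receptor_multiplier * params$r0 * receptor_bump(x, params)
}

#' @describeIn spatial_profiles initial N-acetyl heparan sulfate H0(x): the
#'   same bump scaled by `h0_amp`, or identically 0 when the scenario disables
#'   HS. HS is immobile and neither produced nor degraded, so this profile is
#'   also the conserved per-cell HS moiety.
#' @export
initial_hs_profile <- function(x, params = wnt_params(),
                               scenario = wnt_scenario()) {
  check_domain(x, params)
  if (!scenario$hs_enabled) return(numeric(length(x)))
  params$h0_amp * receptor_bump(x, params)
}

#' Hill repression of sFRP1 production by Wnt signalling
#'
#' The production factor `1 / ((omega / Kd)^n + 1)`, strictly decreasing in
#' the cumulative signalling activity omega and bounded in (0, 1]. At
#' `omega = Kd` the factor is exactly 1/2 for any Hill coefficient.
#'
#' @param omega cumulative signalling activity (nM), scalar or vector, >= 0.
#' @param params a [wnt_params()] supplying `Kd` and `hill_n`.
#' @return Production factor in (0, 1].
#' @examples
#' hill_repression(c(0, 1e-2, 1), wnt_params())
#' @export
hill_repression <- function(omega, params = wnt_params()) {
  if (!is.numeric(omega) || any(!is.finite(omega)))
    stop("omega must be finite numeric")
  if (any(omega < 0)) stop("omega must be >= 0")
  1 / ((omega / params$Kd)^params$hill_n + 1)
}
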