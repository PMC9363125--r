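#' Nondimensional scaling of the model
#'
#' Consistency layer exposing the natural scales of the reaction-diffusion
#' system: the time scale `t* = t_max - t_min` (with `t_min = 0`, the only
#' consistent simulation start), the concentration scale `c* = p1 * t*` (the
#' concentration the Wnt source would build up in its region without any
#' removal) and the diffusion length `x* = sqrt(4 D t*)`. With these,
#' ternary association rates scale as `k * c*^2 * t*`, binary ones as
#' `k * c* * t*`, first-order rates as `k * t*`, production densities as
#' `p * t* / c*` and the diffusion coefficient as `D * t* / x*^2` (exactly
#' 1/4 under the square-root length scale). The dimensional equations are
#' the normative implementation; this layer exists for checking magnitudes
#' and for reporting.
#'
#' @param params a [wnt_params()].
#' @return Object of class `wnt_scaling`: list with `t_star` (s), `x_star`
#'   (um), `c_star` (nM) and `scaled`, the named list of dimensionless
#'   parameters (`k1` ... `k7`, `k1_off` ... `k3_off`, `k4`, `p1`, `p2`,
#'   `Kd`, `diff_coef`, `r0`, `h0_amp`, `x_max`; `p3`, `p4` and `hill_n` are
#'   already dimensionless and pass through).
#' @examples
#' nondimensionalize(wnt_params())$c_star # 10 nM
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "wnt_params"))
  if (params$t_max <= 0) stop("t_max must be positive to nondimensionalize")
  t_star <- params$t_max - 0
  c_star <- params$p1 * t_star
  x_star <- sqrt(4 * params$diff_coef * t_star)
  if (c_star <= 0)
    stop("concentration scale p1 * t_max must be positive")
  p <- unclass(params)
  scaled <- list(
    k1 = p$k1 * c_star^2 * t_star,
    k5 = p$k5 * c_star^2 * t_star,
    k6 = p$k6 * c_star^2 * t_star,
    k7 = p$k7 * c_star^2 * t_star,
    k2 = p$k2 * c_star * t_star,
    k3 = p$k3 * c_star * t_star,
    k1_off = p$k1_off * t_star,
    k2_off = p$k2_off * t_star,
    k3_off = p$k3_off * t_star,
    k4 = p$k4 * t_star,
    p1 = p$p1 * t_star / c_star,
    p2 = p$p2 * t_star / c_star,
    p3 = p$p3, p4 = p$p4, hill_n = p$hill_n,
    Kd = p$Kd / c_star,
    diff_coef = p$diff_coef * t_star / x_star^2,
    r0 = p$r0 / c_star,
    h0_amp = p$h0_amp / c_star,
    x_max = p$x_max / x_star)
  structure(list(t_star = t_star, x_star = x_star, c_star = c_star,
                 scaled = scaled),
            class = "wnt_scaling")
}

#' Recover dimensional parameters from a scaling
#'
#' Exact inverse of [nondimensionalize()]; round-trips to relative error
#' below 1e-12.
#'
#' @param scaling a `wnt_scaling`.
#' @param template a [wnt_params()] supplying the fields the scaling does not
#'   carry (region boundaries, t_max).
#' @return A `wnt_params` object.
#' @export
redimensionalize <- function(scaling, template = wnt_params()) {
  stopifnot(inherits(scaling, "wnt_scaling"))
  s <- scaling$scaled
  t_star <- scaling$t_star; c_star <- scaling$c_star; x_star <- scaling$x_star
  wnt_params(
    k1 = s$k1 / (c_star^2 * t_star),
    k5 = s$k5 / (c_star^2 * t_star),
    k6 = s$k6 / (c_star^2 * t_star),
    k7 = s$k7 / (c_star^2 * t_star),
    k2 = s$k2 / (c_star * t_star),
    k3 = s$k3 / (c_star * t_star),
    k1_off = s$k1_off / t_star,
    k2_off = s$k2_off / t_star,
    k3_off = s$k3_off / t_star,
    k4 = s$k4 / t_star,
    p1 = s$p1 * c_star / t_star,
    p2 = s$p2 * c_star / t_star,
    p3 = s$p3, p4 = s$p4, hill_n = s$hill_n,
    Kd = s$Kd * c_star,
    diff_coef = s$diff_coef * x_star^2 / t_star,
    r0 = s$r0 * c_star,
    h0_amp = s$h0_amp * c_star,
    x_max = s$x_max * x_star,
    t_max = t_star,
    wnt_source_right_edge = template$wnt_source_right_edge,
    sfrp1_source_left_edge = template$sfrp1_source_left_edge,
    bump_left = template$bump_left, bump_right = template$bump_right)
}
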