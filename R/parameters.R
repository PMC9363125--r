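#' Model parameters for the Wnt6 gradient model
#'
#' Constructs the full parameter set of the one-dimensional Wnt6 / Fzd7 /
#' sFRP1 / heparan-sulfate reaction-diffusion model. Defaults are the model's
#' reference parameterisation for *Xenopus* cardiogenic mesoderm; every value
#' can be overridden by name.
#'
#' Units: rate constants in nM^-2 s^-1 (ternary association), nM^-1 s^-1
#' (binary association) or s^-1 (dissociation / internalization); production
#' densities in nM s^-1; lengths in micrometres; times in seconds.
#'
#' @param k1 association rate of one Wnt6 with two Fzd7 (nM^-2 s^-1).
#' @param k1_off shared dissociation rate of all receptor-containing
#'   complexes (s^-1).
#' @param k2 association rate of Wnt6 with sFRP1, free or HS-bound
#'   (nM^-1 s^-1).
#' @param k2_off dissociation rate of the Wnt6-sFRP1 complex (s^-1).
#' @param k3 association rate of sFRP1 (free or Wnt-bound) with N-acetyl
#'   heparan sulfate (nM^-1 s^-1).
#' @param k3_off dissociation rate of the sFRP1-HS complex (s^-1).
#' @param k4 internalization (endocytosis) rate of the Wnt-receptor complex
#'   WR2 (s^-1); its integral defines signalling activity omega.
#' @param k5 association rate of Wnt6 with two dnFzd7 (nM^-2 s^-1).
#' @param k6 association rate of Wnt6 with one Fzd7 and one dnFzd7
#'   (nM^-2 s^-1).
#' @param k7 Wnt-catalysed dimerization coefficient for Fzd7+dnFzd7 and
#'   dnFzd7+dnFzd7 (rate k7\[W\]\[R\]\[Dn\] resp. k7\[W\]\[Dn\]^2; nM^-2 s^-1).
#' @param p1 Wnt6 production rate density in the source region (nM s^-1).
#' @param p2 sFRP1 production rate density in the source region (nM s^-1).
#' @param p3 dimensionless receptor feedback-production coefficient: new
#'   receptor is produced at rate p3 * k4 * \[WR2\].
#' @param p4 dimensionless dnFzd7 production coefficient (same coupling to
#'   the internalization flux as p3); 0 means no dnFzd7.
#' @param Kd Hill dissociation constant of the repression of sFRP1
#'   production by Wnt signalling activity (nM).
#' @param hill_n Hill coefficient of that repression (dimensionless, >= 1).
#' @param diff_coef diffusion coefficient shared by the three diffusible
#'   species W, S and WS (um^2 s^-1).
#' @param r0 amplitude of the initial receptor profile (nM); the sinusoidal
#'   bump peaks at 2 * r0.
#' @param h0_amp amplitude of the immobile N-acetyl HS profile (nM).
#' @param x_max width of the developmental field (um).
#' @param t_max simulated duration (s), about one day of heart development.
#' @param wnt_source_right_edge right edge of the Wnt6 production region (um).
#' @param sfrp1_source_left_edge left edge of the sFRP1 production region (um).
#' @param bump_left,bump_right support of the sinusoidal initial receptor /
#'   HS bump (um).
#'
#' @return An object of class `wnt_params`: a named list of validated values.
#' @examples
#' p <- wnt_params()
#' p$k1
#' wnt_params(p3 = 50)$p3 # strong feedback hard-coded into the parameter set
#' @export
wnt_params <- function(k1 = 2.66e-6, k1_off = 9.6e-5,
                       k2 = 4.33e-5, k2_off = 4.86e-4,
                       k3 = 1.86e-4, k3_off = 3.66e-3,
                       k4 = 2.52e-4,
                       k5 = k1, k6 = k1, k7 = 0,
                       p1 = 1e-4, p2 = 1e-3, p3 = 10, p4 = 0,
                       Kd = 1e-2, hill_n = 2,
                       diff_coef = 20,
                       r0 = 75, h0_amp = 1e8,
                       x_max = 100, t_max = 1e5,
                       wnt_source_right_edge = 10,
                       sfrp1_source_left_edge = 25,
                       bump_left = 10, bump_right = 40) {
  p <- list(k1 = k1, k1_off = k1_off, k2 = k2, k2_off = k2_off,
            k3 = k3, k3_off = k3_off, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
            p1 = p1, p2 = p2, p3 = p3, p4 = p4,
            Kd = Kd, hill_n = hill_n, diff_coef = diff_coef,
            r0 = r0, h0_amp = h0_amp, x_max = x_max, t_max = t_max,
            wnt_source_right_edge = wnt_source_right_edge,
            sfrp1_source_left_edge = sfrp1_source_left_edge,
            bump_left = bump_left, bump_right = bump_right)
  class(p) <- "wnt_params"
  validate_wnt_params(p)
  p
}

#' @export
print.wnt_params <- function(x, ...) {
  cat("<wnt_params> Wnt6 gradient model parameters\n")
  nm <- names(unclass(x))
  v <- vapply(unclass(x), function(e) format(e, digits = 6), character(1))
  cat(paste0("  ", format(nm, width = 24), v, collapse = "\n"), "\n")
  invisible(x)
}

validate_wnt_params <- function(p) {
  num <- unlist(unclass(p))
  bad <- names(num)[!is.finite(num)]
  if (length(bad))
    stop("non-finite parameter value: ", paste(bad, collapse = ", "))
  neg <- names(num)[num < 0]
  if (length(neg))
    stop("negative parameter value not allowed: ", paste(neg, collapse = ", "))
  if (p$hill_n < 1) stop("hill_n must be >= 1")
  if (p$x_max <= 0) stop("x_max must be > 0")
  if (p$t_max <= 0) stop("t_max must be > 0")
  if (!(p$wnt_source_right_edge < p$sfrp1_source_left_edge &&
        p$sfrp1_source_left_edge < p$x_max))
    stop("region boundaries must satisfy ",
         "wnt_source_right_edge < sfrp1_source_left_edge < x_max")
  if (!(p$bump_left < p$bump_right && p$bump_right <= p$x_max))
    stop("bump support must satisfy bump_left < bump_right <= x_max")
  invisible(p)
}

#' Scenario switches for in-silico experiments
#'
#' A scenario is the experiment switchboard layered on top of a fixed
#' parameter set: dimensionless multipliers on the feedback strength, the
#' initial receptor amount and the ligand production rate, on/off switches for
#' the sFRP1 antagonist and N-acetyl heparan sulfate, and the dominant-negative
#' Fzd7 condition. Switches are realised purely as parameter overrides (see
#' [effective_params()]); the model equations are never restructured.
#'
#' @param feedback_multiplier scale on the receptor feedback coefficient p3
#'   (0 = no feedback, 1 = normal, 5 = strong).
#' @param initial_receptor_multiplier scale on the initial receptor
#'   amplitude r0.
#' @param ligand_multiplier scale on the Wnt production rate p1.
#' @param sfrp1_enabled if `FALSE`, sFRP1 production p2 is treated as 0.
#' @param hs_enabled if `FALSE`, the HS amplitude h0_amp is treated as 0.
#' @param dnfzd7_condition one of `"none"`, `"both_functions"`,
#'   `"inactivate_only"`, `"trap_only"`; see [dnfzd7_condition_params()].
#' @return An object of class `wnt_scenario`.
#' @examples
#' wnt_scenario(feedback_multiplier = 5) # "strong feedback"
#' @export
wnt_scenario <- function(feedback_multiplier = 1,
                         initial_receptor_multiplier = 1,
                         ligand_multiplier = 1,
                         sfrp1_enabled = TRUE,
                         hs_enabled = TRUE,
                         dnfzd7_condition = c("none", "both_functions",
                                              "inactivate_only", "trap_only")) {
  dnfzd7_condition <- match.arg(dnfzd7_condition)
  m <- c(feedback_multiplier, initial_receptor_multiplier, ligand_multiplier)
  if (any(!is.finite(m)) || any(m < 0))
    stop("scenario multipliers must be finite and >= 0")
  stopifnot(is.logical(sfrp1_enabled), length(sfrp1_enabled) == 1,
            is.logical(hs_enabled), length(hs_enabled) == 1)
  s <- list(feedback_multiplier = feedback_multiplier,
            initial_receptor_multiplier = initial_receptor_multiplier,
            ligand_multiplier = ligand_multiplier,
            sfrp1_enabled = sfrp1_enabled,
            hs_enabled = hs_enabled,
            dnfzd7_condition = dnfzd7_condition)
  class(s) <- "wnt_scenario"
  s
}

#' @export
print.wnt_scenario <- function(x, ...) {
  cat("<wnt_scenario> feedback x", x$feedback_multiplier,
      "| initial receptor x", x$initial_receptor_multiplier,
      "| ligand x", x$ligand_multiplier,
      "| sFRP1", if (x$sfrp1_enabled) "on" else "off",
      "| HS", if (x$hs_enabled) "on" else "off",
      "| dnFzd7", x$dnfzd7_condition, "\n")
  invisible(x)
}

#' Effective dnFzd7 parameters for a named condition
#'
#' The dominant-negative receptor has two separable functions: trapping Wnt
#' (in WD2 / WRD complexes) and inactivating Fzd7 (heterodimer RD). The four
#' conditions select combinations by overriding `(p4, k5, k6, k7)`:
#'
#' * `none`: no dnFzd7 production (`p4 = 0`, `k5 = k6 = k1`, `k7 = 0`);
#' * `both_functions`: `p4 = 100 * p3`, `k5 = k6 = k1`, `k7 = 0`;
#' * `inactivate_only`: `p4 = 100 * p3`, `k5 = k6 = 0`, `k7 = k1` (the
#'   Fzd7-dnFzd7 association is made Wnt-dependent with rate `k7 [W]` so
#'   inactivation survives while trapping is deleted);
#' * `trap_only`: `p4 = 100 * p3`, `k5 = k1`, `k6 = 0`, `k7 = 0`.
#'
#' `p4` is tied to the *base* receptor feedback coefficient `p3` of `params`;
#' scenario feedback multipliers do not rescale it.
#'
#' @param condition condition label (see above).
#' @param params a [wnt_params()] object supplying `k1` and `p3`.
#' @return Named list with elements `p4`, `k5`, `k6`, `k7`.
#' @examples
#' dnfzd7_condition_params("trap_only", wnt_params())
#' @export
dnfzd7_condition_params <- function(condition, params) {
  stopifnot(inherits(params, "wnt_params"))
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% c("none", "both_functions", "inactivate_only", "trap_only"))
    stop("unknown dnFzd7 condition: ",
         paste(deparse(condition), collapse = ""),
         " (expected one of none, both_functions, inactivate_only, trap_only)")
  k1 <- params$k1
  p4 <- if (condition == "none") 0 else 100 * params$p3
  switch(condition,
    none            = list(p4 = 0,  k5 = k1, k6 = k1, k7 = 0),
    both_functions  = list(p4 = p4, k5 = k1, k6 = k1, k7 = 0),
    inactivate_only = list(p4 = p4, k5 = 0,  k6 = 0,  k7 = k1),
    trap_only       = list(p4 = p4, k5 = k1, k6 = 0,  k7 = 0))
}

#' Resolve a scenario into an effective parameter set
#'
#' Applies all scenario switches as parameter overrides: `p1 <- ligand * p1`,
#' `p3 <- feedback * p3`, `r0 <- initial_receptor * r0`, `p2 <- 0` when sFRP1
#' is disabled, `h0_amp <- 0` when HS is disabled, and the dnFzd7 condition
#' row for `(p4, k5, k6, k7)`. The returned object is an ordinary
#' `wnt_params` and is the single source of truth for the right-hand sides.
#'
#' @param params base [wnt_params()].
#' @param scenario a [wnt_scenario()].
#' @return A `wnt_params` object with overrides applied.
#' @export
effective_params <- function(params, scenario) {
  stopifnot(inherits(params, "wnt_params"), inherits(scenario, "wnt_scenario"))
  eff <- unclass(params)
  dn <- dnfzd7_condition_params(scenario$dnfzd7_condition, params)
  eff$p1 <- eff$p1 * scenario$ligand_multiplier
  eff$p3 <- eff$p3 * scenario$feedback_multiplier
  eff$r0 <- eff$r0 * scenario$initial_receptor_multiplier
  if (!scenario$sfrp1_enabled) eff$p2 <- 0
  if (!scenario$hs_enabled) eff$h0_amp <- 0
  eff[c("p4", "k5", "k6", "k7")] <- dn[c("p4", "k5", "k6", "k7")]
  class(eff) <- "wnt_params"
  validate_wnt_params(eff)
  eff
}

#' Names of the model's state components
#'
#' The 13 molecular species plus the cumulative signalling activity `omega`,
#' in the canonical order used throughout the package: W (free Wnt6), S (free
#' sFRP1), WS, H (free N-acetyl HS), SH, WSH, R (free Fzd7), WR2 (the
#' signalling complex Wnt.Fzd7_2), Dn (free dnFzd7), RD, D2, WD2, WRD, omega.
#' The dominant-negative receptor is called `Dn` (not a single letter) to
#' avoid collision with the diffusion coefficient.
#'
#' @return Character vector of length 14.
#' @export
wnt_species <- function() {
  c("W", "S", "WS", "H", "SH", "WSH", "R", "WR2",
    "Dn", "RD", "D2", "WD2", "WRD", "omega")
}

# species that carry a diffusion term (all complexes on cells or HS are fixed)
DIFFUSIBLE_SPECIES <- c("W", "S", "WS")
N_SPECIES <- 14L
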