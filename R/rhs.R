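#' Reaction terms of the Wnt6 gradient model
#'
#' Time derivatives of all 14 state components from the mass-action reaction
#' network, excluding diffusion (which [diffusion_operator()] adds for the
#' three diffusible species W, S and WS). The network comprises: ligand-
#' receptor binding W + 2R <-> WR2 with internalization WR2 -> signal at rate
#' k4; antagonist binding W + S <-> WS and W + SH <-> WSH; HS capture
#' S + H <-> SH and WS + H <-> WSH; the dominant-negative reactions
#' W + 2Dn <-> WD2, W + R + Dn <-> WRD and the Wnt-catalysed dimerizations
#' R + Dn <-> RD, Dn + Dn <-> D2 (forward rate proportional to \[W\]);
#' spatially restricted production of W and (Hill-repressed) S; and
#' signal-dependent production of R and Dn at rates p3 k4 \[WR2\] and
#' p4 k4 \[WR2\]. The cumulative signalling activity omega integrates the
#' internalization flux, d omega/dt = k4 \[WR2\].
#'
#' Stoichiometry: dimer-forming reactions consume two monomers (factor 2 on R
#' in the WR2 reaction and on Dn in the WD2 / D2 reactions) and dissociation
#' returns them both. All receptor-containing complexes share the
#' dissociation rate `k1_off`.
#'
#' @param state numeric matrix `n_cells x 14` (columns in [wnt_species()]
#'   order), or a vector of length 14 for a single cell. Concentrations in nM.
#' @param x position(s) of the cell centre(s), um; length must match the
#'   number of rows of `state`.
#' @param params an *effective* [wnt_params()] (see [effective_params()]);
#'   multiplier-type scenario switches must already be folded in.
#' @return Derivatives (nM/s) with the same shape as `state`.
#' @examples
#' p <- wnt_params()
#' s <- stats::setNames(numeric(14), wnt_species())
#' s["W"] <- 1; s["R"] <- 75
#' reaction_rhs(s, x = 20, params = p)[c("R", "WR2")]
#' @export
reaction_rhs <- function(state, x, params) {
  vec_in <- is.null(dim(state))
  M <- if (vec_in) matrix(state, nrow = 1) else as.matrix(state)
  if (ncol(M) != N_SPECIES)
    stop("state must have ", N_SPECIES, " components")
  if (length(x) != nrow(M))
    stop("length of x must match the number of state rows")
  if (any(!is.finite(M))) {
    bad <- wnt_species()[unique(which(!is.finite(M), arr.ind = TRUE)[, 2])]
    stop("non-finite concentration in species: ", paste(bad, collapse = ", "))
  }
  if (any(M < 0)) {
    bad <- wnt_species()[unique(which(M < 0, arr.ind = TRUE)[, 2])]
    stop("negative concentration in species: ", paste(bad, collapse = ", "))
  }
  d <- reaction_rhs_raw(M, x, params)
  colnames(d) <- wnt_species()
  if (vec_in) d[1, ] else d
}

# unchecked core, shared by the integrator path; state is n_cells x 14
reaction_rhs_raw <- function(M, x, p) {
  W <- M[, 1L]; S <- M[, 2L]; WS <- M[, 3L]; H <- M[, 4L]
  SH <- M[, 5L]; WSH <- M[, 6L]; R <- M[, 7L]; WR2 <- M[, 8L]
  Dn <- M[, 9L]; RD <- M[, 10L]; D2 <- M[, 11L]; WD2 <- M[, 12L]
  WRD <- M[, 13L]; omega <- M[, 14L]

  # net forward fluxes of each reversible reaction
  b1  <- p$k1 * W * R * R   - p$k1_off * WR2   # W + 2R  <-> WR2
  b2  <- p$k2 * W * S       - p$k2_off * WS    # W + S   <-> WS
  b2h <- p$k2 * W * SH      - p$k2_off * WSH   # W + SH  <-> WSH
  b3  <- p$k3 * S * H       - p$k3_off * SH    # S + H   <-> SH
  b3w <- p$k3 * WS * H      - p$k3_off * WSH   # WS + H  <-> WSH
  b5  <- p$k5 * W * Dn * Dn - p$k1_off * WD2   # W + 2Dn <-> WD2
  b6  <- p$k6 * W * R * Dn  - p$k1_off * WRD   # W + R + Dn <-> WRD
  b7r <- p$k7 * W * R * Dn  - p$k1_off * RD    # R + Dn  <-> RD  (Wnt-catalysed)
  b7d <- p$k7 * W * Dn * Dn - p$k1_off * D2    # 2Dn     <-> D2  (Wnt-catalysed)

  internal <- p$k4 * WR2
  f <- as.numeric(x <= p$wnt_source_right_edge)
  g <- as.numeric(x >= p$sfrp1_source_left_edge)
  hill <- 1 / ((omega / p$Kd)^p$hill_n + 1)

  cbind(
    W     = -b1 - b2 - b2h - b5 - b6 + p$p1 * f,
    S     = -b2 - b3 + p$p2 * hill * g,
    WS    =  b2 - b3w,
    H     = -b3 - b3w,
    SH    = -b2h + b3,
    WSH   =  b2h + b3w,
    R     = -2 * b1 - b6 - b7r + p$p3 * internal,
    WR2   =  b1 - internal,
    Dn    = -2 * b5 - b6 - b7r - 2 * b7d + p$p4 * internal,
    RD    =  b7r,
    D2    =  b7d,
    WD2   =  b5,
    WRD   =  b6,
    omega =  internal
  )
}
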