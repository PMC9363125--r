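#' Uniform cell-centered grid over the developmental field
#'
#' Finite-volume style discretization of `[0, x_max]` into `n_cells` equal
#' cells; state is carried at cell centres. At least 20 cells are required so
#' that the 10 / 25 / 40 um region boundaries of the model are resolvable.
#' Step-function source regions are evaluated at cell centres: a cell belongs
#' to a region iff its centre satisfies the region inequality.
#'
#' @param x_max domain width, um.
#' @param n_cells number of cells (>= 20).
#' @return Object of class `wnt_grid` with fields `n_cells`, `cell_width`,
#'   `cell_centers`, `x_max`.
#' @examples
#' discretize_domain(100, 200)
#' @export
discretize_domain <- function(x_max = 100, n_cells = 200) {
  if (!is.numeric(x_max) || length(x_max) != 1 || x_max <= 0)
    stop("x_max must be a positive number")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 20)
    stop("n_cells must be >= 20 (region boundaries unresolvable on coarser grids)")
  dx <- x_max / n_cells
  g <- list(n_cells = n_cells, cell_width = dx,
            cell_centers = (seq_len(n_cells) - 0.5) * dx,
            x_max = x_max)
  class(g) <- "wnt_grid"
  g
}

#' @export
print.wnt_grid <- function(x, ...) {
  cat("<wnt_grid>", x$n_cells, "cells of", format(x$cell_width),
      "um on [0,", x$x_max, "] um\n")
  invisible(x)
}

#' Zero-flux diffusion operator
#'
#' Second-order central-difference approximation of `D d2c/dx2` on a
#' [discretize_domain()] grid with reflecting (zero-flux, Neumann) ghost
#' cells at both ends, encoding the bilateral symmetry of the heart field.
#' The operator is conservative: its output sums to zero over the domain to
#' round-off. In the model it is applied only to the diffusible species W, S
#' and WS; all other species are immobile.
#'
#' @param field concentration profile at cell centres (length `n_cells`), nM.
#' @param grid a `wnt_grid`.
#' @param diff_coef diffusion coefficient, um^2/s.
#' @return Rate profile, nM/s.
#' @export
diffusion_operator <- function(field, grid, diff_coef) {
  stopifnot(inherits(grid, "wnt_grid"))
  n <- grid$n_cells
  if (length(field) != n)
    stop("field length ", length(field), " does not match grid (", n, " cells)")
  left <- c(field[1L], field[-n])      # ghost: mirror of first/last cell
  right <- c(field[-1L], field[n])
  diff_coef * (left - 2 * field + right) / grid$cell_width^2
}
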