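#' Peak bacterial density and its location
#'
#' The maximum of the density field over cells (the accumulation
#' observable B_S around a transient source) and the cell-center
#' coordinate where it is attained; ties are broken towards the smaller
#' coordinate.
#'
#' @param state A [field_state()].
#' @param grid The [make_grid()] object the state lives on.
#' @return List with `value` (B_S) and `location`.
#' @export
peak_density <- function(state, grid) {
  stopifnot(length(state$B) == grid$n_cells)
  i <- which.max(state$B)   # first maximum = smallest coordinate
  list(value = state$B[i], location = grid$cell_centers[i])
}

#' Integrated population size
#'
#' `sum(B * w)` with cell weights `w = dx` (Cartesian) or `2*pi*R*dx`
#' (axisymmetric, cell-center radius) -- exact for piecewise-constant
#' fields, i.e. the bacterial density integrated over the simulation
#' domain.
#'
#' @inheritParams peak_density
#' @return A single number.
#' @export
total_population <- function(state, grid) {
  stopifnot(length(state$B) == grid$n_cells)
  sum(state$B * grid$cell_weights)
}

#' Wave-front position and width
#'
#' Locates the outermost crossing of the level `threshold_frac * max(B)`
#' (linearly interpolated between cell centers) -- the front of a
#' travelling band -- and the innermost crossing of the same level; their
#' distance is reported as the wave width. If the profile never crosses
#' the level (e.g. a uniform field), the front is reported at the outer
#' boundary with `crossed = FALSE`.
#'
#' @inheritParams peak_density
#' @param threshold_frac Level as a fraction of the maximum, in (0, 1).
#' @return List with `front`, `width` and logical `crossed`.
#' @export
front_position <- function(state, grid, threshold_frac = 0.1) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must be in (0, 1)", call. = FALSE)
  B <- state$B
  x <- grid$cell_centers
  level <- threshold_frac * max(B)
  d <- B - level
  s <- d[-length(d)] * d[-1]
  idx <- which(s < 0 | (d[-length(d)] == 0 & d[-1] != 0))
  if (!length(idx)) {
    return(list(front = grid$x_max, width = grid$x_max - grid$x_min,
                crossed = FALSE))
  }
  cross <- x[idx] + (level - B[idx]) / (B[idx + 1] - B[idx]) * grid$dx
  list(front = max(cross), width = max(cross) - min(cross),
       crossed = TRUE)
}
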