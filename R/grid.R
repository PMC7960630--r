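#' Uniform finite-volume grid
#'
#' Cell-centered uniform mesh for the 1D Cartesian or 2D axisymmetric
#' (radial) geometry. Faces sit at `x_min + i*dx`, cell centers at the
#' midpoints. In the axisymmetric geometry the domain must start at
#' `R = 0`, where the first face carries zero area so the coordinate
#' singularity never enters the discretization.
#'
#' @param geometry `"cartesian1d"` or `"axisymmetric"`.
#' @param x_min Left boundary (must be 0 for axisymmetric grids).
#' @param x_max Right boundary (> `x_min`).
#' @param n_cells Number of cells (integer >= 2).
#' @return An object of class `"ck_grid"`: list with `geometry`, `x_min`,
#'   `x_max`, `n_cells`, `dx`, `cell_centers`, `face_positions`,
#'   `face_areas` (1 or R at faces) and `cell_weights` (integration
#'   weights: `dx`, or `2*pi*R*dx`).
#' @examples
#' g <- make_grid("axisymmetric", x_max = 10, n_cells = 100)
#' sum(g$cell_weights)  # pi * 10^2
#' @export
make_grid <- function(geometry = c("cartesian1d", "axisymmetric"),
                      x_min = 0, x_max, n_cells) {
  geometry <- match.arg(geometry)
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("'n_cells' must be >= 2", call. = FALSE)
  if (x_max <= x_min) stop("'x_max' must exceed 'x_min'", call. = FALSE)
  if (geometry == "axisymmetric" && x_min != 0)
    stop("axisymmetric grids must start at R = 0", call. = FALSE)
  dx <- (x_max - x_min) / n_cells
  faces <- x_min + dx * (0:n_cells)
  centers <- (faces[-1] + faces[-(n_cells + 1)]) / 2
  g <- list(
    geometry = geometry, x_min = x_min, x_max = x_max,
    n_cells = n_cells, dx = dx,
    cell_centers = centers, face_positions = faces,
    face_areas = if (geometry == "axisymmetric") faces
                 else rep(1, n_cells + 1),
    cell_weights = if (geometry == "axisymmetric") 2 * pi * centers * dx
                   else rep(dx, n_cells)
  )
  class(g) <- "ck_grid"
  g
}

#' @export
print.ck_grid <- function(x, ...) {
  cat(sprintf("<ck_grid> %s, [%g, %g], %d cells (dx = %g)\n",
              x$geometry, x$x_min, x$x_max, x$n_cells, x$dx))
  invisible(x)
}

#' Bacterial density and attractant fields at one time
#'
#' @param T Dimensionless time.
#' @param B Bacterial density per cell (>= 0).
#' @param C Attractant concentration per cell (>= 0).
#' @return An object of class `"field_state"`.
#' @export
field_state <- function(T, B, C) {
  if (length(B) != length(C))
    stop("'B' and 'C' must have the same length", call. = FALSE)
  if (any(!is.finite(B)) || any(!is.finite(C)))
    stop("fields must be finite", call. = FALSE)
  if (any(B < 0) || any(C < 0))
    stop("fields must be non-negative", call. = FALSE)
  structure(list(T = T, B = B, C = C), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "<field_state> T = %g, %d cells; max B = %.4g, max C = %.4g\n",
    x$T, length(x$B), max(x$B), max(x$C)))
  invisible(x)
}
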