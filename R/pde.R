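div_weights <- function(grid) {
  # divergence weights: cell "volume" per unit cross-section (no 2*pi)
  if (grid$geometry == "axisymmetric") grid$cell_centers * grid$dx
  else rep(grid$dx, grid$n_cells)
}

#' Conservative finite-volume Laplacian
#'
#' Flux-form discrete Laplacian with zero-flux boundaries: face fluxes
#' `grad = diff(field)/dx`, weighted by the face area (1 in Cartesian, R in
#' axisymmetric geometry, so the axisymmetric operator is
#' `(1/R) d/dR (R d/dR)` and the R = 0 face carries exactly zero flux).
#'
#' @param field Numeric vector on the cells of `grid`.
#' @param grid A [make_grid()] object.
#' @return Numeric vector: the discrete Laplacian per cell.
#' @export
fv_laplacian <- function(field, grid) {
  M <- grid$n_cells
  stopifnot(length(field) == M)
  grad <- diff(field) / grid$dx
  aF <- c(0, grid$face_areas[2:M] * grad, 0)
  (aF[2:(M + 1)] - aF[1:M]) / div_weights(grid)
}

#' Finite-volume divergence of the bacterial flux
#'
#' Discrete `-div(J)` for the bacterial flux `J = -V^2 grad(B) +
#' (V_k + V_chi) B`: the diffusive part uses the face-averaged squared
#' speed, the drift part is evaluated at faces (arithmetic-mean C) and
#' applied to the upwind-side face value of B reconstructed with
#' minmod-limited slopes (second-order where smooth, monotone at fronts),
#' and boundary faces carry exactly zero total flux, so the operator
#' telescopes and conserves `sum(B * weights)` to round-off.
#'
#' @param B,C Density and concentration fields on the cells of `grid`.
#' @param dCdT Temporal derivative of C (scalar 0 or a per-cell vector),
#'   entering the chemotactic drift's temporal correction.
#' @param grid A [make_grid()] object.
#' @param p A [model_params()] object.
#' @return Numeric vector: `-div(J)` per cell.
#' @export
divergence_of_flux <- function(B, C, dCdT = 0, grid, p) {
  M <- grid$n_cells
  stopifnot(length(B) == M, length(C) == M)
  dx <- grid$dx
  V <- hill_speed(C, p)
  D_face <- (V[-M]^2 + V[-1]^2) / 2
  gradB <- diff(B) / dx
  gradC <- diff(C) / dx
  Cf <- (C[-M] + C[-1]) / 2
  dCdTf <- if (length(dCdT) == 1L) rep(dCdT, M - 1)
           else (dCdT[-M] + dCdT[-1]) / 2
  drift <- chemokinetic_drift(Cf, gradC, p) +
    chemotactic_drift(Cf, gradC, dCdTf, p)
  dB_ <- diff(B)
  slope <- c(0, ifelse(dB_[-(M - 1)] * dB_[-1] <= 0, 0,
                       ifelse(abs(dB_[-(M - 1)]) < abs(dB_[-1]),
                              dB_[-(M - 1)], dB_[-1])), 0)
  B_up <- ifelse(drift > 0, B[-M] + slope[-M] / 2, B[-1] - slope[-1] / 2)
  J <- -D_face * gradB + drift * B_up
  aJ <- c(0, grid$face_areas[2:M] * J, 0)
  (aJ[1:M] - aJ[2:(M + 1)]) / div_weights(grid)
}

#' Right-hand side of the coupled model equations
#'
#' Evaluates `dB/dT = -div(J) + growth` and `dC/dT = N lap(C) - H B g(C)`
#' (dynamic attractant) or `dC/dT = 0` (frozen attractant). The temporal
#' derivative fed into the chemotactic drift's zeta-correction is the
#' just-computed `dC/dT`, not a finite difference of stored time levels,
#' so it is exactly zero for a frozen field.
#'
#' This is the reference implementation used for verification; the time
#' integrator [advance()] runs an equivalent compiled version.
#'
#' @param state A [field_state()].
#' @param grid A [make_grid()] object.
#' @param p A [model_params()] object.
#' @param c_mode `"dynamic"` or `"frozen"`.
#' @return List with numeric vectors `dB` and `dC`.
#' @export
pde_rhs <- function(state, grid, p, c_mode = c("dynamic", "frozen")) {
  c_mode <- match.arg(c_mode)
  B <- state$B; C <- state$C
  r <- reaction_terms(B, C, p)
  dC <- if (c_mode == "dynamic")
    p$N * fv_laplacian(C, grid) + r$consumption
  else rep(0, length(C))
  dB <- divergence_of_flux(B, C, dC, grid, p) + r$growth
  list(dB = dB, dC = dC)
}

#' Integrate the model forward in time
#'
#' Advances a [field_state()] with an adaptive explicit Heun (two-stage
#' Runge-Kutta) scheme in a compiled core. The step size obeys a
#' CFL-style bound
#' `dt <= safety * min(dx^2/(2 max V^2), dx^2/(2 N), dx / max|V_k + V_chi|)`
#' recomputed every step, which together with limited upwinding keeps the
#' fields non-negative; any residual negative round-off is clipped to
#' zero and the clipped mass accounted for. Snapshots are emitted at the
#' requested output times (the step is shortened to land on them exactly).
#'
#' @param state Initial [field_state()] (its `T` is the start time).
#' @param grid A [make_grid()] object.
#' @param p A [model_params()] object.
#' @param t_out Strictly increasing output times, all > `state$T`.
#' @param c_mode `"dynamic"` (attractant diffuses and is consumed),
#'   `"frozen"` (attractant static), or `"analytic_pulse"` (attractant
#'   prescribed as the spreading 2D Gaussian pulse of [gaussian_pulse()];
#'   requires `pulse`).
#' @param pulse For `c_mode = "analytic_pulse"`: list with `S` (pulse
#'   content) and `N` (attractant diffusivity used in the kernel).
#' @param safety CFL safety factor (default 0.4).
#' @param dt_min Abort threshold for step-size collapse.
#' @param max_clip_frac Maximum tolerated cumulative clipped mass,
#'   relative to the total content of the respective field; exceeding it
#'   is a validation failure and raises an error.
#' @return An object of class `"ck_trajectory"`: list with `times`,
#'   matrices `B` and `C` (cells x output times), the `grid`, `params`,
#'   `c_mode`, step diagnostics (`n_steps`, `dt_last`) and the clipped
#'   masses.
#' @examples
#' g <- make_grid("cartesian1d", 0, 10, 100)
#' p <- model_params()  # pure diffusion at unit speed
#' B0 <- exp(-(g$cell_centers - 5)^2)
#' s <- field_state(0, B0, rep(0, 100))
#' tr <- advance(s, g, p, t_out = c(0.5, 1), c_mode = "frozen")
#' total_population(get_state(tr, 2), g)
#' @export
advance <- function(state, grid, p, t_out,
                    c_mode = c("dynamic", "frozen", "analytic_pulse"),
                    pulse = NULL, safety = 0.4, dt_min = 1e-12,
                    max_clip_frac = 1e-6) {
  c_mode <- match.arg(c_mode)
  stopifnot(inherits(state, "field_state"), inherits(grid, "ck_grid"),
            inherits(p, "model_params"))
  t_out <- as.numeric(t_out)
  if (any(diff(t_out) <= 0) || t_out[1] <= state$T)
    stop("'t_out' must be strictly increasing and all > state$T",
         call. = FALSE)
  if (c_mode == "analytic_pulse") {
    if (is.null(pulse) || is.null(pulse$S) || is.null(pulse$N))
      stop("'pulse' with S and N required for analytic_pulse mode",
           call. = FALSE)
    if (grid$geometry != "axisymmetric")
      stop("analytic_pulse mode requires an axisymmetric grid",
           call. = FALSE)
    if (state$T <= 0)
      stop("analytic_pulse mode requires a start time > 0", call. = FALSE)
  }
  mode_int <- match(c_mode, c("frozen", "dynamic", "analytic_pulse")) - 1L
  res <- cpp_advance(
    state$B, state$C, state$T, t_out, grid$dx,
    if (grid$geometry == "axisymmetric") 1L else 0L,
    grid$cell_centers, grid$face_positions, unclass(p), mode_int,
    if (is.null(pulse)) 0 else pulse$S,
    if (is.null(pulse)) 0 else pulse$N,
    safety, dt_min)
  traj <- structure(
    list(times = t_out, B = res$B, C = res$C, grid = grid, params = p,
         c_mode = c_mode, pulse = pulse, safety = safety,
         n_steps = res$n_steps, dt_last = res$dt_last,
         clipped_B = res$clipped_B, clipped_C = res$clipped_C),
    class = "ck_trajectory")
  dw <- div_weights(grid)   # same weights as the compiled clip accounting
  wB <- sum(state$B * dw)
  wC <- max(sum(state$C * dw),
            apply(res$C, 2, function(x) sum(x * dw)))
  if (wB > 0 && res$clipped_B > max_clip_frac * wB)
    stop(sprintf(
      "validation failure: clipped bacterial mass %.3g exceeds %.1g of total %.3g",
      res$clipped_B, max_clip_frac, wB), call. = FALSE)
  if (wC > 0 && res$clipped_C > max_clip_frac * wC)
    stop(sprintf(
      "validation failure: clipped attractant mass %.3g exceeds %.1g of total %.3g",
      res$clipped_C, max_clip_frac, wC), call. = FALSE)
  traj
}

#' @export
print.ck_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ck_trajectory> %d snapshots on [%g, %g], %s grid (%d cells), %d steps\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    x$grid$geometry, x$grid$n_cells, x$n_steps))
  invisible(x)
}

#' Extract one snapshot of a trajectory as a field state
#'
#' @param traj A `"ck_trajectory"` from [advance()].
#' @param i Snapshot index (1 .. number of output times).
#' @return A [field_state()].
#' @export
get_state <- function(traj, i) {
  stopifnot(inherits(traj, "ck_trajectory"),
            i >= 1L, i <= length(traj$times))
  field_state(traj$times[i], traj$B[, i], traj$C[, i])
}
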