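`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spreading 2D Gaussian attractant pulse
#'
#' The axisymmetric diffusion kernel
#' \deqn{C(R, T) = \frac{S}{4 \pi N T} \exp\left(-\frac{R^2}{4 N T}\right),}
#' describing a point release of total attractant content S spreading with
#' diffusivity N: the radial integral \eqn{\int_0^\infty C \, 2\pi R \, dR}
#' equals S at every time.
#'
#' @param R Radial coordinate(s), >= 0.
#' @param T Time since release, > 0.
#' @param S Total attractant content of the pulse (dimensionless).
#' @param N Attractant diffusivity (dimensionless), > 0.
#' @return Concentration value(s), same length as `R`.
#' @examples
#' gaussian_pulse(0, T = 0.01, S = 0.5, N = 0.5)  # ~7.96
#' @export
gaussian_pulse <- function(R, T, S, N) {
  if (any(T <= 0)) stop("'T' must be > 0", call. = FALSE)
  if (N <= 0) stop("'N' must be > 0", call. = FALSE)
  if (any(R < 0)) stop("'R' must be >= 0", call. = FALSE)
  S / (4 * pi * N * T) * exp(-R^2 / (4 * N * T))
}

build_field <- function(desc, grid) {
  x <- grid$cell_centers
  switch(desc$kind,
    uniform = rep(desc$value, grid$n_cells),
    linear = desc$C_max * (x - grid$x_min) / (grid$x_max - grid$x_min),
    pulse = gaussian_pulse(x, desc$T0, desc$S, desc$N),
    gaussian = {
      f <- exp(-(x - desc$center)^2 / (2 * desc$sigma^2))
      if (identical(desc$normalize, "mass")) {
        f * desc$value / sum(f * grid$cell_weights)
      } else {               # "peak"
        f * desc$value
      }
    },
    stop("unknown initial-field kind: ", desc$kind, call. = FALSE)
  )
}

#' Benchmark scenario specification
#'
#' Bundles a grid, a parameter set, initial-condition descriptors, the
#' attractant mode and the output schedule for one benchmark set-up,
#' together with named comparison variants (parameter overrides run
#' alongside the base set). Normally created through one of the scenario
#' constructors ([make_linear_gradient()], [make_agar_plate()],
#' [make_transient_source()]) or read from a config file
#' ([read_scenario_config()]).
#'
#' @param name Scenario name.
#' @param grid A [make_grid()] object.
#' @param params A [model_params()] object (the base parameter set).
#' @param initial List with descriptors `B` and `C`; each has a `kind`
#'   (`"uniform"`, `"linear"`, `"gaussian"`, `"pulse"`) plus its shape
#'   parameters.
#' @param c_mode `"frozen"`, `"dynamic"` or `"analytic_pulse"`.
#' @param T_snapshots Strictly increasing output times (> `T0`).
#' @param variants Named list of parameter-override lists.
#' @param T0 Start time (0 except for the transient pulse, which starts at
#'   the first reported snapshot of the analytic kernel).
#' @param front_threshold Fraction of the density maximum used by
#'   [front_position()].
#' @return An object of class `"scenario_spec"` with the built initial
#'   fields in `$B_init` / `$C_init`.
#' @export
scenario_spec <- function(name, grid, params, initial, c_mode,
                          T_snapshots, variants = list(), T0 = 0,
                          front_threshold = 0.1) {
  stopifnot(inherits(grid, "ck_grid"), inherits(params, "model_params"))
  c_mode <- match.arg(c_mode, c("frozen", "dynamic", "analytic_pulse"))
  T_snapshots <- as.numeric(T_snapshots)
  if (any(diff(T_snapshots) <= 0) || T_snapshots[1] <= T0)
    stop("'T_snapshots' must be strictly increasing and > T0",
         call. = FALSE)
  if (length(variants) &&
      (is.null(names(variants)) || any(names(variants) == "")))
    stop("'variants' must be a named list", call. = FALSE)
  B_init <- build_field(initial$B, grid)
  C_init <- build_field(initial$C, grid)
  if (any(B_init < 0) || any(C_init < 0))
    stop("initial fields must be non-negative", call. = FALSE)
  structure(
    list(name = name, grid = grid, params = params, initial = initial,
         B_init = B_init, C_init = C_init, c_mode = c_mode,
         T_snapshots = T_snapshots, variants = variants, T0 = T0,
         front_threshold = front_threshold),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> '%s': %s grid [%g, %g] x %d, c_mode = %s\n",
    x$name, x$grid$geometry, x$grid$x_min, x$grid$x_max,
    x$grid$n_cells, x$c_mode))
  cat(sprintf("  %d snapshot times in [%g, %g]; variants: %s\n",
              length(x$T_snapshots), x$T_snapshots[1],
              x$T_snapshots[length(x$T_snapshots)],
              if (length(x$variants))
                paste(names(x$variants), collapse = ", ")
              else "(none)"))
  invisible(x)
}

apply_overrides <- function(p, overrides) {
  if (!length(overrides)) return(p)
  fields <- unclass(p)
  unknown <- setdiff(names(overrides), names(fields))
  if (length(unknown))
    stop("unknown parameter override(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(model_params, modifyList(fields, overrides))
}

#' Fixed linear attractant gradient (microfluidic-style assay)
#'
#' A 1D Cartesian domain with a static linear attractant profile rising
#' from 0 at the left boundary to `C_max` at the right, no consumption or
#' growth (`H = 0`, `N = 0`), and a localized bacterial bump near the
#' low-attractant side. The default parameters are the benchmark set
#' `K_chi = 0.53, delta0 = 50, eta = 2, omega = 0.2, n = 5` with snapshots
#' at T = 1, 9, 17. Variants: a pure-chemotaxis control (`eta = 0`) and
#' the Hill-exponent sweep n = 1, 10, 40 (the base run provides n = 5).
#'
#' @param p_overrides Named list of parameter overrides applied to the
#'   base set.
#' @param x_max Domain length (dimensionless; default 10).
#' @param n_cells Grid resolution (default 400).
#' @param C_max Attractant concentration at the right boundary (default 1,
#'   so the profile spans the full Hill response including `C = omega`).
#' @param T_snapshots Output times.
#' @return A [scenario_spec()].
#' @export
make_linear_gradient <- function(p_overrides = list(), x_max = 10,
                                 n_cells = 400, C_max = 1,
                                 T_snapshots = c(1, 9, 17)) {
  params <- apply_overrides(
    model_params(N = 0, H = 0, K_S = 1, eta = 2, omega = 0.2, n_hill = 5,
                 delta0 = 50, zeta = 0, K_chi = 0.53, growth_on = FALSE),
    p_overrides)
  grid <- make_grid("cartesian1d", 0, x_max, n_cells)
  scenario_spec(
    name = "linear_gradient", grid = grid, params = params,
    initial = list(
      B = list(kind = "gaussian", center = 1, sigma = 0.2,
               normalize = "mass", value = 0.2 * x_max),
      C = list(kind = "linear", C_max = C_max)),
    c_mode = "frozen", T_snapshots = T_snapshots,
    variants = list(
      pure_chemotaxis = list(eta = 0),
      n_1 = list(n_hill = 1),
      n_10 = list(n_hill = 10),
      n_40 = list(n_hill = 40)))
}

#' Self-generated gradient on an agar plate
#'
#' An axisymmetric domain with initially uniform attractant (C = 1) and a
#' narrow bacterial inoculum at the origin. Growth and consumption are
#' active, so the population creates its own gradient and follows it
#' outwards as a travelling wave. The attractant profile is assumed
#' stationary in the frame of the wave (`zeta = 0`). Default parameters:
#' `H = 3.5, K_S = 1, N = 0.5, K_chi = 0.53, delta0 = 105, eta = 0.5,
#' omega = 0.5, n = 5`. Variants: purely chemotactic populations at
#' constant speed 1 (base speed) and `1 + eta` (permanently elevated
#' speed).
#'
#' @inheritParams make_linear_gradient
#' @param x_max Domain radius (default 60, large enough that the
#'   travelling wave stays clear of the outer boundary over the default
#'   snapshot schedule; doubling it changes the late-time front position
#'   by well under 0.5%).
#' @param n_cells Grid resolution (default 900).
#' @param inoculum_sigma Width of the Gaussian inoculum at the origin
#'   (default 0.6; peak density 1).
#' @return A [scenario_spec()].
#' @export
make_agar_plate <- function(p_overrides = list(), x_max = 60,
                            n_cells = 900, inoculum_sigma = 0.6,
                            T_snapshots = sort(unique(c(
                              seq(0.4, 16.4, by = 0.4), 1, 8.8)))) {
  params <- apply_overrides(
    model_params(N = 0.5, H = 3.5, K_S = 1, eta = 0.5, omega = 0.5,
                 n_hill = 5, delta0 = 105, zeta = 0, K_chi = 0.53,
                 growth_on = TRUE),
    p_overrides)
  grid <- make_grid("axisymmetric", 0, x_max, n_cells)
  scenario_spec(
    name = "agar_plate", grid = grid, params = params,
    initial = list(
      B = list(kind = "gaussian", center = 0, sigma = inoculum_sigma,
               normalize = "peak", value = 1),
      C = list(kind = "uniform", value = 1)),
    c_mode = "dynamic", T_snapshots = T_snapshots,
    variants = list(
      constant_base = list(mode = "constant_speed", speed_factor = 1),
      constant_fast = list(mode = "constant_speed",
                           speed_factor = 1 + params$eta)))
}

#' Transient attractant pulse (lysed alga / exuding particle)
#'
#' An axisymmetric domain in which a localized pulse of attractant of
#' content S spreads by diffusion from the origin while being consumed
#' (`H = 3.5`); bacterial growth is off, and the population starts
#' uniformly at density 0.2. The run starts at `T0 = 0.01` from the
#' analytic kernel [gaussian_pulse()]. The temporal decay of the profile
#' biases the chemotactic drift (`zeta > 0`); chemokinesis mitigates that
#' bias. Default parameters: `K_chi = 0.53, delta0 = 50, eta = 2,
#' omega = 0.2, n = 1, S = 0.5, zeta = 8.164e-3`. Variants: the three
#' companions of the base (chemokinetic, zeta as set) run -- chemokinetic
#' with `zeta = 0`, pure chemotaxis with `zeta` as set, and pure
#' chemotaxis with `zeta = 0`.
#'
#' @inheritParams make_linear_gradient
#' @param x_max Domain radius (default 10).
#' @param n_cells Grid resolution (default 400).
#' @param S Attractant content of the pulse (default 0.5).
#' @param T0 Start time (default 0.01, the first reported snapshot of the
#'   kernel).
#' @param c_field `"evolved"`: the attractant field is integrated forward
#'   with diffusion and consumption from the kernel initial condition;
#'   `"prescribed"`: the analytic kernel is imposed at all times (no
#'   consumption feedback).
#' @return A [scenario_spec()].
#' @export
make_transient_source <- function(p_overrides = list(), x_max = 10,
                                  n_cells = 400, S = 0.5, T0 = 0.01,
                                  c_field = c("evolved", "prescribed"),
                                  T_snapshots = sort(unique(c(
                                    seq(0.02, 1, by = 0.02), 0.05)))) {
  c_field <- match.arg(c_field)
  params <- apply_overrides(
    model_params(N = 0.5, H = 3.5, K_S = 1, eta = 2, omega = 0.2,
                 n_hill = 1, delta0 = 50, zeta = 8.164e-3, K_chi = 0.53,
                 growth_on = FALSE),
    p_overrides)
  grid <- make_grid("axisymmetric", 0, x_max, n_cells)
  scenario_spec(
    name = "transient_source", grid = grid, params = params,
    initial = list(
      B = list(kind = "uniform", value = 0.2),
      C = list(kind = "pulse", S = S, N = params$N, T0 = T0)),
    c_mode = if (c_field == "evolved") "dynamic" else "analytic_pulse",
    T_snapshots = T_snapshots, T0 = T0,
    variants = list(
      ck_zeta0 = list(zeta = 0),
      pure_chemotaxis = list(eta = 0),
      pure_chemotaxis_zeta0 = list(eta = 0, zeta = 0)))
}

#' Run a scenario (base parameter set and variants)
#'
#' Integrates the model for the base parameter set and each requested
#' variant of a [scenario_spec()], and collects the observable time series
#' (peak density, integrated population, front position/width) at the
#' initial time and every snapshot time.
#'
#' @param spec A [scenario_spec()].
#' @param variants Character vector of variant names to run (`"base"` is
#'   the base set). Default: base plus all variants.
#' @param resolution Optional override of the grid resolution (initial
#'   fields are rebuilt from their descriptors).
#' @param safety CFL safety factor passed to [advance()].
#' @return An object of class `"scenario_run"`: list with the (possibly
#'   re-gridded) `grid`, named trajectories in `$runs`, and a long-format
#'   data frame `$series` with columns `variant`, `time`, `B_S`,
#'   `B_S_location`, `total_population`, `front_position`, `front_width`,
#'   `front_crossed`.
#' @export
run_scenario <- function(spec, variants = NULL, resolution = NULL,
                         safety = 0.4) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- spec$grid
  if (!is.null(resolution)) {
    grid <- make_grid(spec$grid$geometry, spec$grid$x_min,
                      spec$grid$x_max, resolution)
  }
  B0 <- build_field(spec$initial$B, grid)
  C0 <- build_field(spec$initial$C, grid)
  sets <- c(list(base = list()), spec$variants)
  if (!is.null(variants)) {
    missing <- setdiff(variants, names(sets))
    if (length(missing))
      stop("unknown variant(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    sets <- sets[variants]
  }
  pulse <- if (spec$c_mode == "analytic_pulse")
    list(S = spec$initial$C$S, N = spec$initial$C$N) else NULL

  runs <- list()
  rows <- list()
  for (nm in names(sets)) {
    p <- apply_overrides(spec$params, sets[[nm]])
    st0 <- field_state(spec$T0, B0, C0)
    traj <- advance(st0, grid, p, spec$T_snapshots, c_mode = spec$c_mode,
                    pulse = pulse, safety = safety)
    runs[[nm]] <- traj
    states <- c(list(st0), lapply(seq_along(traj$times),
                                  function(i) get_state(traj, i)))
    rows[[nm]] <- do.call(rbind, lapply(states, function(s) {
      pk <- peak_density(s, grid)
      fr <- front_position(s, grid, spec$front_threshold)
      data.frame(variant = nm, time = s$T, B_S = pk$value,
                 B_S_location = pk$location,
                 total_population = total_population(s, grid),
                 front_position = fr$front, front_width = fr$width,
                 front_crossed = fr$crossed,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(spec = spec, grid = grid, runs = runs,
                 series = do.call(rbind, c(rows, make.row.names = FALSE)),
                 safety = safety),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> '%s': %d variant(s) x %d times\n",
              x$spec$name, length(x$runs),
              length(unique(x$series$time))))
  invisible(x)
}
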