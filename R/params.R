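#' Dimensionless model parameters
#'
#' Bundles the dimensionless parameter set of the extended Keller-Segel
#' model. Lengths are measured in units of the run length scale
#' \eqn{x_0 = \sqrt{D_b^0 / k_g}}, times in units of the inverse maximal
#' growth rate \eqn{1/k_g}, densities and concentrations relative to their
#' initial scales \eqn{b_0, c_0}; see [nondimensionalize()].
#'
#' @param N Attractant-to-bacterial diffusivity ratio \eqn{D_c / D_b^0}
#'   (>= 0).
#' @param H Consumption strength \eqn{b_0 / (Y c_0)} (>= 0). `H = 0`
#'   disables attractant consumption.
#' @param K_S Monod half-saturation of growth/consumption, in units of
#'   `c0` (> 0).
#' @param eta Maximum relative swimming-speed increase \eqn{\eta = v_c/v_0}.
#'   `eta > 0` is positive chemokinesis (faster at high attractant);
#'   values in (-1, 0] model a negative or absent response. Must be >= -1.
#' @param omega Chemokinetic half-saturation concentration \eqn{\omega}
#'   (> 0): the attractant level at which half the maximal speed increase
#'   is reached.
#' @param n_hill Hill exponent n (>= 1) controlling the steepness of the
#'   speed response at `omega`; `n_hill = 1` is Michaelis-Menten, large n
#'   approaches a step response.
#' @param delta0 Chemotactic sensitivity ratio \eqn{\delta_0 = \chi_0 /
#'   D_b^0} (>= 0). `delta0 = 0` disables chemotaxis.
#' @param zeta Temporal-correction coefficient \eqn{\zeta = v_0/(\alpha
#'   x_0)} (>= 0): weight of the perceived temporal change of the
#'   attractant in the chemotactic drift. `zeta = 0` assumes the gradient
#'   is stationary in the frame of the swimming cell.
#' @param K_chi Chemotactic half-saturation concentration (> 0) of the
#'   receptor-saturation function \eqn{f_\chi = C/(C + K_\chi)}.
#' @param growth_on Logical: is the logistic growth term in the bacterial
#'   equation active? (Consumption of attractant is governed by `H` alone,
#'   so a population can consume without growing, as around a transient
#'   nutrient pulse.)
#' @param mode `"chemokinetic"` (speed follows the Hill response) or
#'   `"constant_speed"` (speed is uniformly `speed_factor`; the
#'   chemokinetic drift is then identically zero while diffusivity and
#'   chemotactic drift carry the factor `speed_factor^2`).
#' @param speed_factor Uniform dimensionless speed s >= 0 used in
#'   `"constant_speed"` mode; ignored otherwise.
#'
#' @return An object of class `"model_params"` (a validated list).
#' @seealso [nondimensionalize()], [hill_speed()], [hill_threshold()]
#' @examples
#' p <- model_params(eta = 2, omega = 0.2, n_hill = 5,
#'                   delta0 = 50, K_chi = 0.53)
#' hill_speed(c(0, 0.2, 1), p)
#' @export
model_params <- function(N = 0, H = 0, K_S = 1, eta = 0, omega = 1,
                         n_hill = 1, delta0 = 0, zeta = 0, K_chi = 1,
                         growth_on = FALSE,
                         mode = c("chemokinetic", "constant_speed"),
                         speed_factor = 1) {
  mode <- match.arg(mode)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(
    N = num1(N, "N"), H = num1(H, "H"), K_S = num1(K_S, "K_S"),
    eta = num1(eta, "eta"), omega = num1(omega, "omega"),
    n_hill = num1(n_hill, "n_hill"), delta0 = num1(delta0, "delta0"),
    zeta = num1(zeta, "zeta"), K_chi = num1(K_chi, "K_chi"),
    growth_on = isTRUE(growth_on), mode = mode,
    speed_factor = num1(speed_factor, "speed_factor")
  )
  if (p$N < 0) stop("'N' must be >= 0", call. = FALSE)
  if (p$H < 0) stop("'H' must be >= 0", call. = FALSE)
  if (p$K_S <= 0) stop("'K_S' must be > 0", call. = FALSE)
  if (p$eta < -1) stop("'eta' must be >= -1", call. = FALSE)
  if (p$omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  if (p$n_hill < 1) stop("'n_hill' must be >= 1", call. = FALSE)
  if (p$delta0 < 0) stop("'delta0' must be >= 0", call. = FALSE)
  if (p$zeta < 0) stop("'zeta' must be >= 0", call. = FALSE)
  if (p$K_chi <= 0) stop("'K_chi' must be > 0", call. = FALSE)
  if (p$speed_factor < 0) stop("'speed_factor' must be >= 0", call. = FALSE)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dimensionless model parameters (class 'model_params')\n")
  cat(sprintf("  diffusion/kinetics: N = %g, H = %g, K_S = %g, growth %s\n",
              x$N, x$H, x$K_S, if (x$growth_on) "on" else "off"))
  if (x$mode == "constant_speed") {
    cat(sprintf("  speed: constant, V = %g (chemokinetic drift off)\n",
                x$speed_factor))
  } else {
    cat(sprintf("  chemokinesis: eta = %g, omega = %g, n = %g\n",
                x$eta, x$omega, x$n_hill))
  }
  cat(sprintf("  chemotaxis: delta0 = %g, K_chi = %g, zeta = %g\n",
              x$delta0, x$K_chi, x$zeta))
  invisible(x)
}

#' Dimensional swimming, response and kinetic parameters
#'
#' Holds the dimensional quantities of the full model before rescaling.
#' The derived scales are `t0 = 1/k_g` (time), `D_b0 = v0^2/alpha`
#' (bacterial diffusivity) and `x0 = sqrt(t0 * D_b0)` (length).
#'
#' @param v0 Base swimming speed (length/time).
#' @param v_c Maximum chemokinetic speed increase (length/time, >= 0 for a
#'   positive response).
#' @param k_c Chemokinetic half-saturation concentration.
#' @param alpha Tumble rate (1/time).
#' @param beta Chemotactic response constant linking microscopic tumbling
#'   bias to the macroscopic sensitivity \eqn{\chi_0 = v_0^2 \beta /
#'   \alpha}.
#' @param k_chi Chemotactic half-saturation concentration.
#' @param k_g Maximum growth rate (1/time).
#' @param Y Bacterial yield (cells per unit attractant).
#' @param k_b Carrying capacity (cell density).
#' @param k_s Monod half-saturation concentration of growth.
#' @param D_c Attractant diffusivity (length^2/time).
#' @param b0 Initial bacterial density scale.
#' @param c0 Initial attractant concentration scale.
#'
#' @return An object of class `"dimensional_params"`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(v0, v_c, k_c, alpha, beta, k_chi,
                               k_g, Y, k_b, k_s, D_c, b0, c0) {
  d <- list(v0 = v0, v_c = v_c, k_c = k_c, alpha = alpha, beta = beta,
            k_chi = k_chi, k_g = k_g, Y = Y, k_b = k_b, k_s = k_s,
            D_c = D_c, b0 = b0, c0 = c0)
  bad <- !vapply(d, function(x) is.numeric(x) && length(x) == 1L &&
                   is.finite(x), logical(1))
  if (any(bad))
    stop("non-numeric dimensional parameter(s): ",
         paste(names(d)[bad], collapse = ", "), call. = FALSE)
  pos <- c("v0", "alpha", "k_g", "Y", "k_b", "k_s", "c0", "b0", "k_c",
           "k_chi")
  bad <- vapply(pos, function(nm) d[[nm]] <= 0, logical(1))
  if (any(bad))
    stop("dimensional parameter(s) must be > 0: ",
         paste(pos[bad], collapse = ", "), call. = FALSE)
  if (d$v_c < 0 && d$v_c <= -d$v0)
    stop("'v_c' must exceed -v0 (speed must stay positive)", call. = FALSE)
  if (d$D_c < 0) stop("'D_c' must be >= 0", call. = FALSE)
  class(d) <- "dimensional_params"
  d
}

#' Map dimensional parameters to the dimensionless model
#'
#' Computes the characteristic scales `t0 = 1/k_g`, `D_b0 = v0^2/alpha`,
#' `x0 = sqrt(t0 * D_b0)` and returns the dimensionless parameter set:
#' `N = D_c/D_b0`, `H = b0/(Y*c0)`, `K_S = k_s/c0`, `eta = v_c/v0`,
#' `omega = k_c/c0`, `delta0 = chi0/D_b0` with `chi0 = v0^2*beta/alpha`,
#' `zeta = v0/(alpha*x0)` and `K_chi = k_chi/c0`.
#'
#' @param d A [dimensional_params()] object.
#' @param n_hill Hill exponent of the speed response (dimensionless, passed
#'   through unchanged).
#' @param growth_on,mode,speed_factor Passed through to [model_params()].
#' @return A list with elements `params` (a `model_params` object) and
#'   `scales` (list with `t0`, `x0`, `D_b0`, `chi0`, `b0`, `c0`).
#' @examples
#' d <- dimensional_params(v0 = 20, v_c = 10, k_c = 1e-3, alpha = 1,
#'                         beta = 0.5, k_chi = 1e-3, k_g = 5e-4, Y = 1e9,
#'                         k_b = 1e9, k_s = 1e-3, D_c = 500,
#'                         b0 = 1e8, c0 = 1e-3)
#' nondimensionalize(d)$params
#' @export
nondimensionalize <- function(d, n_hill = 1, growth_on = TRUE,
                              mode = "chemokinetic", speed_factor = 1) {
  stopifnot(inherits(d, "dimensional_params"))
  t0 <- 1 / d$k_g
  D_b0 <- d$v0^2 / d$alpha
  x0 <- sqrt(t0 * D_b0)
  chi0 <- d$v0^2 * d$beta / d$alpha
  p <- model_params(
    N = d$D_c / D_b0,
    H = d$b0 / (d$Y * d$c0),
    K_S = d$k_s / d$c0,
    eta = d$v_c / d$v0,
    omega = d$k_c / d$c0,
    n_hill = n_hill,
    delta0 = chi0 / D_b0,
    zeta = d$v0 / (d$alpha * x0),
    K_chi = d$k_chi / d$c0,
    growth_on = growth_on, mode = mode, speed_factor = speed_factor
  )
  list(params = p,
       scales = list(t0 = t0, x0 = x0, D_b0 = D_b0, chi0 = chi0,
                     b0 = d$b0, c0 = d$c0))
}
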