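check_conc <- function(C) {
  if (!is.numeric(C) || any(!is.finite(C)))
    stop("concentration must be finite and numeric", call. = FALSE)
  if (any(C < 0))
    stop("concentration must be >= 0", call. = FALSE)
  invisible(C)
}

#' Dimensionless swimming-speed response
#'
#' Hill-type chemokinetic speed response
#' \deqn{V(C) = 1 + \eta \, C^n / (C^n + \omega^n),}
#' i.e. the local swimming speed relative to the base speed. At `C = omega`
#' the response is half-maximal (`1 + eta/2`); for `eta >= 0` the range is
#' `[1, 1 + eta]`. In `constant_speed` mode the response is uniformly
#' `speed_factor`, independent of C.
#'
#' @param C Attractant concentration(s), dimensionless, >= 0.
#' @param p A [model_params()] object.
#' @return Numeric vector of dimensionless speeds, same length as `C`.
#' @seealso [speed_sensitivity()], [chemokinetic_drift()]
#' @export
hill_speed <- function(C, p) {
  check_conc(C)
  if (p$mode == "constant_speed")
    return(rep(p$speed_factor, length(C)))
  Cn <- C^p$n_hill
  1 + p$eta * Cn / (Cn + p$omega^p$n_hill)
}

#' Derivative of the speed response with respect to concentration
#'
#' Analytic derivative of [hill_speed()]:
#' \deqn{dV/dC = n \eta \omega^n C^{n-1} / (C^n + \omega^n)^2,}
#' maximal near `C = omega` for the Hill family, zero in `constant_speed`
#' mode. (For `n_hill = 1` the value at `C = 0` is the finite limit
#' `eta/omega`.)
#'
#' @inheritParams hill_speed
#' @return Numeric vector, same length as `C`.
#' @export
speed_sensitivity <- function(C, p) {
  check_conc(C)
  if (p$mode == "constant_speed" || p$eta == 0)
    return(rep(0, length(C)))
  on <- p$omega^p$n_hill
  Cn <- C^p$n_hill
  p$n_hill * p$eta * on * C^(p$n_hill - 1) / (Cn + on)^2
}

#' Chemokinetic drift speed
#'
#' Drift induced by a spatially varying swimming speed,
#' \deqn{V_k = -V(C) \, (dV/dC) \, \nabla C,}
#' directed towards regions of *lower* speed: for positive chemokinesis
#' (`eta > 0`) it opposes the attractant gradient. Identically zero in
#' `constant_speed` mode.
#'
#' @inheritParams hill_speed
#' @param gradC Spatial attractant gradient(s) (same length as `C` or
#'   length 1).
#' @return Numeric vector of dimensionless drift speeds.
#' @export
chemokinetic_drift <- function(C, gradC, p) {
  -hill_speed(C, p) * speed_sensitivity(C, p) * gradC
}

#' Chemotactic drift speed
#'
#' Keller-Segel chemotactic drift with receptor saturation and an optional
#' temporal-gradient correction,
#' \deqn{V_\chi = V(C)^2 \frac{\delta_0 K_\chi}{(C + K_\chi)^2}
#'   \left(\nabla C + \frac{\zeta}{V(C)} \partial_T C\right).}
#' A temporally decaying attractant field (`dCdT < 0`) reduces the drift a
#' swimming cell experiences; the reduction is weaker at higher swimming
#' speed, which is how chemokinesis mitigates the bias around transient
#' sources.
#'
#' @inheritParams chemokinetic_drift
#' @param dCdT Local temporal derivative of the attractant field
#'   (default 0: stationary profile).
#' @return Numeric vector of dimensionless drift speeds.
#' @export
chemotactic_drift <- function(C, gradC, dCdT = 0, p) {
  V <- hill_speed(C, p)
  V^2 * p$delta0 * p$K_chi / (C + p$K_chi)^2 * (gradC + p$zeta / V * dCdT)
}

#' Monod saturation fraction
#'
#' `C / (C + K_S)`, the saturating growth/consumption kinetics shared by
#' the bacterial growth and attractant consumption terms.
#'
#' @param C Concentration(s), >= 0.
#' @param K_S Half-saturation constant, > 0.
#' @return Numeric vector in `[0, 1)`.
#' @export
monod <- function(C, K_S) {
  check_conc(C)
  if (K_S <= 0) stop("'K_S' must be > 0", call. = FALSE)
  C / (C + K_S)
}

#' Growth and consumption reaction terms
#'
#' Logistic, Monod-limited bacterial growth `B g(C) (1 - B)` (active only
#' when `p$growth_on`) and attractant consumption `-H B g(C)` (governed by
#' `H` alone, so consumption can act while growth is switched off, as
#' around a transient nutrient pulse).
#'
#' @param B Bacterial density (>= 0).
#' @param C Attractant concentration (>= 0).
#' @param p A [model_params()] object.
#' @return List with components `growth` (dB/dT contribution) and
#'   `consumption` (dC/dT contribution, <= 0).
#' @export
reaction_terms <- function(B, C, p) {
  if (any(B < 0)) stop("density must be >= 0", call. = FALSE)
  g <- monod(C, p$K_S)
  growth <- if (p$growth_on) B * g * (1 - B) else rep(0, length(B))
  list(growth = growth, consumption = -p$H * B * g)
}

#' Pointwise bacterial flux
#'
#' Assembles the dimensionless bacterial flux
#' \deqn{J = -V(C)^2 \nabla B + V_k B + V_\chi B,}
#' the sum of Fickian diffusion with speed-dependent diffusivity
#' \eqn{D = V^2}, the chemokinetic drift flux and the chemotactic drift
#' flux. The two drifts compete wherever `eta > 0` and `delta0 > 0`: the
#' chemokinetic part points down-gradient, the chemotactic part up-gradient.
#'
#' @param B,gradB Bacterial density and its spatial gradient.
#' @param C,gradC Attractant concentration and its spatial gradient.
#' @param dCdT Temporal derivative of the attractant field (default 0).
#' @param p A [model_params()] object.
#' @param components If `TRUE`, return a list with the three contributions
#'   (`diffusive`, `chemokinetic`, `chemotactic`) and their sum (`total`).
#' @return Numeric flux vector, or a list of components.
#' @export
assemble_flux <- function(B, gradB, C, gradC, dCdT = 0, p,
                          components = FALSE) {
  V <- hill_speed(C, p)
  diffusive <- -V^2 * gradB
  kinetic <- chemokinetic_drift(C, gradC, p) * B
  tactic <- chemotactic_drift(C, gradC, dCdT, p) * B
  if (components)
    list(diffusive = diffusive, chemokinetic = kinetic,
         chemotactic = tactic, total = diffusive + kinetic + tactic)
  else diffusive + kinetic + tactic
}
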