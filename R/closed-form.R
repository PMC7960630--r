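#' Pointwise comparison of chemokinetic and chemotactic drift strengths
#'
#' For a stationary linear attractant profile the two drift speeds share
#' the factor `V(C)^2 * gradC`, so their relative size reduces to comparing
#' \deqn{\mathrm{lhs} = \frac{n \eta \omega^n C^{n-1}}{(C^n + \omega^n)^2
#'   \, V(C)} \quad \text{vs} \quad
#'   \mathrm{rhs} = \frac{\delta_0 K_\chi}{(C + K_\chi)^2}.}
#' The chemokinetic drift exceeds the chemotactic drift at concentration C
#' exactly when `lhs > rhs`.
#'
#' @inheritParams hill_speed
#' @return List with numeric vectors `lhs` and `rhs` (same length as `C`)
#'   and logical `dominant` (= `lhs > rhs`).
#' @seealso [hill_threshold()]
#' @export
dominance_condition <- function(C, p) {
  check_conc(C)
  V <- hill_speed(C, p)
  lhs <- speed_sensitivity(C, p) / V
  rhs <- p$delta0 * p$K_chi / (C + p$K_chi)^2
  list(lhs = lhs, rhs = rhs, dominant = lhs > rhs)
}

#' Threshold Hill exponent for dominant chemokinetic drift
#'
#' Closed-form threshold
#' \deqn{n^* = \frac{4 \delta_0 \omega K_\chi}{(\omega + K_\chi)^2}
#'   \left(\frac{1}{\eta} + \frac{1}{2}\right),}
#' valid for positive chemokinesis (`eta > 0`): if the Hill exponent
#' exceeds `n*`, the chemokinetic drift is larger than the chemotactic
#' drift at the half-saturation concentration `C = omega`, where the speed
#' gradient of the Hill family is steepest. For `eta <= 0` the two drifts
#' never compete in this sense (negative chemokinesis reinforces
#' chemotaxis), and the sentinel string `"never"` is returned -- a
#' deliberately type-stable marker for parameter scans rather than an
#' infinite numeric.
#'
#' @param p A [model_params()] object with `eta`, `omega`, `delta0`,
#'   `K_chi` set.
#' @return A single number `n*`, or the character string `"never"`.
#' @examples
#' p <- model_params(eta = 2, omega = 0.2, n_hill = 5,
#'                   delta0 = 50, K_chi = 0.53)
#' hill_threshold(p)  # 39.78...
#' @export
hill_threshold <- function(p) {
  if (p$mode == "constant_speed" || p$eta <= 0) return("never")
  4 * p$delta0 * p$omega * p$K_chi / (p$omega + p$K_chi)^2 *
    (1 / p$eta + 1 / 2)
}

#' Zero-flux steady-state density ratio in a fixed attractant profile
#'
#' For a static attractant field with homogeneous Neumann (zero total flux)
#' boundaries, setting J = 0 and integrating gives the steady state
#' \deqn{\frac{B}{B^*} = \frac{V^*}{V}
#'   \exp\left\{\delta_0\left(\frac{C}{C + K_\chi} -
#'   \frac{C^*}{C^* + K_\chi}\right)\right\},}
#' where starred quantities are evaluated at a reference location. The
#' prefactor `V*/V` is the chemokinetic accumulation at low speed; the
#' exponential is the classical chemotactic steady state and is recovered
#' exactly in `constant_speed` mode (uniform V).
#'
#' @param C_profile Static attractant concentration field (numeric vector).
#' @param ref_index Index of the reference location (default 1).
#' @param p A [model_params()] object.
#' @return Numeric vector `B/B*`, equal to 1 at `ref_index`.
#' @export
steady_state_ratio <- function(C_profile, ref_index = 1L, p) {
  check_conc(C_profile)
  stopifnot(ref_index >= 1L, ref_index <= length(C_profile))
  V <- hill_speed(C_profile, p)
  Cs <- C_profile[ref_index]
  Vs <- V[ref_index]
  (Vs / V) * exp(p$delta0 * (C_profile / (C_profile + p$K_chi) -
                               Cs / (Cs + p$K_chi)))
}
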