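# Shared fixtures and independent oracles for the test suite.

# Benchmark parameter set of the fixed-linear-gradient scenario
linear_gradient_params <- function(...) {
  overrides <- list(...)
  base <- list(N = 0, H = 0, K_S = 1, eta = 2, omega = 0.2, n_hill = 5,
               delta0 = 50, zeta = 0, K_chi = 0.53, growth_on = FALSE)
  do.call(model_params, utils::modifyList(base, overrides))
}

# Admissible random parameter draw for property-style tests
random_params <- function() {
  model_params(
    N = runif(1, 0, 2), H = runif(1, 0, 5), K_S = runif(1, 0.2, 2),
    eta = runif(1, 0.2, 3), omega = runif(1, 0.1, 1),
    n_hill = sample(1:12, 1), delta0 = runif(1, 1, 100),
    zeta = runif(1, 0, 0.05), K_chi = runif(1, 0.1, 1))
}

# Independent oracle for the zero-flux steady state: integrate the
# first-order ODE  dB/dX = -B [ (1/2D) dD/dX - delta0 d/dX(C/(C+K_chi)) ]
# with D = V^2, written out from scratch (no package functions), using
# deSolve as the integrator.
steady_ode_oracle <- function(x_out, Cfun, dCdX, eta, omega, n, delta0,
                              K_chi) {
  rhs <- function(x, y, parms) {
    C <- Cfun(x)
    Cn <- C^n
    on <- omega^n
    V <- 1 + eta * Cn / (Cn + on)
    dVdC <- n * eta * on * C^(n - 1) / (Cn + on)^2
    D <- V^2
    dDdX <- 2 * V * dVdC * dCdX(x)
    chem <- delta0 * K_chi / (C + K_chi)^2 * dCdX(x)
    list(-y[1] * (dDdX / (2 * D) - chem))
  }
  deSolve::ode(y = c(B = 1), times = x_out, func = rhs, parms = NULL,
               rtol = 1e-10, atol = 1e-12)[, "B"]
}

# L1 distance between two profiles after normalizing both to unit mass
l1_mass_normalized <- function(B_num, B_ref, w) {
  a <- B_num / sum(B_num * w)
  b <- B_ref / sum(B_ref * w)
  sum(abs(a - b) * w)
}
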