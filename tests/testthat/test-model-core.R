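test_that("hill_speed matches the closed form and its limits", {
  p <- linear_gradient_params()
  # C = omega gives exactly the half-maximal increase
  expect_equal(hill_speed(0.2, p), 2.0)
  # zero attractant: base speed, for any parameter set
  expect_equal(hill_speed(0, p), 1.0)
  expect_equal(hill_speed(0, linear_gradient_params(n_hill = 1)), 1.0)
  # direct evaluation at C = 1
  expect_equal(hill_speed(1, p), 1 + 2 / (1 + 0.2^5), tolerance = 1e-12)
  # constant-speed mode ignores C entirely
  ps <- model_params(mode = "constant_speed", speed_factor = 1.5,
                     eta = 2, omega = 0.2)
  expect_equal(hill_speed(c(0, 0.2, 5), ps), rep(1.5, 3))
  expect_error(hill_speed(-0.1, p), "concentration")
})

test_that("hill_speed is bounded in [1, 1+eta] and monotone for eta > 0", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    C <- sort(runif(60, 0, 4))
    V <- hill_speed(C, p)
    expect_true(all(V >= 1 - 1e-12))
    expect_true(all(V <= 1 + p$eta + 1e-12))
    expect_true(all(diff(V) >= -1e-12))
  }
  # negative chemokinesis stays positive and decreasing
  pn <- model_params(eta = -0.8, omega = 0.3, n_hill = 3)
  V <- hill_speed(seq(0, 5, by = 0.1), pn)
  expect_true(all(V > 0))
  expect_true(all(diff(V) <= 1e-12))
})

test_that("speed_sensitivity is the derivative of hill_speed", {
  p1 <- linear_gradient_params(n_hill = 1)
  # closed form at C = omega, n = 1: eta*omega/(C+omega)^2
  expect_equal(speed_sensitivity(0.2, p1), 2 * 0.2 / 0.4^2,
               tolerance = 1e-12)
  # eta = 0 and saturation limits
  expect_equal(speed_sensitivity(c(0, 0.5, 3),
                                 linear_gradient_params(eta = 0)),
               rep(0, 3))
  expect_lt(speed_sensitivity(1e6, p1), 1e-11)
  # central finite differences on random draws
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    C <- runif(10, 0.05, 3)
    h <- 1e-6 * pmax(C, 1)
    fd <- (hill_speed(C + h, p) - hill_speed(C - h, p)) / (2 * h)
    expect_equal(speed_sensitivity(C, p), fd, tolerance = 1e-6)
  }
})

test_that("chemokinetic drift points towards low speed and scales with n", {
  p <- linear_gradient_params(n_hill = 1)
  expect_equal(chemokinetic_drift(0.5, 0, p), 0)
  expect_equal(chemokinetic_drift(0.5, 1,
                                  linear_gradient_params(eta = 0)), 0)
  # product of speed and sensitivity at C = omega, n = 1
  expect_equal(chemokinetic_drift(0.2, 1, p), -2 * 2.5,
               tolerance = 1e-12)
  # drift opposes the gradient for positive chemokinesis
  set.seed(11)
  for (i in 1:15) {
    pr <- random_params()
    g <- runif(1, 0.1, 2)
    expect_lt(chemokinetic_drift(pr$omega, g, pr), 0)
    expect_gt(chemokinetic_drift(pr$omega, -g, pr), 0)
  }
  # at C = omega the magnitude grows linearly in n:
  # |V_k| = V * n*eta/(4*omega) * |gradC|
  for (n in c(5, 10, 20, 40)) {
    pn <- linear_gradient_params(n_hill = n)
    expect_equal(chemokinetic_drift(0.2, 1, pn),
                 -2 * n * 2 / (4 * 0.2), tolerance = 1e-12)
  }
})

test_that("chemotactic drift follows the saturating Keller-Segel form", {
  p <- linear_gradient_params(eta = 0)   # V = 1
  expect_equal(chemotactic_drift(0.3, 0, 0, p), 0)
  expect_equal(chemotactic_drift(0, 0.1, 0, p), 50 / 0.53 * 0.1,
               tolerance = 1e-12)
  # opposite sign to the chemokinetic drift wherever gradC != 0
  set.seed(13)
  for (i in 1:15) {
    pr <- random_params()
    C <- runif(1, 0.05, 2)
    g <- runif(1, 0.1, 2) * sign(runif(1) - 0.5)
    expect_lt(chemokinetic_drift(C, g, pr) * chemotactic_drift(C, g, 0, pr),
              0)
  }
})

test_that("temporal correction reduces drift for decaying gradients,
           less so at high speed", {
  pz <- linear_gradient_params(zeta = 0.05)
  g <- 0.1
  # decaying attractant strictly reduces the drift
  v_static <- chemotactic_drift(0.3, g, 0, pz)
  v_decay <- chemotactic_drift(0.3, g, -1, pz)
  expect_lt(v_decay, v_static)
  # relative reduction shrinks as the swimming speed grows
  rel_red <- sapply(c(1, 1.5, 2, 3), function(s) {
    ps <- model_params(mode = "constant_speed", speed_factor = s,
                       delta0 = 50, K_chi = 0.53, zeta = 0.05)
    1 - chemotactic_drift(0.3, g, -1, ps) /
      chemotactic_drift(0.3, g, 0, ps)
  })
  expect_true(all(diff(rel_red) < 0))
})

test_that("monod kinetics and reaction terms have the textbook values", {
  expect_equal(monod(0, 1), 0)
  expect_equal(monod(1, 1), 0.5)
  expect_equal(monod(3, 1), 0.75)
  p <- model_params(H = 3.5, K_S = 1, growth_on = TRUE)
  r <- reaction_terms(0.2, 1, p)
  expect_equal(r$growth, 0.08, tolerance = 1e-12)
  expect_equal(r$consumption, -0.35, tolerance = 1e-12)
  # logistic fixed point and absence of attractant
  expect_equal(reaction_terms(1, 0.7, p)$growth, 0)
  r0 <- reaction_terms(0.4, 0, p)
  expect_equal(r0$growth, 0)
  expect_equal(r0$consumption, 0)
  # growth gated off; consumption governed by H alone
  poff <- model_params(H = 3.5, K_S = 1, growth_on = FALSE)
  roff <- reaction_terms(0.2, 1, poff)
  expect_equal(roff$growth, 0)
  expect_equal(roff$consumption, -0.35, tolerance = 1e-12)
  expect_equal(reaction_terms(0.2, 1, model_params(H = 0, K_S = 1,
                                                   growth_on = FALSE))$consumption, 0)
})

test_that("assemble_flux decomposes into its three components", {
  p <- linear_gradient_params(zeta = 0.01)
  # pure diffusion of an infinitesimal population
  expect_equal(assemble_flux(0, 0.3, 0.5, 1, 0, p),
               -hill_speed(0.5, p)^2 * 0.3)
  # uniform static fields carry no flux
  expect_equal(assemble_flux(0.7, 0, 0.5, 0, 0, p), 0)
  set.seed(5)
  for (i in 1:10) {
    pr <- random_params()
    B <- runif(8, 0, 2); gB <- rnorm(8); C <- runif(8, 0, 2)
    gC <- rnorm(8); dC <- rnorm(8)
    parts <- assemble_flux(B, gB, C, gC, dC, pr, components = TRUE)
    expect_equal(parts$total,
                 parts$diffusive + parts$chemokinetic + parts$chemotactic,
                 tolerance = 1e-12)
    expect_equal(parts$total, assemble_flux(B, gB, C, gC, dC, pr),
                 tolerance = 1e-12)
  }
})

test_that("nondimensionalization reproduces the characteristic scales", {
  d <- dimensional_params(v0 = 20, v_c = 10, k_c = 2e-3, alpha = 1,
                          beta = 0.5, k_chi = 1e-3, k_g = 5e-4, Y = 1e9,
                          k_b = 1e9, k_s = 1e-3, D_c = 500, b0 = 1e8,
                          c0 = 1e-3)
  nd <- nondimensionalize(d, n_hill = 2)
  s <- nd$scales
  expect_equal(s$t0, 1 / d$k_g)
  expect_equal(s$D_b0, d$v0^2 / d$alpha)
  expect_equal(s$x0, sqrt(s$t0 * s$D_b0))
  p <- nd$params
  expect_equal(p$N, d$D_c / s$D_b0)
  expect_equal(p$H, d$b0 / (d$Y * d$c0))
  expect_equal(p$eta, d$v_c / d$v0)
  expect_equal(p$omega, d$k_c / d$c0)
  expect_equal(p$zeta, d$v0 / (d$alpha * s$x0))
  # chi0 = v0^2 beta / alpha, so delta0 = chi0/D_b0 = beta;
  # beta = 1 makes chi0 = D_b0 exactly
  expect_equal(p$delta0, d$beta)
  d1 <- dimensional_params(v0 = 20, v_c = 0, k_c = 2e-3, alpha = 1,
                           beta = 1, k_chi = 1e-3, k_g = 5e-4, Y = 1e9,
                           k_b = 1e9, k_s = 1e-3, D_c = 500, b0 = 1e8,
                           c0 = 1e-3)
  p1 <- nondimensionalize(d1)$params
  expect_equal(p1$delta0, 1)
  expect_equal(p1$eta, 0)   # v_c = 0 is pure chemotaxis
  # round trip: re-dimensionalize with the same scales
  expect_equal(p$K_S * d$c0, d$k_s)
  expect_equal(p$K_chi * d$c0, d$k_chi)
  expect_equal(p$eta * d$v0, d$v_c)
  expect_equal(p$N * s$D_b0, d$D_c)
})

test_that("parameter constructors validate their invariants", {
  expect_error(model_params(omega = 0), "omega")
  expect_error(model_params(K_chi = -1), "K_chi")
  expect_error(model_params(n_hill = 0.5), "n_hill")
  expect_error(model_params(delta0 = -1), "delta0")
  expect_error(model_params(eta = -1.5), "eta")
  expect_error(dimensional_params(v0 = -1, v_c = 0, k_c = 1, alpha = 1,
                                  beta = 1, k_chi = 1, k_g = 1, Y = 1,
                                  k_b = 1, k_s = 1, D_c = 1, b0 = 1,
                                  c0 = 1), "v0")
})
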