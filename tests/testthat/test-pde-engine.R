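test_that("finite-volume Laplacian matches closed forms", {
  g <- make_grid("cartesian1d", 0, 4, 200)
  expect_equal(fv_laplacian(rep(3.7, 200), g), rep(0, 200))
  # d2/dx2 of x^2 = 2, exact away from the zero-flux boundaries
  lap <- fv_laplacian(g$cell_centers^2, g)
  interior <- 5:196
  expect_equal(lap[interior], rep(2, length(interior)),
               tolerance = 1e-10)
  # axisymmetric: Laplacian of R^2 is 4 in two dimensions
  ga <- make_grid("axisymmetric", 0, 4, 200)
  lapa <- fv_laplacian(ga$cell_centers^2, ga)
  expect_equal(lapa[1:196], rep(4, 196), tolerance = 1e-10)
})

test_that("axisymmetric operator reduces to Cartesian far from the axis", {
  # a field supported near R = 100: curvature term ~ 1/R is negligible
  ga <- make_grid("axisymmetric", 0, 110, 1100)
  gc <- make_grid("cartesian1d", 0, 110, 1100)
  f <- exp(-(ga$cell_centers - 100)^2 / 4)
  la <- fv_laplacian(f, ga)
  lc <- fv_laplacian(f, gc)
  expect_lt(max(abs(la - lc)) / max(abs(lc)), 0.02)
})

test_that("flux divergence is conservative and reduces to diffusion", {
  set.seed(31)
  for (geom in c("cartesian1d", "axisymmetric")) {
    g <- make_grid(geom, 0, 6, 150)
    w <- g$cell_weights
    B <- runif(150, 0, 2)
    C <- runif(150, 0, 1.5)
    p <- linear_gradient_params(zeta = 0.01)
    # uniform fields carry no flux
    expect_equal(divergence_of_flux(rep(1, 150), rep(0.5, 150), 0, g, p),
                 rep(0, 150))
    # telescoping: the operator moves mass around but never creates it
    div <- divergence_of_flux(B, C, rnorm(150), g, p)
    expect_lt(abs(sum(div * w)) / sum(abs(div) * w), 1e-12)
    # eta = 0, delta0 = 0: V = 1 and the operator is the Laplacian
    pd <- model_params()
    expect_equal(divergence_of_flux(B, C, 0, g, pd), fv_laplacian(B, g),
                 tolerance = 1e-12)
  }
})

test_that("compiled right-hand side matches the R reference", {
  set.seed(37)
  p <- model_params(N = 0.5, H = 3.5, K_S = 1, eta = 2, omega = 0.2,
                    n_hill = 5, delta0 = 50, zeta = 0.01, K_chi = 0.53,
                    growth_on = TRUE)
  for (geom in c("cartesian1d", "axisymmetric")) {
    g <- make_grid(geom, 0, 5, 80)
    geom_i <- if (geom == "axisymmetric") 1L else 0L
    B <- runif(80, 0, 2)
    C <- runif(80, 0, 1.5)
    st <- field_state(0, B, C)
    for (cm in c("frozen", "dynamic")) {
      rR <- pde_rhs(st, g, p, cm)
      rC <- chemokin:::cpp_rhs(B, C, 0, g$dx, geom_i, g$cell_centers,
                               g$face_positions, unclass(p),
                               match(cm, c("frozen", "dynamic")) - 1L,
                               0, 0)
      scale <- max(abs(rR$dB), 1)
      expect_lt(max(abs(rR$dB - rC$dB)) / scale, 1e-12)
      expect_lt(max(abs(rR$dC - rC$dC)) / max(abs(rR$dC), 1), 1e-12)
    }
  }
})

test_that("frozen attractant and zero kinetics leave uniform fields at rest", {
  g <- make_grid("cartesian1d", 0, 5, 60)
  p <- linear_gradient_params()
  r <- pde_rhs(field_state(0, rep(0.3, 60), rep(0.8, 60)), g, p, "frozen")
  expect_equal(r$dB, rep(0, 60))
  expect_equal(r$dC, rep(0, 60))
})

test_that("diffusion-only dynamics reproduce the spreading heat kernel", {
  # axisymmetric pulse of unit content, unit diffusivity (V = 1)
  g <- make_grid("axisymmetric", 0, 10, 400)
  p <- model_params()
  B0 <- gaussian_pulse(g$cell_centers, 0.05, 1, 1)
  tr <- advance(field_state(0.05, B0, rep(0, 400)), g, p,
                t_out = c(0.1, 0.2), c_mode = "frozen")
  for (i in 1:2) {
    ref <- gaussian_pulse(g$cell_centers, tr$times[i], 1, 1)
    expect_lt(max(abs(tr$B[, i] - ref)), 1e-3)
  }
  # peak decays as 1/T
  expect_equal(max(tr$B[, 2]) / max(tr$B[, 1]), 0.1 / 0.2,
               tolerance = 2e-3)
})

test_that("mass is conserved and fields stay non-negative", {
  set.seed(41)
  for (geom in c("cartesian1d", "axisymmetric")) {
    g <- make_grid(geom, 0, 8, 160)
    x <- g$cell_centers
    p <- model_params(N = 0.5, H = 2, K_S = 1, eta = 2, omega = 0.2,
                      n_hill = 5, delta0 = 30, zeta = 5e-3, K_chi = 0.53,
                      growth_on = FALSE)
    B0 <- 0.2 + exp(-(x - 3)^2)
    C0 <- exp(-(x - 4)^2 / 2)
    tr <- advance(field_state(0, B0, C0), g, p, t_out = c(0.5, 1, 2),
                  c_mode = "dynamic")
    m0 <- sum(B0 * g$cell_weights)
    for (i in 1:3) {
      expect_lt(abs(sum(tr$B[, i] * g$cell_weights) - m0) / m0, 1e-8)
      expect_true(all(tr$B[, i] >= 0))
      expect_true(all(tr$C[, i] >= 0))
    }
    expect_equal(tr$clipped_B, 0)
  }
})

test_that("logistic growth at saturating attractant is exponential at
           unit rate", {
  g <- make_grid("cartesian1d", 0, 5, 50)
  p <- model_params(K_S = 1, growth_on = TRUE)
  C0 <- rep(9, 50)           # g(C) = 0.9
  B0 <- rep(1e-4, 50)        # far below carrying capacity
  tr <- advance(field_state(0, B0, C0), g, p, t_out = 1,
                c_mode = "frozen")
  expect_equal(max(tr$B[, 1]) / 1e-4, exp(0.9), tolerance = 1e-3)
})

test_that("error against the steady-state oracle shrinks at the scheme's
           order under grid refinement", {
  p <- model_params(eta = 1, omega = 0.3, n_hill = 2, delta0 = 6,
                    K_chi = 0.5)
  errs <- sapply(c(50, 100, 200), function(nc) {
    g <- make_grid("cartesian1d", 0, 2, nc)
    C <- g$cell_centers / 2
    tr <- advance(field_state(0, rep(1, nc), C), g, p, t_out = 30,
                  c_mode = "frozen")
    ref <- steady_state_ratio(C, 1L, p)
    l1_mass_normalized(tr$B[, 1], ref, g$cell_weights)
  })
  expect_true(all(diff(errs) < 0))
  # observed convergence is about second order (ratio ~ 4 per halving)
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("time stepping aborts on step-size collapse with a diagnostic", {
  g <- make_grid("cartesian1d", 0, 5, 100)
  p <- linear_gradient_params()
  st <- field_state(0, exp(-(g$cell_centers - 1)^2), g$cell_centers / 5)
  expect_error(advance(st, g, p, t_out = 5, c_mode = "frozen",
                       dt_min = 1),
               "step-size collapse")
})

test_that("grid and state constructors enforce their invariants", {
  expect_error(make_grid("axisymmetric", 1, 5, 10), "R = 0")
  expect_error(make_grid("cartesian1d", 0, 0, 10), "x_max")
  g <- make_grid("axisymmetric", 0, 10, 100)
  expect_equal(sum(g$cell_weights), pi * 100, tolerance = 1e-12)
  expect_equal(diff(g$face_positions), rep(g$dx, 100))
  expect_error(field_state(0, c(-1, 1), c(0, 0)), "non-negative")
  expect_error(field_state(0, c(1, NaN), c(0, 0)), "finite")
  expect_error(advance(field_state(0, rep(1, 100), rep(0, 100)), g,
                       model_params(), t_out = c(2, 1)), "increasing")
})
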