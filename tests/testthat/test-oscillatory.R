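test_that("zero forcing keeps the fluid at rest", {
  g <- radial_grid(0.002, 64)
  sol <- solve_oscillatory(g, water_like(), source_term("constant_zero"),
                           t_end = 0.5, dt = 0.01)
  expect_equal(max(abs(sol$u)), 0)
})

test_that("step forcing converges to the Poiseuille profile", {
  w <- water_like()
  R <- 0.002                       # viscous time R^2/nu = 4 s
  g <- radial_grid(R, 128)
  sol <- solve_oscillatory(g, w, source_term("constant", amplitude = 10),
                           t_end = 30, dt = 0.05)
  u_exact <- 10 * (R^2 - g$r^2) / (4 * w$dynamic_viscosity)
  u_end <- sol$u[nrow(sol$u), ]
  expect_lt(max(abs(u_end - u_exact)) / max(u_exact), 0.01)
  expect_equal(u_end[length(u_end)], 0)  # no-slip
})

test_that("solver matches the analytic Womersley profile", {
  w <- water_like()
  R <- 0.002; nu <- 1e-6
  womersley_l2 <- function(alpha, n_periods, n = 128) {
    f <- alpha^2 * nu / (2 * pi * R^2)
    g <- radial_grid(R, n)
    src <- source_term("sinusoidal", amplitude = 100, frequency = f)
    sol <- solve_oscillatory(g, w, src, t_end = n_periods / f,
                             dt = (1 / f) / 200)
    uhat <- analytic_womersley(alpha, 100, f, w, R, g$r / R)
    idx <- which(sol$times >= (n_periods - 1) / f)
    err <- 0; ref <- 0
    for (k in idx) {
      ua <- Im(uhat * exp(2i * pi * f * sol$times[k]))
      err <- err + sum((sol$u[k, ] - ua)^2)
      ref <- ref + sum(ua^2)
    }
    sqrt(err / ref)
  }
  # moderate alpha: the start-up transient decays within a few periods
  expect_lt(womersley_l2(3, n_periods = 6), 0.01)
  # aortic alpha = 15 needs a multi-viscous-time horizon for the transient
  expect_lt(womersley_l2(15, n_periods = 60), 0.01)
})

test_that("analytic profile satisfies no-slip and the quasi-steady limit", {
  w <- water_like()
  R <- 0.002; nu <- 1e-6
  f <- 0.01^2 * nu / (2 * pi * R^2)
  u0 <- analytic_womersley(0.01, 10, f, w, R, c(0, 0.5, 1))
  pois <- 10 * (R^2 - c(0, R / 2, R)^2) / (4 * w$dynamic_viscosity)
  expect_equal(Mod(u0), pois, tolerance = 1e-3)
  expect_equal(Mod(analytic_womersley(15, 100, 1, blood(), 0.01, 1)), 0)
  expect_error(analytic_womersley(40, 1, 1, w, R, 0.5), "asymptotic")
})

test_that("radial discretization is at least second order", {
  w <- water_like()
  R <- 0.002; nu <- 1e-6; alpha <- 3
  f <- alpha^2 * nu / (2 * pi * R^2)
  err_at <- function(n) {
    g <- radial_grid(R, n)
    src <- source_term("sinusoidal", amplitude = 100, frequency = f)
    sol <- solve_oscillatory(g, w, src, t_end = 6 / f, dt = (1 / f) / 400)
    uhat <- analytic_womersley(alpha, 100, f, w, R, g$r / R)
    k <- nrow(sol$u)
    ua <- Im(uhat * exp(2i * pi * f * sol$times[k]))
    sqrt(mean((sol$u[k, ] - ua)^2)) / max(Mod(uhat))
  }
  e1 <- err_at(40); e2 <- err_at(80)
  expect_gt(e1 / e2, 2.5)          # halving the spacing cuts error ~4x
})

test_that("the oscillatory problem is linear in the forcing amplitude", {
  g <- radial_grid(0.01, 48)
  b <- blood()
  s1 <- solve_oscillatory(g, b, source_term("sinusoidal", amplitude = 100,
                                            frequency = 1),
                          t_end = 2, dt = 0.01)
  s2 <- solve_oscillatory(g, b, source_term("sinusoidal", amplitude = 200,
                                            frequency = 1),
                          t_end = 2, dt = 0.01)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-12)
})

test_that("coarse time steps are refused and grids validated", {
  g <- radial_grid(0.01, 48)
  expect_error(solve_oscillatory(g, blood(),
                                 source_term("sinusoidal", frequency = 10),
                                 t_end = 1, dt = 0.01),
               "steps per forcing period")
  expect_error(radial_grid(0.01, 8), "at least 32")
})

test_that("total velocity superposes steady and oscillatory parts", {
  g <- radial_grid(0.01, 48)
  b <- blood()
  u <- solve_oscillatory(g, b, source_term("sinusoidal", amplitude = 100,
                                           frequency = 1),
                         t_end = 1, dt = 0.01)
  v_st <- 0.35 * (1 - (g$r / g$R)^2)
  vz <- total_velocity(v_st, u)
  expect_equal(vz[1, ], v_st)                       # u(t=0) = 0
  expect_equal(total_velocity(rep(0, 48), u), u$u)
  k <- nrow(u$u)
  expect_equal(profile_mean(vz[k, ], g),
               profile_mean(v_st, g) + profile_mean(u$u[k, ], g))
  expect_error(total_velocity(rep(0.3, 47), u), "grids differ")
})
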