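test_that("laminar marching recovers Hagen-Poiseuille downstream", {
  # Re = 50: the hydrodynamic entry length (0.05 m) sits well inside the
  # 0.2 m domain, so the exit profile is essentially developed
  props <- air_like()
  v_in <- 50 * props$dynamic_viscosity / (props$density * 0.02)
  fl <- solve_steady_flow(aorta(), props, v_in, closure = "laminar")
  n <- nrow(fl$v)
  expect_gt(fl$v[n, 1] / v_in, 1.95)
  r <- fl$eta * 0.01
  pois <- 2 * v_in * (1 - (r / 0.01)^2)
  expect_lt(max(abs(fl$v[n, ] - pois)) / max(pois), 0.02)
  # mass conservation along the march
  w <- graftherm:::cv_weights(r)
  m <- apply(fl$v, 1, function(v) sum(w * v))
  expect_lt((max(m) - min(m)) / m[1], 0.005)
})

test_that("transitional closure flattens the profile below Poiseuille", {
  fl <- flow_035()
  n <- nrow(fl$v)
  expect_lt(fl$v[n, 1] / mean_velocity(fl, 0.2), 2)
  # higher in the transitional band the eddy viscosity makes the profile
  # fuller near the wall than a forced-laminar solution, and it stays far
  # from the Poiseuille peak (the blunting signature, clearest off-axis
  # because both entrance profiles are still slug-like on the centerline)
  fl65 <- solve_steady_flow(aorta(), blood(), 0.65)
  fll65 <- solve_steady_flow(aorta(), blood(), 0.65, closure = "laminar",
                             force = TRUE)
  i9 <- which.min(abs(fl65$eta - 0.9))
  expect_gt(fl65$v[n, i9] / mean_velocity(fl65, 0.2),
            1.2 * fll65$v[n, i9] / mean_velocity(fll65, 0.2))
  expect_lt(fl65$v[n, 1] / mean_velocity(fl65, 0.2), 2)
  expect_error(solve_steady_flow(aorta(), blood(), 0.35,
                                 closure = "laminar"), "refused")
})

test_that("fully developed laminar heat transfer reaches Nu = 48/11", {
  props <- air_like()                     # Pr ~ 0.7: thermal development fits
  v_in <- 100 * props$dynamic_viscosity / (props$density * 0.02)
  fl <- solve_steady_flow(aorta(), props, v_in, closure = "laminar")
  tp <- solve_temperature(fl, props, q_in = 200, T_in = 310.15)
  Nu_exit <- tp$h[length(tp$h)] * 0.02 / props$thermal_conductivity
  expect_equal(Nu_exit, 48 / 11, tolerance = 0.02)
})

test_that("the energy balance closes for the steady temperature field", {
  fl <- flow_035(); tp <- temp_035()
  r <- fl$eta * 0.01
  w <- graftherm:::cv_weights(r)
  mdot_cp <- blood()$density * blood()$specific_heat *
    2 * pi * sum(w * fl$v[1, ])
  wall_in <- 2 * pi * 0.01 * 0.2 * tp$q_in
  gain <- mdot_cp * (tp$T_bulk[length(tp$T_bulk)] - tp$T_in)
  expect_equal(wall_in / gain, 1, tolerance = 0.01)
  # zero wall flux leaves the field isothermal
  tp0 <- solve_temperature(fl, blood(), q_in = 0)
  expect_equal(range(tp0$T), c(310.15, 310.15))
})

test_that("bulk temperature is the mass-flow-weighted mean", {
  fl <- flow_035(); tp <- temp_035()
  # uniform temperature: bulk equals it
  tpu <- tp; tpu$T[] <- 300
  expect_equal(bulk_temperature(tpu, fl, 0.1), 300)
  # plug flow with linear T(r): closed form T0 + 2 beta R / 3
  fake <- fl
  fake$v <- matrix(1, nrow(fl$v), ncol(fl$v))
  ft <- tp
  R <- 0.01; beta <- 50
  ft$T <- matrix(rep(300 + beta * fl$eta * R, each = nrow(tp$T)),
                 nrow = nrow(tp$T))
  got <- bulk_temperature(ft, fake, 0.1)
  expect_equal(got, 300 + 2 * beta * R / 3, tolerance = 1e-3)
  # quadrature reaches the closed form to 1e-6 relative on a fine grid:
  # v = 1 - x^2, T = 300 + 50 x^2 gives T_bulk = 950/3
  eta <- radial_grid(1, 2048)$r
  fl2 <- structure(list(z = c(0, 1), eta = eta, Rz = c(0.01, 0.01),
                        v = rbind(1 - eta^2, 1 - eta^2)),
                   class = "steady_flow_field")
  tp2 <- structure(list(T = rbind(300 + 50 * eta^2, 300 + 50 * eta^2)),
                   class = "temperature_field")
  expect_equal(bulk_temperature(tp2, fl2, 1), 950 / 3, tolerance = 1e-6)
  # and agrees with a dense trapezoid oracle on real solver output
  j <- graftherm:::station_index(fl$z, 0.1)
  r <- fl$eta * 0.01
  rr <- seq(0, 0.01, length.out = 20001)
  vv <- approx(r, fl$v[j, ], rr)$y
  TTT <- approx(r, tp$T[j, ], rr)$y
  oracle_dT <- sum(vv * TTT * rr) / sum(vv * rr) - 310.15
  expect_equal(bulk_temperature(tp, fl, 0.1) - 310.15, oracle_dT,
               tolerance = 0.02)
  expect_error(bulk_temperature(tp, fl, 0.5), "outside")
})

test_that("h arithmetic and degenerate cases", {
  expect_equal(heat_transfer_coefficient(311.15, 310.15, 200), 200)
  expect_equal(heat_transfer_coefficient(310.20, 310.15, 200), 4000)
  expect_error(heat_transfer_coefficient(310.15, 310.15, 200), "undefined")
})

test_that("h(z) decreases downstream and increases with velocity", {
  hp35 <- steady_h_profile(temp_035())
  expect_true(all(diff(hp35$h_mean) < 0))
  fl65 <- solve_steady_flow(aorta(), blood(), 0.65)
  hp65 <- steady_h_profile(solve_temperature(fl65, blood()))
  expect_true(all(hp65$h_mean > hp35$h_mean))
})

test_that("two-term power law fits with fixed exponents", {
  z <- seq(0.01, 0.2, by = 0.01)
  h1 <- list(z = z, h_mean = 2 * z^-0.5)
  f1 <- fit_h_powerlaw(h1)
  expect_equal(f1$fit$a, 2, tolerance = 1e-10)
  expect_equal(f1$fit$c, 0, tolerance = 1e-10)
  expect_equal(f1$fit$r_squared, 1)
  h2 <- list(z = z, h_mean = z^-0.5 + 3 * z^-1.5)
  f2 <- fit_h_powerlaw(h2)
  expect_equal(unname(c(f2$fit$a, f2$fit$c)), c(1, 3), tolerance = 1e-10)
  expect_error(fit_h_powerlaw(list(z = z[1:3], h_mean = z[1:3])),
               "at least 4")
  # transitional-regime solver output is captured with high R-squared
  fit35 <- fit_h_powerlaw(steady_h_profile(temp_035()))
  expect_gte(fit35$fit$r_squared, 0.96)
})

test_that("a tapering radius raises the heat-transfer coefficient", {
  tap <- vessel_geometry(0.01, 0.2, taper_rate = -0.01)  # 1 cm -> 0.8 cm
  flt <- solve_steady_flow(tap, blood(), 0.35)
  hpt <- steady_h_profile(solve_temperature(flt, blood()))
  hp0 <- steady_h_profile(temp_035())
  expect_true(all(hpt$h_mean[-1] > hp0$h_mean[-1]))
})

test_that("pulsatility change bookkeeping", {
  z <- seq(0.01, 0.2, by = 0.01)
  a <- structure(list(z = z, h_mean = rep(100, 20)), class = "h_profile")
  expect_equal(pulsatility_change(a, a)$mean, 0)
  expect_equal(pulsatility_change(a, a)$sd, 0)
  b <- a; b$h_mean <- 1.07 * a$h_mean
  pc <- pulsatility_change(b, a)
  expect_equal(pc$mean, 7, tolerance = 1e-12)
  expect_equal(pc$sd, 0)
  cshort <- a; cshort$z <- z + 0.001
  expect_error(pulsatility_change(cshort, a), "station")
})
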