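test_that("model construction places the three shells and the sensor", {
  m <- graft_coarse()
  expect_equal(m$rf[1], 0.010)
  expect_true(any(abs(m$rf - 0.01105) < 1e-12))
  expect_equal(m$rf[length(m$rf)], 0.020)
  expect_equal(levels(m$layer),
               c("wall_in", "sensor_layer", "wall_out", "infection_layer",
                 "tissue"))
  # sensor cells exist, carry the sensor conductivity, and sit mid-wall
  expect_gt(sum(m$sensor_mask), 0)
  expect_true(all(m$K[m$sensor_mask] == m$materials[["sensor"]]))
  expect_true(all(m$K[m$layer == "tissue", , ] ==
                    m$materials[["aortic_tissue"]]))
  expect_error(graft_model(inner_radius = 0.02, graft_outer_radius = 0.011),
               "inner_radius <")
  expect_error(material_library(PDMS = 0.5), "PDMS < PTFE")
})

test_that("zero sources leave the model in uniform equilibrium", {
  m <- graft_coarse()
  sol <- solve_conduction(m, thermal_bcs(1200), Q = 0,
                          factor = graft_factor_at(1200))
  expect_equal(max(abs(sol$dT)), 0)
  expect_equal(sensor_flux(sol)$q_avg, 0)
  expect_equal(max_temperature_rise(sol)$dT_sensor, 0)
  # zero-radius infection has no source cells
  expect_equal(sum(graftherm:::infection_source(m, 2000, 0, 0)), 0)
})

test_that("discrete energy conservation and the maximum principle hold", {
  m <- graft_coarse()
  sol <- solve_conduction(m, thermal_bcs(1200), Q = 2000,
                          infection_radius = 0.004, d = 0,
                          factor = graft_factor_at(1200))
  eb <- energy_balance(sol)
  expect_lt(eb$relative_error, 1e-8)
  expect_gt(eb$generated, 0)
  # with a positive source no temperature drops below body temperature
  expect_gte(min(sol$dT), -1e-12)
  expect_gt(max_temperature_rise(sol)$dT_global,
            max_temperature_rise(sol)$dT_sensor - 1e-15)
})

test_that("sensor flux is linear in the source and convention-consistent", {
  m <- graft_coarse()
  fac <- graft_factor_at(1200)
  s1 <- solve_conduction(m, thermal_bcs(1200), Q = 2000,
                         infection_radius = 0.004, factor = fac)
  s2 <- solve_conduction(m, thermal_bcs(1200), Q = 4000,
                         infection_radius = 0.004, factor = fac)
  f1 <- sensor_flux(s1); f2 <- sensor_flux(s2)
  expect_equal(f2$q_avg, 2 * f1$q_avg, tolerance = 1e-10)
  expect_equal(2 * max_temperature_rise(s1)$dT_sensor,
               max_temperature_rise(s2)$dT_sensor, tolerance = 1e-10)
  # the steady sensor sheet stores no heat: the lumen-oriented signed
  # difference is far smaller than the mean through-flux
  expect_lt(abs(sensor_flux(s1, "signed_difference")$q_avg),
            0.1 * abs(f1$q_avg))
})

test_that("arc-length offset maps to angle with wrap-around", {
  m <- graft_coarse()
  b0 <- graftherm:::infection_source(m, 2000, 0.003, 0)
  bwrap <- graftherm:::infection_source(m, 2000, 0.003,
                                        2 * pi * m$graft_outer_radius)
  expect_equal(b0, bwrap)
  # offset by half the circumference lands opposite the sensor
  bhalf <- graftherm:::infection_source(m, 2000, 0.003,
                                        pi * m$graft_outer_radius)
  expect_gt(sum(bhalf), 0)
  expect_equal(sum(b0 > 0), sum(bhalf > 0))
  expect_error(graftherm:::infection_source(m, 2000, 0.04, 0),
               "beyond the axial domain")
})

test_that("axisymmetric ring source matches the annulus resistance network", {
  # pure-PDMS wall (vanishing sensor footprint), ring sheet on the
  # wall-tissue interface over the whole surface, long domain: the mid-plane
  # partition between the lumen and tissue branches follows the closed-form
  # series/parallel log-annulus network
  mats <- material_library()
  m <- graft_model(sensor_footprint = 1e-9, axial_length = 0.12,
                   n_theta = 8, n_z = 48, nr_wall = 3, nr_sensor = 3,
                   nr_infection = 2, nr_tissue = 10)
  h <- 1000
  bc <- thermal_bcs(h_inner = h)
  # uniform interface sheet: reuse the patch machinery with full masks
  m_full <- m
  m_full$foot_th <- rep(TRUE, m$n_theta)
  m_full$foot_z <- rep(TRUE, m$n_z)
  b <- graftherm:::patch_source(m_full, 1)
  sol <- solve_conduction(m, bc, Q = 0, extra_source = b)
  x <- array(sol$dT, dim = c(m$nr, m$n_theta, m$n_z))
  kmid <- m$n_z %/% 2
  inward <- sum(sol$mats$Gin[, kmid] * x[1, , kmid])
  input <- sum(array(b, dim = dim(x))[, , kmid])
  r0 <- m$inner_radius; rg <- m$graft_outer_radius
  rout <- m$tissue_outer_radius
  kp <- mats[["PDMS"]]; kt <- mats[["aortic_tissue"]]
  R_in <- log(rg / r0) / (2 * pi * kp) + 1 / (2 * pi * r0 * h)
  R_out <- log(rout / rg) / (2 * pi * kt)
  frac_1d <- R_out / (R_in + R_out)
  expect_equal(inward / input, frac_1d, tolerance = 0.01)
})

test_that("detectability is monotone in source, radius and distance", {
  m <- graft_coarse()
  sw <- detectability_sweep(m, h_grid = 1200, Q_grid = c(2000, 10000),
                            radius_grid = c(0.002, 0.004),
                            d_grid = c(0, 0.002, 0.004, 0.006))
  expect_s3_class(sw, "sweep_result")
  expect_false(anyNA(sw$q_sensor_W_m2))
  expect_identical(sw$detectable, sw$q_sensor_W_m2 >= 0.41)
  for (Q in unique(sw$Q_W_m3)) for (r in unique(sw$radius_mm)) {
    sub <- sw[sw$Q_W_m3 == Q & sw$radius_mm == r, ]
    expect_true(all(diff(sub$q_sensor_W_m2[order(sub$d_mm)]) <= 1e-12))
  }
  for (d in unique(sw$d_mm)) {
    sub <- sw[sw$d_mm == d, ]
    agg <- stats::aggregate(q_sensor_W_m2 ~ radius_mm, sub, mean)
    expect_true(all(diff(agg$q_sensor_W_m2[order(agg$radius_mm)]) > 0))
    agg2 <- stats::aggregate(q_sensor_W_m2 ~ Q_W_m3, sub, mean)
    expect_true(all(diff(agg2$q_sensor_W_m2[order(agg2$Q_W_m3)]) > 0))
  }
  expect_error(detectability_sweep(m, h_grid = numeric(0)), "non-empty")
})

test_that("efficiency rises with conductivity, h, and thinner walls", {
  mk <- function(...) graft_model(n_theta = 48, n_z = 30, nr_wall = 2,
                                  nr_sensor = 2, nr_infection = 1,
                                  nr_tissue = 6, ...)
  e_pdms <- heat_transfer_efficiency(mk(), thermal_bcs(600))
  e_dacron <- heat_transfer_efficiency(mk(wall_material = "Dacron"),
                                       thermal_bcs(600))
  expect_gt(e_dacron, e_pdms)
  e_thin <- heat_transfer_efficiency(mk(graft_outer_radius = 0.0108),
                                     thermal_bcs(600))
  expect_gt(e_thin, e_pdms)
  m <- mk()
  eff <- vapply(c(200, 600, 1200), function(h)
    heat_transfer_efficiency(m, thermal_bcs(h)), numeric(1))
  expect_true(all(diff(eff) > 0))
  # the 200 -> 600 step is the largest
  expect_gt(eff[2] - eff[1], eff[3] - eff[2])
  expect_error(heat_transfer_efficiency(m, thermal_bcs(600),
                                        applied_flux = 0), "applied_flux")
})
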