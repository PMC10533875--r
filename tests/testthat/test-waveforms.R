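test_that("synthetic aortic waveform hits its amplitude contract", {
  w <- synth_aortic_waveform(heart_rate = 60, systolic = 16000,
                             diastolic = 10700, seed = 3)
  expect_equal(w$period, 1.0)
  expect_equal(max(w$pressures), 16000, tolerance = 0.01)
  expect_equal(min(w$pressures), 10700, tolerance = 0.01)
  # determinism and seed sensitivity
  w2 <- synth_aortic_waveform(heart_rate = 60, systolic = 16000,
                              diastolic = 10700, seed = 3)
  expect_identical(w$pressures, w2$pressures)
  w3 <- synth_aortic_waveform(heart_rate = 60, systolic = 16000,
                              diastolic = 10700, seed = 4)
  expect_false(identical(w$pressures, w3$pressures))
  expect_equal(synth_aortic_waveform(heart_rate = 75)$period, 60 / 75)
  expect_error(synth_aortic_waveform(systolic = 9000, diastolic = 10000),
               "systolic")
  # synthesis must not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(synth_aortic_waveform(seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("CSV round trip and resampling behave", {
  w <- synth_aortic_waveform(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  w2 <- load_waveform_csv(path, n_samples = length(w$times))
  expect_equal(w2$period, w$period, tolerance = 1e-9)
  expect_equal(w2$pressures, w$pressures, tolerance = 1e-6)
  # non-uniform grid is linearly interpolated; compare against approx oracle
  tt <- sort(c(0, runif(40, 0, 2), 2))
  pp <- 12000 + 2000 * sin(pi * tt)
  df <- data.frame(time_s = tt, pressure_pa = pp)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  wu <- load_waveform_csv(path2, n_samples = 64)
  probes <- c(0.3, 0.7, 1.1, 1.5, 1.9)
  oracle <- approx(tt, pp, xout = probes)$y
  got <- approx(wu$times, wu$pressures, xout = probes)$y
  expect_equal(got, oracle, tolerance = 1e-2)
  # degenerate files
  small <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[1:2, ], small, row.names = FALSE)
  expect_error(load_waveform_csv(small), "at least 8 rows")
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 1, 0.5, 2, 3, 4, 5, 6),
                       pressure_pa = 1:8), bad, row.names = FALSE)
  expect_error(load_waveform_csv(bad), "non-monotone times at row 3")
})

test_that("spectral time derivative is exact on band-limited signals", {
  tt <- seq(0, 1, length.out = 65)[1:64]
  wc <- pressure_waveform(tt, rep(1.2e4, 64), 1)
  expect_equal(waveform_time_derivative(wc), rep(0, 64))
  ws <- pressure_waveform(tt, 1000 * sin(2 * pi * tt), 1)
  d <- waveform_time_derivative(ws)
  expect_equal(d, 2 * pi * 1000 * cos(2 * pi * tt), tolerance = 0.005)
  w <- synth_aortic_waveform(seed = 2)
  dw <- waveform_time_derivative(w)
  expect_lt(abs(mean(dw) * w$period), 1e-6 * max(abs(w$pressures)))
})

test_that("forcing terms respect amplitude, phase and retarded time", {
  s0 <- source_term("constant_zero")
  expect_equal(evaluate_source(s0, c(0, 0.3, 2), 0.1), c(0, 0, 0))
  s <- source_term("sinusoidal", amplitude = 100, frequency = 1,
                   c_wave = 8.8)
  expect_equal(evaluate_source(s, t = 0.1 / 8.8, z = 0.1), 0)
  tt <- seq(0, 1, by = 1e-4)
  expect_equal(max(evaluate_source(s, tt, 0)), 100, tolerance = 1e-6)
  sdiv <- source_term("sinusoidal", amplitude = 100, frequency = 1,
                      c_wave = 8.8, convention = "divided_by_c")
  expect_equal(max(evaluate_source(sdiv, tt, 0)), 100 / 8.8,
               tolerance = 1e-6)
  # mean over one period is zero (sinusoidal and waveform kinds)
  expect_lt(abs(mean(evaluate_source(s, tt[-length(tt)], 0))), 1e-10)
  w <- synth_aortic_waveform(seed = 1)
  sw <- source_term("waveform", waveform = w, c_wave = 8.8)
  expect_lt(abs(mean(evaluate_source(sw, tt[-length(tt)], 0))),
            1e-4 * max(abs(evaluate_source(sw, tt, 0))))
  # retarded-time identity s(t, z) = s(t - z/c, 0)
  for (z in c(0.05, 0.13)) {
    t1 <- seq(z / 8.8, z / 8.8 + 1, length.out = 11)
    expect_equal(evaluate_source(sw, t1, z),
                 evaluate_source(sw, t1 - z / 8.8, 0), tolerance = 1e-12)
    expect_equal(evaluate_source(s, t1, z),
                 evaluate_source(s, t1 - z / 8.8, 0), tolerance = 1e-12)
  }
})
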