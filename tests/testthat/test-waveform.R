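test_that("reading a waveform converts declared clinical units to SI", {
  path <- withr::local_tempfile(fileext = ".csv")
  t_ms <- seq(0, 950, by = 50)  # 20 samples over 1 s, open grid
  v_cms <- 10 + 5 * sin(2 * pi * t_ms / 1000)
  writeLines(c("# duplex trace", "time,value",
               paste(t_ms, v_cms, sep = ",")), path)
  w <- read_waveform(path, kind = "velocity", time_unit = "ms",
                     value_unit = "cm/s")
  expect_equal(w$t, t_ms / 1000)
  expect_equal(w$v, v_cms / 100)
  expect_equal(w$period, 1)
  expect_identical(w$kind, "velocity")
})

test_that("short, malformed and non-periodic traces are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,value", "0,1", "0.1,2", "0.2,1"), path)
  expect_error(read_waveform(path, kind = "flow"), "at least 16 samples")

  writeLines(c("time,value",
               paste(seq(0, 0.19, 0.01), "x", sep = ",")), path)
  expect_error(read_waveform(path, kind = "flow"), "line 2")

  # closed grid whose endpoints disagree, period claimed explicitly
  t <- seq(0, 1, length.out = 21)
  writeLines(c("time,value", paste(t, 2 + t, sep = ",")), path)
  expect_error(read_waveform(path, kind = "flow", period = 1),
               "non-periodic")
})

test_that("a constant zero trace is a valid waveform", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,value", paste(seq(0, 1, 0.05), 0, sep = ",")), path)
  w <- read_waveform(path, kind = "flow")
  expect_true(all(w$v == 0))
  expect_equal(w$period, 1)
})

test_that("velocity-to-flow follows the flat and parabolic profile conventions", {
  n <- 32
  t <- (seq_len(n) - 1) / n
  w0 <- waveform(t, rep(0, n), period = 1, kind = "velocity")
  for (prof in c("flat", "parabolic")) {
    expect_true(all(velocity_to_flow(w0, 0.002, prof)$v == 0))
  }
  w <- waveform(t, rep(0.1, n), period = 1, kind = "velocity")
  Q_flat <- velocity_to_flow(w, 0.002, "flat")
  expect_equal(Q_flat$v[1], 0.1 * pi * 0.002^2, tolerance = 1e-12)
  expect_equal(Q_flat$v[1], 1.2566e-6, tolerance = 1e-4)
  Q_par <- velocity_to_flow(w, 0.002, "parabolic")
  expect_equal(Q_par$v, Q_flat$v / 2)
  expect_identical(Q_flat$kind, "flow")
  expect_error(velocity_to_flow(w, -1), "radius")
  expect_error(velocity_to_flow(Q_flat, 0.002), "velocity")
})

test_that("velocity-to-flow is linear in v and quadratic in r", {
  n <- 32
  t <- (seq_len(n) - 1) / n
  v <- 0.1 + 0.05 * sin(2 * pi * t)
  w <- waveform(t, v, period = 1, kind = "velocity")
  w3 <- waveform(t, 3 * v, period = 1, kind = "velocity")
  base <- velocity_to_flow(w, 0.002)$v
  expect_equal(velocity_to_flow(w3, 0.002)$v, 3 * base, tolerance = 1e-14)
  expect_equal(velocity_to_flow(w, 0.004)$v, 4 * base, tolerance = 1e-14)
})

test_that("periodic resampling is exact on its own grid and for band-limited input", {
  w <- sine_flow(n = 64, mean = 2, amp = 1)
  same <- resample_periodic(w, 64)
  expect_equal(same$v, w$v, tolerance = 1e-12)

  up <- resample_periodic(w, 256)
  expect_equal(up$v, 2 + sin(2 * pi * up$t), tolerance = 1e-6)

  const <- resample_periodic(constant_flow(3, n = 20), 100)
  expect_true(all(abs(const$v - 3) < 1e-12))

  expect_error(resample_periodic(w, 8), ">= 16")
})

test_that("resampling preserves the cycle mean and respects min/max", {
  set.seed(7)
  for (n_in in c(32, 33, 47, 64)) {  # even (Fourier) and odd (spline) paths
    t <- (seq_len(n_in) - 1) / n_in
    v <- 1 + 0.5 * sin(2 * pi * t) + 0.2 * cos(6 * pi * t + 1)
    w <- waveform(t, v, period = 1, kind = "flow")
    r <- resample_periodic(w, 128)
    expect_lt(abs(cycle_mean(r) - cycle_mean(w)) / abs(cycle_mean(w)), 1e-3)
    expect_gt(min(r$v), min(w$v) - 0.05 * diff(range(w$v)))
    expect_lt(max(r$v), max(w$v) + 0.05 * diff(range(w$v)))
  }
})

test_that("waveform construction enforces its invariants", {
  t <- (0:31) / 32
  expect_error(waveform(t, seq_len(31), period = 1, kind = "flow"),
               "equal length")
  expect_error(waveform(rev(t), rnorm(32), period = 1, kind = "flow"),
               "strictly increasing")
  expect_error(waveform(t + 0.5, rnorm(32), period = 1, kind = "flow"),
               "start at t = 0")
  # closed grid with matching endpoints drops the duplicate
  tc <- seq(0, 1, length.out = 33)
  w <- waveform(tc, sin(2 * pi * tc), period = 1, kind = "flow")
  expect_length(w$t, 32)
})
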