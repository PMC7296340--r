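test_that("effective viscosity recovers its limits and the Newtonian value", {
  cy <- viscosity_model("carreau_yasuda")
  expect_identical(effective_viscosity(0, cy), cy$mu0)
  expect_equal(effective_viscosity(1e9, cy), cy$mu_inf, tolerance = 1e-6)

  nw <- viscosity_model("newtonian", mu = shear_as_pascal(0.035, "dyn/cm2"))
  expect_equal(nw$mu, 0.0035, tolerance = 1e-15)
  expect_equal(effective_viscosity(c(0, 1, 1e4), nw), rep(0.0035, 3),
               tolerance = 1e-15)
})

test_that("Carreau-Yasuda viscosity is nonincreasing in shear rate", {
  set.seed(5)
  gd <- sort(c(0, 10^seq(-3, 6, length.out = 60)))
  for (i in 1:25) {
    mu_inf <- runif(1, 1e-3, 5e-3)
    m <- viscosity_model("carreau_yasuda", mu0 = mu_inf * runif(1, 1, 100),
                         mu_inf = mu_inf, lambda = runif(1, 0.1, 20),
                         a = runif(1, 0.2, 2), n = runif(1, 0.05, 0.99))
    expect_true(all(diff(effective_viscosity(gd, m)) <= 1e-15))
  }
})

test_that("Windkessel pressure matches steady-state, decay and phasor forms", {
  R <- 1.5e8; C <- 8e-9; T <- 1  # RC = 1.2 s
  p <- windkessel_params(R, C)

  # steady state: P -> Q*R after 10 time constants
  Qc <- constant_flow(5e-6, period = T)
  pw <- windkessel_pressure(Qc, p, P0 = 0, n_cycles = ceiling(10 * R * C / T))
  expect_equal(pw$p[length(pw$p)], 5e-6 * R, tolerance = 1e-3)

  # zero inflow: pure exponential decay
  pw0 <- windkessel_pressure(constant_flow(0, period = T), p, P0 = 1e4,
                             n_cycles = 1)
  expect_equal(pw0$p, 1e4 * exp(-pw0$t / (R * C)), tolerance = 1e-6)

  # single harmonic: amplitude ratio R/sqrt(1+(wRC)^2), phase lag atan(wRC)
  Q <- sine_flow(n = 256, mean = 5e-6, amp = 2e-6, period = T)
  pw1 <- windkessel_pressure(Q, p, P0 = 0,
                             n_cycles = ceiling(10 * R * C / T) + 5)
  om <- 2 * pi / T
  exact <- 5e-6 * R + 2e-6 * R / sqrt(1 + (om * R * C)^2) *
    sin(om * pw1$t - atan(om * R * C))
  expect_lt(sqrt(sum((pw1$p - exact)^2) / sum(exact^2)), 1e-4)
})

test_that("Windkessel tuning recovers resistance and compliance", {
  # constant inflow, zero pulse target: R = P/Q exactly, any C valid
  tuned0 <- tune_windkessel(constant_flow(1e-6), 12000, 0)
  expect_identical(tuned0$R, 1.2e10)

  # round trip from a known parameter pair
  R_true <- 1.8e8; C_true <- 6e-9
  Q <- demo_inflow()
  ss <- windkessel_pressure(Q, windkessel_params(R_true, C_true),
                            P0 = cycle_mean(Q) * R_true, n_cycles = 60)
  tuned <- tune_windkessel(Q, mean(ss$p), max(ss$p) - min(ss$p))
  expect_equal(tuned$R, R_true, tolerance = 1e-9)
  expect_equal(tuned$C, C_true, tolerance = 0.01)

  expect_error(tune_windkessel(Q, 12000, 30000), "target_pulse_P")
})

test_that("quasi-steady wall shear matches the Poiseuille closed form", {
  g <- tube_graft(radius = 2e-3)
  nw <- viscosity_model("newtonian", mu = 0.0035)

  w0 <- wall_shear_series(g, constant_flow(0), nw, n_time = 32)
  expect_true(all(w0$tau == 0))

  w <- wall_shear_series(g, constant_flow(1e-6), nw, n_time = 32)
  tau_exact <- 4 * 0.0035 * 1e-6 / (pi * (2e-3)^3)
  expect_equal(as.vector(w$tau), rep(tau_exact, length(w$tau)),
               tolerance = 1e-12)
  expect_equal(tau_exact, 0.557, tolerance = 1e-3)

  # doubling the radius scales tau by 1/8
  g2 <- tube_graft(radius = 4e-3)
  w2 <- wall_shear_series(g2, constant_flow(1e-6), nw, n_time = 32)
  expect_equal(as.vector(w2$tau), rep(tau_exact / 8, length(w2$tau)),
               tolerance = 1e-12)

  # reverse flow flips the sign
  wneg <- wall_shear_series(g, constant_flow(-1e-6), nw, n_time = 32)
  expect_true(all(wneg$tau < 0))
})

test_that("iterative consistency equals approximate exactly for Newtonian", {
  g <- tube_graft()
  nw <- viscosity_model("newtonian", mu = 0.004)
  Q <- demo_inflow()
  wa <- wall_shear_series(g, Q, nw, "approximate", n_time = 64)
  wi <- wall_shear_series(g, Q, nw, "iterative", n_time = 64)
  expect_identical(wa$tau, wi$tau)
})

test_that("iterative Carreau-Yasuda shear solves the wall consistency fixed point", {
  g <- tube_graft(radius = 2.5e-3)
  cy <- viscosity_model("carreau_yasuda")
  Q <- constant_flow(2e-6)
  wa <- wall_shear_series(g, Q, cy, "approximate", n_time = 32)
  wi <- wall_shear_series(g, Q, cy, "iterative", n_time = 32)
  # shear thinning: the corrected wall shear rate exceeds the nominal one
  expect_true(all(wi$tau >= wa$tau))
  # independent oracle: solve the Weissenberg-Rabinowitsch-Mooney equation
  # gd = gd_nom * (3 + 1/n_loc(gd))/4 by bracketed root finding
  gd_nom <- 4 * 2e-6 / (pi * 2.5e-3^3)
  n_loc <- function(gd) graftnih:::local_flow_exponent(gd, cy)
  gd_star <- stats::uniroot(
    function(gd) gd - gd_nom * (3 + 1 / n_loc(gd)) / 4,
    c(gd_nom, 2 * gd_nom), tol = 1e-12)$root
  expect_equal(wi$tau[1, 1], effective_viscosity(gd_star, cy) * gd_star,
               tolerance = 1e-7)
})

test_that("WSS fields round-trip through CSV and ragged grids are rejected", {
  g <- tube_graft()
  w <- wall_shear_series(g, demo_inflow(), n_time = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  export_wss_field(w, path)
  w2 <- import_wss_field(path)
  expect_identical(w2$tau, w$tau)
  expect_identical(w2$stations, w$stations)
  expect_identical(w2$period, w$period)

  lines <- readLines(path)
  writeLines(lines[-10], path)  # drop one (station, time) cell
  expect_error(import_wss_field(path), "ragged")

  # single-station field with 64 time samples is valid
  t <- (0:63) / 64
  f1 <- wss_field(0.05, t, matrix(sin(2 * pi * t), 1), period = 1)
  path1 <- withr::local_tempfile(fileext = ".csv")
  export_wss_field(f1, path1)
  f2 <- import_wss_field(path1)
  expect_identical(dim(f2$tau), c(1L, 64L))
})
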