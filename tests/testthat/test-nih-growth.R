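test_that("the empty-tissue state is absorbing and Hill identities hold", {
  p <- nih_params("demo-2020")
  d <- nih_rhs(c(N = 0, G = 0, S = 0, C = 0, A = 0), stimulus = 0.3, p)
  expect_identical(unname(d[c("S", "C", "A")]), c(0, 0, 0))

  # at stimulus = theta the low-shear activation is exactly 1/2, any h
  for (h in c(1, 2, 8)) {
    ph <- nih_params("demo-2020", h = h)
    d0 <- nih_rhs(c(0, 0, 0, 0, 0), stimulus = ph[["theta"]], ph)
    expect_equal(unname(d0["G"]), ph[["k_G"]] / 2, tolerance = 1e-14)
  }

  # high shear: activation ~ 0, so G decays and S cannot grow
  dhi <- nih_rhs(c(N = 1, G = 0, S = 0.5, C = 0, A = 0), stimulus = 1e6, p)
  expect_lt(unname(dhi["G"]), 1e-9)
  expect_lte(unname(dhi["S"]), 0)
})

test_that("integration matches a high-accuracy reference and closed forms", {
  p <- nih_params("demo-2020")
  # logistic-like SMC growth at zero stimulus with G at equilibrium k_G/d_G
  s0 <- nih_state(1, G = p[["k_G"]] / p[["d_G"]], S = 1e-3)
  fast <- integrate_growth(s0, 0, p, 200, rtol = 1e-8, atol = 1e-10)
  ref <- growth_trajectory(s0, 0, p, times = 200, rtol = 1e-12,
                           atol = 1e-14, method = "radau")[[1]]
  expect_equal(fast[1, ], ref[1, ], tolerance = 1e-6)

  # NO steady state: N -> k_N * sigma(x) / d_N
  x <- 0.7
  st <- growth_trajectory(nih_state(1), x, p, times = 300,
                          rtol = 1e-10, atol = 1e-12)[[1]]
  expect_equal(unname(st[1, "N"]),
               p[["k_N"]] * (x / (x + p[["tau_ref"]])) / p[["d_N"]],
               tolerance = 1e-6)

  # vanishing step leaves the state unchanged
  tiny <- integrate_growth(s0, 0.2, p, 1e-9, rtol = 1e-10, atol = 1e-14)
  expect_equal(tiny[1, c("G", "S")], unclass(s0)[1, c("G", "S")],
               tolerance = 1e-8)
})

test_that("the system preserves nonnegativity from any nonnegative state", {
  set.seed(17)
  for (i in 1:20) {
    p <- nih_params("demo-2020",
                    k_N = runif(1, 0, 2), d_N = runif(1, 0.1, 2),
                    k_G = runif(1, 0, 2), d_G = runif(1, 0.1, 2),
                    p_S = runif(1, 0, 0.5), d_S = runif(1, 0, 0.1),
                    alpha_N = runif(1, 0, 5), k_C = runif(1, 0, 0.2),
                    d_C = runif(1, 0.01, 0.5), theta = runif(1, 0.1, 1),
                    h = sample(1:6, 1), tau_ref = runif(1, 0.2, 2))
    s0 <- nih_state(3, N = runif(3, 0, 1), G = runif(3, 0, 1),
                    S = runif(3, 0, 1), C = runif(3, 0, 1),
                    A_intima = runif(3, 0, 1e-5))
    out <- integrate_growth(s0, runif(3, 0, 3), p, 100,
                            rtol = 1e-8, atol = 1e-10)
    expect_true(all(out >= -1e-9))
    expect_true(all(is.finite(out)))
    expect_true(all(out[, "S"] <= p[["S_max"]] * (1 + 1e-6)))
  }
})

test_that("intimal growth responds monotonically to the shear stimulus", {
  p <- nih_params("demo-2020")
  stimuli <- c(0.05, 0.15, 0.3, 0.45)  # all within the low-shear region
  A_final <- vapply(stimuli, function(x) {
    integrate_growth(nih_state(1), x, p, 360)[1, "A"]
  }, numeric(1))
  expect_true(all(diff(A_final) <= 1e-12))

  # and A itself never decreases along a trajectory
  traj <- growth_trajectory(nih_state(1), 0.2, p, times = seq(10, 360, 10))
  A_path <- vapply(traj, function(s) s[1, "A"], numeric(1))
  expect_true(all(diff(A_path) >= -1e-15))
})

test_that("growth parameters are recoverable from clean observations", {
  p_true <- nih_params("demo-2020")
  obs <- make_observation_set(p_true, c(0.1, 0.35), 240, n_times = 10,
                              noise_sd = 0)
  p0 <- nih_params("demo-2020", p_S = 0.12)
  fit <- fit_growth_params(obs$observations, p0, free = "p_S")
  expect_equal(fit$params[["p_S"]], p_true[["p_S"]], tolerance = 0.01)

  # zero free parameters: p0 returned untouched, residual reported
  none <- fit_growth_params(obs$observations, p0, free = character(0))
  expect_identical(unclass(none$params), unclass(p0))
  expect_gt(none$residual_norm, 0)

  expect_error(fit_growth_params(obs$observations[1, ], p0,
                                 free = c("p_S", "d_S")),
               "at least as many observations")
})

test_that("parameter constructor validates presets and overrides", {
  expect_error(nih_params("no-such-preset"), "unknown preset")
  expect_error(nih_params("demo-2020", bogus = 1), "unknown NIH parameter")
  expect_error(nih_params("demo-2020", h = 0.5), "'h'")
  expect_error(nih_params("demo-2020", theta = -1), "'theta'")
  p <- nih_params("demo-2020", p_S = 0.2)
  expect_identical(p[["p_S"]], 0.2)
})
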