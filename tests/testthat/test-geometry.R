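test_that("straight segments have zero curvature and tortuosity", {
  s <- seq(0, 0.1, length.out = 50)
  c3 <- centerline(cbind(s, 2 * s, -s))
  m <- frenet_metrics(c3)
  expect_true(all(m$curvature <= 1e-8))
  expect_true(all(m$planar_flag))
  expect_true(all(m$torsion == 0))
  expect_lt(tortuosity(c3), 1e-12)
})

test_that("circle and helix metrics match their closed forms", {
  R <- 0.05
  th <- seq(0, 1.5 * pi, length.out = 220)
  circ <- centerline(cbind(R * cos(th), R * sin(th), 0))
  m <- frenet_metrics(circ)
  expect_equal(m$curvature, rep(1 / R, 220), tolerance = 1e-3)
  expect_true(all(abs(m$torsion) < 1e-6))

  Rh <- 0.03; ch <- 0.01
  tt <- seq(0, 4 * pi, length.out = 250)
  hx <- centerline(cbind(Rh * cos(tt), Rh * sin(tt), ch * tt))
  mh <- frenet_metrics(hx)
  expect_equal(mh$curvature, rep(Rh / (Rh^2 + ch^2), 250), tolerance = 1e-3)
  expect_equal(mh$torsion, rep(ch / (Rh^2 + ch^2), 250), tolerance = 1e-3)
  expect_false(any(mh$planar_flag))
})

test_that("tortuosity is L/D - 1: semicircle value and rotation invariance", {
  th <- seq(0, pi, length.out = 400)
  semi <- centerline(cbind(cos(th), sin(th), 0) * 0.04)
  expect_equal(tortuosity(semi), pi / 2 - 1, tolerance = 1e-4)

  set.seed(11)
  Rm <- random_rotation()
  moved <- centerline(rigid_transform(semi$points, Rm, c(0.3, -0.1, 5)))
  expect_equal(tortuosity(moved), tortuosity(semi), tolerance = 1e-12)

  ring <- centerline(cbind(cos(seq(0, 2 * pi, length.out = 50)),
                           sin(seq(0, 2 * pi, length.out = 50)), 0))
  expect_error(tortuosity(ring), "coincident endpoints")
})

test_that("curvature and torsion are invariant under rigid-body motion", {
  set.seed(21)
  tt <- seq(0, 3 * pi, length.out = 150)
  hx <- centerline(cbind(0.02 * cos(tt), 0.02 * sin(tt), 0.008 * tt))
  m0 <- frenet_metrics(hx)
  for (i in 1:20) {
    Rm <- random_rotation()
    mi <- frenet_metrics(centerline(
      rigid_transform(hx$points, Rm, stats::rnorm(3))))
    expect_equal(mi$curvature, m0$curvature, tolerance = 1e-8)
    expect_equal(mi$torsion, m0$torsion, tolerance = 1e-6)
  }
})

test_that("the synthetic graft satisfies its construction contract", {
  # uniform tube: no caliber change, end stations labeled as anastomoses
  tube <- tube_graft(radius = 2e-3, length = 0.1, spacing = 0.01)
  expect_true(all(abs(tube$stations$A_base - pi * (2e-3)^2) < 1e-18))
  expect_identical(tube$stations$region[1], "proximal_anastomosis")
  expect_identical(tube$stations$region[nrow(tube$stations)],
                   "distal_anastomosis")
  expect_true("mid_graft" %in% tube$stations$region)

  # default demo spec: caliber is largest at the anastomoses
  g <- build_synthetic_graft()
  st <- g$stations
  expect_equal(max(st$A_base), pi * (3.5e-3)^2, tolerance = 1e-12)
  expect_true(st$A_base[1] > st$A_base[st$region == "mid_graft"][1])
  expect_true(all(st$A_intima == 0))
  expect_true(all(st$A_media > 0))

  # station counting
  fine <- build_synthetic_graft(graft_length = 0.4, spacing = 1e-3)
  expect_identical(nrow(fine$stations), 401L)

  expect_error(build_synthetic_graft(body_radius = -1), "body_radius")
  expect_error(build_synthetic_graft(graft_length = 0), "graft_length")
})

test_that("lumen radius follows the area relation", {
  g <- tube_graft(radius = 2e-3)
  expect_equal(lumen_radius(g), rep(2e-3, nrow(g$stations)), tolerance = 1e-12)

  g$stations$A_intima <- 0.75 * g$stations$A_base
  expect_equal(lumen_radius(g), rep(1e-3, nrow(g$stations)), tolerance = 1e-12)

  g$stations$A_base[1] <- 3.1416e-5
  g$stations$A_intima[1] <- 1.1416e-5
  expect_equal(lumen_radius(g, 1), sqrt(2e-5 / pi), tolerance = 1e-12)
  expect_equal(lumen_radius(g, 1), 2.523e-3, tolerance = 1e-4)
})

test_that("graft models round-trip through CSV", {
  g <- build_synthetic_graft(spacing = 0.02)
  g$stations$A_intima <- 0.1 * g$stations$A_base
  path <- withr::local_tempfile(fileext = ".csv")
  write_graft_csv(g, path)
  g2 <- read_graft_csv(path)
  expect_equal(g2$stations$A_base, g$stations$A_base, tolerance = 1e-9)
  expect_equal(g2$stations$A_intima, g$stations$A_intima, tolerance = 1e-9)
  expect_equal(g2$stations$A_media, g$stations$A_media, tolerance = 1e-9)
  expect_identical(g2$stations$region, g$stations$region)
})

test_that("graft model invariants are enforced", {
  g <- tube_graft()
  st <- g$stations
  st$A_intima[2] <- st$A_base[2]  # lumen closed
  expect_error(graft_model(g$centerline, st), "A_intima < A_base")
  st <- g$stations
  st$A_media[1] <- 0
  expect_error(graft_model(g$centerline, st), "media")
  st <- g$stations
  st$s[2] <- st$s[1]
  expect_error(graft_model(g$centerline, st), "strictly increasing")
  expect_error(centerline(matrix(rnorm(9), 3)), "at least 4")
})
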