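# Shared builders for test fixtures; everything is generated in code.

# uniform flow waveform mean + amp*sin(2*pi*t/T) on n samples over [0, T)
sine_flow <- function(n = 64, mean = 0, amp = 1, period = 1) {
  t <- period * (seq_len(n) - 1) / n
  waveform(t, mean + amp * sin(2 * pi * t / period), period = period,
           kind = "flow")
}

constant_flow <- function(value, n = 64, period = 1) {
  t <- period * (seq_len(n) - 1) / n
  waveform(t, rep(value, n), period = period, kind = "flow")
}

# uniform straight tube graft (single caliber everywhere)
tube_graft <- function(radius = 2e-3, length = 0.1, spacing = 0.01) {
  build_synthetic_graft(graft_length = length, body_radius = radius,
                        anastomosis_radius = radius, transition_length = 0.02,
                        spacing = spacing, bow_height = 0)
}

demo_graft <- function() build_synthetic_graft()

demo_inflow <- function() {
  make_waveform("femoral_triphasic", period = 1, mean_flow = 5e-6,
                pulsatility = 3)
}

demo_config <- function(stimulus = "holmes", months = 19,
                        growth_step_days = 7, ...) {
  simulation_config(demo_graft(), demo_inflow(),
                    stimulus_index = stimulus, months = months,
                    growth_step_days = growth_step_days, ...)
}

# random proper rotation matrix (det +1)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Qm <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Qm) < 0) Qm[, 1] <- -Qm[, 1]  # proper rotation only
  Qm
}

rigid_transform <- function(points, Rm, shift) {
  sweep(points %*% t(Rm), 2, shift, `+`)
}

# random wall shear field with sign changes, on a uniform cycle grid
random_wss_field <- function(n_st = 4, n_t = 48, period = 0.8) {
  t <- period * (seq_len(n_t) - 1) / n_t
  tau <- t(vapply(seq_len(n_st), function(i) {
    stats::rnorm(1, 0, 1) + stats::rnorm(1, 0, 1) * sin(2 * pi * t / period) +
      stats::rnorm(1, 0, 0.5) * cos(4 * pi * t / period)
  }, numeric(n_t)))
  wss_field(seq_len(n_st) * 0.01, t, tau, period)
}
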