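# Synthetic-data generators: physiologic-like inflow waveforms and noisy
# observation sets for parameter recovery. All generators are pure functions
# of their arguments (and seed); no hidden global state survives a call.

# triphasic femoral template: fixed shape built from three lobes (systolic
# forward, early-diastolic reverse, late-diastolic forward), truncated to a
# finite Fourier series. Returned on a fine grid, zero-mean, peak +1.
triphasic_template <- function(n_fine = 1024, harmonics = 8) {
  u <- (seq_len(n_fine) - 1) / n_fine
  f <- exp(-((u - 0.15) / 0.07)^2) -
    0.42 * exp(-((u - 0.38) / 0.10)^2) +
    0.12 * exp(-((u - 0.68) / 0.14)^2)
  co <- stats::fft(f) / n_fine
  co[1] <- 0                      # exact zero mean
  k <- seq_len(n_fine) - 1
  k_sym <- pmin(k, n_fine - k)
  co[k_sym > harmonics] <- 0
  s <- Re(stats::fft(co, inverse = TRUE))
  s / max(s)
}

#' Generate a synthetic inflow waveform
#'
#' Three kinds: `"femoral_triphasic"` (a fixed truncated-Fourier template
#' with a systolic peak, an early-diastolic reverse-flow phase and a small
#' late-diastolic forward phase — the reverse phase makes OSI > 0),
#' `"sinusoid"`, and `"constant"`. Shapes are scaled as
#' `Q(t) = mean_flow * (1 + pulsatility * s(t))` where `s` is the zero-mean
#' template normalized to peak +1, so the cycle mean is exactly `mean_flow`
#' and `pulsatility` is the ratio of the shape's peak excursion to the mean
#' (reverse flow appears once `pulsatility * |min s|` exceeds 1). The
#' generator is deterministic given its arguments.
#'
#' @param kind waveform family.
#' @param period cardiac cycle length, s (> 0).
#' @param mean_flow cycle-mean flow, m^3/s.
#' @param pulsatility peak excursion over mean (>= 0); ignored for
#'   `"constant"`.
#' @param harmonics harmonic count of the triphasic template (>= 1).
#' @param n samples per cycle.
#' @return a flow [waveform].
#' @examples
#' Q <- make_waveform("femoral_triphasic", mean_flow = 5e-6)
#' min(Q$v) < 0  # reverse-flow phase present at the default pulsatility
#' @export
make_waveform <- function(kind = c("femoral_triphasic", "sinusoid",
                                   "constant"),
                          period = 1, mean_flow = 5e-6, pulsatility = 3,
                          harmonics = 8, n = 256) {
  kind <- match.arg(kind)
  check_scalar(period, "period", positive = TRUE)
  check_scalar(mean_flow, "mean_flow")
  check_scalar(pulsatility, "pulsatility", nonnegative = TRUE)
  stop_if(harmonics < 1 || harmonics != round(harmonics),
          "'harmonics' must be an integer >= 1")
  stop_if(n < 16 || n != round(n), "'n' must be an integer >= 16")
  u <- (seq_len(n) - 1) / n
  s <- switch(kind,
    constant = numeric(n),
    sinusoid = sin(2 * pi * u),
    femoral_triphasic = {
      tpl <- triphasic_template(harmonics = min(harmonics, n %/% 2 - 1))
      out <- fft_resample(tpl, n)
      out / max(out)  # peak +1 on the delivered grid
    })
  waveform(u * period, mean_flow * (1 + pulsatility * s), period = period,
           kind = "flow")
}

#' Generate a noisy observation set for parameter recovery
#'
#' Simulates intimal-area trajectories of the growth model at constant
#' stimuli, applies multiplicative Gaussian noise, and returns the
#' observations together with the generating ground truth. Fully
#' reproducible from `seed`.
#'
#' @param params generating [nih_params].
#' @param stimuli constant shear stimuli, Pa.
#' @param horizon_days total observation window, days.
#' @param n_times observation times per stimulus (evenly spaced over
#'   `(0, horizon_days]`).
#' @param noise_sd relative standard deviation of the multiplicative noise
#'   (>= 0).
#' @param seed RNG seed.
#' @param state0 initial one-station state.
#' @return list with `observations` (data frame `stimulus,t_days,A_intima`),
#'   `truth` (the generating parameters), and `seed`.
#' @export
make_observation_set <- function(params, stimuli, horizon_days,
                                 n_times = 20, noise_sd = 0, seed = 1,
                                 state0 = nih_state(1)) {
  params <- validate_nih_params(params)
  stop_if(length(stimuli) < 1 || any(stimuli < 0),
          "'stimuli' must be nonnegative")
  check_scalar(horizon_days, "horizon_days", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  times <- seq(horizon_days / n_times, horizon_days, length.out = n_times)
  clean <- lapply(stimuli, function(x) {
    traj <- growth_trajectory(state0, x, params, times = times,
                              rtol = 1e-10, atol = 1e-12)
    vapply(traj, function(s) s[1, "A"], numeric(1))
  })
  obs <- data.frame(
    stimulus = rep(stimuli, each = n_times),
    t_days = rep(times, length(stimuli)),
    A_intima = unlist(clean, use.names = FALSE)
  )
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    obs$A_intima <- obs$A_intima *
      (1 + stats::rnorm(nrow(obs), sd = noise_sd))
  }
  list(observations = obs, truth = params, seed = seed)
}
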