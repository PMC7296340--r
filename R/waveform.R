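# Periodic inflow waveforms: the inlet boundary data of the framework.
# A waveform stores one cardiac cycle on the half-open grid [0, T); the value
# at T is the value at 0 by periodicity.

#' Construct a periodic waveform
#'
#' A waveform is one cardiac cycle of centerline velocity (m/s) or volumetric
#' flow (m^3/s) sampled at strictly increasing times. Internally the cycle is
#' stored on the half-open interval `[0, period)`; if `t` includes the closing
#' endpoint `t = period`, the first and last values must agree to within 1e-9
#' relative tolerance and the duplicate sample is dropped.
#'
#' @param t sample times in seconds, strictly increasing, `t[1] = 0`.
#' @param v sample values (velocity in m/s or flow in m^3/s).
#' @param period cycle period T in seconds.
#' @param kind `"flow"` or `"velocity"`.
#' @return an object of class `waveform` with fields `t`, `v`, `period`,
#'   `kind`.
#' @examples
#' w <- waveform(seq(0, 0.95, by = 0.05), sin(2 * pi * seq(0, 0.95, 0.05)),
#'               period = 1, kind = "flow")
#' cycle_mean(w)
#' @export
waveform <- function(t, v, period, kind = c("flow", "velocity")) {
  kind <- match.arg(kind)
  stop_if(!is.numeric(t) || !is.numeric(v) || length(t) != length(v),
          "'t' and 'v' must be numeric vectors of equal length")
  stop_if(anyNA(t) || anyNA(v) || any(!is.finite(t)) || any(!is.finite(v)),
          "waveform samples must be finite")
  check_scalar(period, "period", positive = TRUE)
  stop_if(any(diff(t) <= 0), "waveform time must be strictly increasing")
  stop_if(abs(t[1]) > 1e-12 * period, "waveform time must start at t = 0")
  n <- length(t)
  if (abs(t[n] - period) <= 1e-9 * period) {
    # closed grid: enforce periodicity and drop the duplicate endpoint
    vscale <- max(abs(v), .Machine$double.xmin)
    stop_if(abs(v[n] - v[1]) > 1e-9 * max(1, vscale),
            "waveform endpoints disagree: v(0) and v(T) must match within ",
            "1e-9 relative tolerance (non-periodic trace)")
    t <- t[-n]
    v <- v[-n]
    n <- n - 1L
  }
  stop_if(t[n] >= period, "waveform time samples must lie within [0, period]")
  stop_if(n < 16L, "waveform needs at least 16 samples per cycle")
  structure(list(t = t, v = v, period = period, kind = kind),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> kind=%s, %d samples, period %.4g s\n",
              x$kind, length(x$t), x$period))
  cat(sprintf("  cycle mean %.4g, range [%.4g, %.4g]\n",
              cycle_mean(x), min(x$v), max(x$v)))
  invisible(x)
}

#' Cycle mean of a periodic waveform
#'
#' Trapezoidal integral over one closed cycle (the wrap-around segment from
#' the last sample back to `v(0)` is included) divided by the period.
#'
#' @param w a [waveform].
#' @return the cycle-averaged value.
#' @export
cycle_mean <- function(w) {
  stopifnot(inherits(w, "waveform"))
  t <- c(w$t, w$period)
  v <- c(w$v, w$v[1])
  sum(diff(t) * (v[-length(v)] + v[-1]) / 2) / w$period
}

#' Read a waveform from a two-column CSV file
#'
#' The file must have a header `time,value`; lines starting with `#` are
#' comments. Units are declared by the caller and converted to SI on read.
#' The cycle period is taken from `period` when supplied; otherwise, if the
#' final value matches the first (1e-9 relative) the final time is treated as
#' the closing endpoint `T`, and failing that a uniform grid is assumed and
#' `T` extends one sample step past the last time.
#'
#' @param path CSV file path.
#' @param kind `"velocity"` or `"flow"`.
#' @param time_unit `"s"` or `"ms"`.
#' @param value_unit `"m/s"` or `"cm/s"` for velocity; `"m3/s"` or `"mL/s"`
#'   for flow.
#' @param period optional cycle period in the declared time unit.
#' @return a [waveform] in SI units.
#' @export
read_waveform <- function(path, kind = c("flow", "velocity"),
                          time_unit = c("s", "ms"),
                          value_unit = NULL, period = NULL) {
  kind <- match.arg(kind)
  time_unit <- match.arg(time_unit)
  if (is.null(value_unit)) {
    value_unit <- if (kind == "velocity") "m/s" else "m3/s"
  }
  unit_table <- if (kind == "velocity") .velocity_units else .flow_units
  stop_if(!value_unit %in% names(unit_table),
          sprintf("unknown %s unit '%s' (expected one of: %s)", kind,
                  value_unit, paste(names(unit_table), collapse = ", ")))
  stop_if(!file.exists(path), sprintf("waveform file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop(sprintf("malformed waveform CSV '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  stop_if(!all(c("time", "value") %in% names(raw)),
          sprintf("waveform CSV '%s' must have header 'time,value'", path))
  tv <- suppressWarnings(as.numeric(raw$time))
  vv <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(tv) | !is.finite(vv))
  stop_if(length(bad) > 0,
          sprintf("malformed waveform CSV '%s': non-numeric data at line %d",
                  path, bad[1] + 1L))
  stop_if(length(tv) < 16L,
          "waveform needs at least 16 samples per cycle")
  stop_if(any(diff(tv) <= 0),
          sprintf("non-monotone time in waveform CSV '%s' at line %d",
                  path, which(diff(tv) <= 0)[1] + 2L))
  t <- tv * .time_units[[time_unit]]
  v <- vv * unit_table[[value_unit]]
  n <- length(t)
  if (!is.null(period)) {
    period <- period * .time_units[[time_unit]]
  } else if (abs(v[n] - v[1]) <= 1e-9 * max(1, max(abs(v)))) {
    period <- t[n]
  } else if (is_uniform_grid(t, tol = 1e-6)) {
    period <- t[n] + (t[n] - t[n - 1])
  } else {
    stop("cannot infer the cycle period: supply 'period' explicitly for a ",
         "non-uniform trace whose endpoints differ", call. = FALSE)
  }
  waveform(t, v, period = period, kind = kind)
}

#' Write a waveform to CSV
#'
#' Inverse of [read_waveform()]; the closing endpoint `t = T` is written so
#' the trace round-trips with its period.
#'
#' @param w a [waveform].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time = fmt_num(c(w$t, w$period)),
                   value = fmt_num(c(w$v, w$v[1])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a velocity waveform to volumetric flow
#'
#' With the flat profile the measured velocity is taken as the cross-sectional
#' mean, `Q(t) = v(t) * pi * r^2`. With the parabolic (Poiseuille) profile the
#' measured velocity is taken as the centerline peak, whose cross-sectional
#' mean is half the peak, so `Q(t) = v(t)/2 * pi * r^2`.
#'
#' @param w a velocity [waveform].
#' @param radius lumen radius in m.
#' @param profile `"flat"` or `"parabolic"`.
#' @return a flow [waveform] (m^3/s).
#' @export
velocity_to_flow <- function(w, radius, profile = c("flat", "parabolic")) {
  profile <- match.arg(profile)
  stopifnot(inherits(w, "waveform"))
  stop_if(w$kind != "velocity", "'w' must be a velocity waveform")
  check_scalar(radius, "radius", positive = TRUE)
  scale <- pi * radius^2 * if (profile == "flat") 1 else 0.5
  waveform(w$t, w$v * scale, period = w$period, kind = "flow")
}

# Trigonometric (FFT) resampling of one real cycle onto n_out uniform samples.
# Exact for band-limited input; preserves the cycle mean exactly (DC copied).
fft_resample <- function(v, n_out) {
  n_in <- length(v)
  if (n_out == n_in) return(v)
  c_in <- stats::fft(v) / n_in
  c_out <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  c_out[1] <- c_in[1]
  k_pair <- min((n_in - 1) %/% 2, (n_out - 1) %/% 2)
  if (k_pair >= 1) {
    ks <- seq_len(k_pair)
    c_out[1 + ks] <- c_in[1 + ks]
    c_out[n_out + 1 - ks] <- c_in[n_in + 1 - ks]
  }
  if (n_in %% 2 == 0 && n_out > n_in) {
    # split the input Nyquist bin symmetrically when expanding
    ny <- n_in %/% 2
    c_out[1 + ny] <- c_in[1 + ny] / 2
    c_out[n_out + 1 - ny] <- Conj(c_in[1 + ny]) / 2
  }
  if (n_out < n_in && n_out %% 2 == 0) {
    # fold the +/- bins that alias onto the output Nyquist frequency
    ny <- n_out %/% 2
    c_out[1 + ny] <- c_in[1 + ny] + c_in[n_in + 1 - ny]
  }
  Re(stats::fft(c_out, inverse = TRUE))
}

#' Resample a waveform onto a uniform periodic grid
#'
#' Uses trigonometric (Fourier) interpolation when the input grid is uniform
#' with an even sample count, and a periodic cubic spline otherwise. The cycle
#' mean is preserved exactly under the Fourier path and to within 1e-3
#' relative under the spline path for `n` at least the input sample count.
#'
#' @param w a [waveform].
#' @param n number of output samples (>= 16), placed at `T*(0:(n-1))/n`.
#' @return a [waveform] on the uniform grid.
#' @export
resample_periodic <- function(w, n) {
  stopifnot(inherits(w, "waveform"))
  stop_if(!is.numeric(n) || length(n) != 1L || n != round(n) || n < 16,
          "'n' must be an integer >= 16")
  n <- as.integer(n)
  t_out <- w$period * (seq_len(n) - 1) / n
  n_in <- length(w$t)
  uniform <- is_uniform_grid(c(w$t, w$period))
  if (uniform && n_in %% 2 == 0) {
    if (abs(w$t[1]) < .Machine$double.eps && n == n_in) {
      v_out <- w$v
    } else {
      v_out <- fft_resample(w$v, n)
    }
  } else {
    f <- stats::splinefun(c(w$t, w$period), c(w$v, w$v[1]),
                          method = "periodic")
    v_out <- f(t_out)
  }
  waveform(t_out, v_out, period = w$period, kind = w$kind)
}
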