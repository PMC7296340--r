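# Reduced-order pulsatile hemodynamics: two-element Windkessel outlet
# models, Newtonian / Carreau-Yasuda viscosity, and quasi-steady wall shear
# time series along the graft. Externally computed 3D wall shear fields can
# be injected through the CSV import contract.

#' Two-element Windkessel parameters
#'
#' @param R peripheral resistance in Pa s/m^3 (> 0).
#' @param C compliance in m^3/Pa (> 0).
#' @return an object of class `windkessel_params`.
#' @export
windkessel_params <- function(R, C) {
  check_scalar(R, "R", positive = TRUE)
  check_scalar(C, "C", positive = TRUE)
  structure(list(R = R, C = C), class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf("<windkessel_params> R = %.4g Pa.s/m^3, C = %.4g m^3/Pa (RC = %.4g s)\n",
              x$R, x$C, x$R * x$C))
  invisible(x)
}

#' Blood viscosity model
#'
#' Either Newtonian with constant viscosity `mu`, or the shear-thinning
#' Carreau-Yasuda law
#' `mu(gd) = mu_inf + (mu0 - mu_inf) * (1 + (lambda*gd)^a)^((n-1)/a)`.
#' The Carreau-Yasuda defaults are standard literature values for whole
#' blood; the Newtonian default 0.0035 Pa s corresponds to the conventional
#' 0.035 dyn s/cm2.
#'
#' @param kind `"carreau_yasuda"` or `"newtonian"`.
#' @param mu Newtonian viscosity, Pa s.
#' @param mu0,mu_inf zero- and infinite-shear viscosities, Pa s
#'   (`mu0 >= mu_inf`).
#' @param lambda relaxation time, s.
#' @param a Yasuda exponent (> 0).
#' @param n power-law index (0 < n <= 1).
#' @return an object of class `viscosity_model`.
#' @export
viscosity_model <- function(kind = c("carreau_yasuda", "newtonian"),
                            mu = 0.0035, mu0 = 0.16, mu_inf = 0.0035,
                            lambda = 8.2, a = 0.64, n = 0.2128) {
  kind <- match.arg(kind)
  if (kind == "newtonian") {
    check_scalar(mu, "mu", positive = TRUE)
    return(structure(list(kind = kind, mu = mu), class = "viscosity_model"))
  }
  check_scalar(mu0, "mu0", positive = TRUE)
  check_scalar(mu_inf, "mu_inf", positive = TRUE)
  stop_if(mu0 < mu_inf, "'mu0' must be >= 'mu_inf'")
  check_scalar(lambda, "lambda", positive = TRUE)
  check_scalar(a, "a", positive = TRUE)
  check_scalar(n, "n", positive = TRUE)
  stop_if(n > 1, "'n' must satisfy 0 < n <= 1")
  structure(list(kind = kind, mu0 = mu0, mu_inf = mu_inf, lambda = lambda,
                 a = a, n = n), class = "viscosity_model")
}

#' @export
print.viscosity_model <- function(x, ...) {
  if (x$kind == "newtonian") {
    cat(sprintf("<viscosity_model> newtonian, mu = %.4g Pa.s\n", x$mu))
  } else {
    cat(sprintf(
      "<viscosity_model> Carreau-Yasuda: mu0 %.4g, mu_inf %.4g Pa.s, lambda %.3g s, a %.3g, n %.4g\n",
      x$mu0, x$mu_inf, x$lambda, x$a, x$n))
  }
  invisible(x)
}

#' Effective viscosity at a shear rate
#'
#' @param gamma_dot shear rate(s) in 1/s (>= 0).
#' @param model a [viscosity_model].
#' @return viscosity in Pa s (vectorized over `gamma_dot`).
#' @export
effective_viscosity <- function(gamma_dot, model) {
  stopifnot(inherits(model, "viscosity_model"))
  stop_if(any(gamma_dot < 0), "'gamma_dot' must be >= 0")
  if (model$kind == "newtonian") {
    return(rep(model$mu, length(gamma_dot)))
  }
  model$mu_inf + (model$mu0 - model$mu_inf) *
    (1 + (model$lambda * gamma_dot)^model$a)^((model$n - 1) / model$a)
}

# d(log tau)/d(log gamma_dot) = 1 + gd * mu'(gd)/mu(gd): the local power-law
# exponent used by the Weissenberg-Rabinowitsch-Mooney wall correction.
# Equals 1 identically for a Newtonian fluid.
local_flow_exponent <- function(gamma_dot, model) {
  if (model$kind == "newtonian") return(rep(1, length(gamma_dot)))
  lg_a <- (model$lambda * gamma_dot)^model$a
  mu <- model$mu_inf + (model$mu0 - model$mu_inf) * (1 + lg_a)^((model$n - 1) / model$a)
  gd_dmu <- (model$mu0 - model$mu_inf) * (model$n - 1) * lg_a *
    (1 + lg_a)^((model$n - 1 - model$a) / model$a)
  1 + gd_dmu / mu
}

# phi functions of the exponential integrator, series-guarded near 0
.phi1 <- function(z) {
  if (abs(z) < 1e-5) 1 + z / 2 + z^2 / 6 else (exp(z) - 1) / z
}
.phi2 <- function(z) {
  if (abs(z) < 1e-5) 0.5 + z / 6 + z^2 / 24 else (exp(z) - 1 - z) / z^2
}

# one cycle of the Windkessel ODE C dP/dt = Q - P/R by an exponential
# (exact linear-part) integrator with linear reconstruction of Q on each of
# n_steps fixed substeps; returns the pressure at every node incl. both ends
wk_cycle <- function(P0, Qgrid, dt, R, C) {
  z <- -dt / (R * C)
  ez <- exp(z)
  f1 <- .phi1(z)
  f2 <- .phi2(z)
  n <- length(Qgrid) - 1L
  P <- numeric(n + 1L)
  P[1] <- P0
  w <- (dt / C) * (Qgrid[-(n + 1L)] * (f1 - f2) + Qgrid[-1L] * f2)
  for (k in seq_len(n)) P[k + 1L] <- ez * P[k] + w[k]
  P
}

#' Outlet pressure from a two-element Windkessel model
#'
#' Integrates `C dP/dt = Q(t) - P/R` from `P(0) = P0` over `n_cycles`
#' cardiac cycles and returns the final cycle. The integrator treats the
#' linear decay exactly (exponential integrator) with the flow reconstructed
#' linearly on a fixed grid of `n_steps` substeps per cycle, so the
#' zero-inflow decay and the constant-inflow steady state are exact and
#' periodic forcing is resolved to second order. The response reaches its
#' periodic steady state when `n_cycles >= 10 * R*C / T`; intermediate cycles
#' are advanced through the exact affine cycle map rather than stepped, so
#' large `n_cycles` costs nothing.
#'
#' @param Q a flow [waveform] (m^3/s).
#' @param params a [windkessel_params].
#' @param P0 initial pressure in Pa.
#' @param n_cycles number of cycles to integrate (>= 1).
#' @param n_steps substeps per cycle (default 1024).
#' @return an object of class `pressure_wave`: list with `t` (s, half-open
#'   cycle grid), `p` (Pa), `period`, and the start-of-cycle pressure `P0`.
#' @export
windkessel_pressure <- function(Q, params, P0 = 0, n_cycles = 1,
                                n_steps = 1024) {
  stopifnot(inherits(Q, "waveform"), inherits(params, "windkessel_params"))
  stop_if(Q$kind != "flow", "'Q' must be a flow waveform")
  check_scalar(P0, "P0", nonnegative = FALSE)
  stop_if(!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles),
          "'n_cycles' must be an integer >= 1")
  Qu <- resample_periodic(Q, n_steps)
  Qgrid <- c(Qu$v, Qu$v[1])
  dt <- Q$period / n_steps
  R <- params$R
  C <- params$C
  # affine one-cycle map P_T = alpha * P0 + beta; the homogeneous multiplier
  # of the discrete scheme is exactly exp(-T/(R*C))
  beta <- wk_cycle(0, Qgrid, dt, R, C)[n_steps + 1L]
  alpha <- exp(-Q$period / (R * C))
  k <- n_cycles - 1L
  P_start <- if (k == 0) P0 else {
    alpha^k * P0 + beta * if (alpha == 1) k else (1 - alpha^k) / (1 - alpha)
  }
  P <- wk_cycle(P_start, Qgrid, dt, R, C)
  structure(list(t = Qu$t, p = P[seq_len(n_steps)], period = Q$period,
                 P0 = P_start), class = "pressure_wave")
}

#' @export
print.pressure_wave <- function(x, ...) {
  cat(sprintf("<pressure_wave> mean %.4g Pa (%.1f mmHg), pulse %.4g Pa over %.3g s\n",
              mean(x$p), mean(x$p) / PA_PER_MMHG, max(x$p) - min(x$p),
              x$period))
  invisible(x)
}

# periodic steady-state pressure cycle (start pressure from the fixed point
# of the affine cycle map)
wk_periodic <- function(Q, R, C, n_steps = 1024) {
  Qu <- resample_periodic(Q, n_steps)
  Qgrid <- c(Qu$v, Qu$v[1])
  dt <- Q$period / n_steps
  beta <- wk_cycle(0, Qgrid, dt, R, C)[n_steps + 1L]
  alpha <- exp(-Q$period / (R * C))
  P0 <- beta / (1 - alpha)
  wk_cycle(P0, Qgrid, dt, R, C)
}

#' Tune Windkessel parameters to target pressures
#'
#' Reproduces the zero-dimensional tuning step: the resistance is fixed by
#' the mean, `R = target_mean_P / mean(Q)`, and the compliance is found by
#' scalar root finding so that the periodic steady-state pulse pressure
#' (max - min over the cycle) matches `target_pulse_P` to within 0.5%.
#'
#' @param Q a flow [waveform].
#' @param target_mean_P target mean outlet pressure, Pa (> 0).
#' @param target_pulse_P target pulse pressure, Pa (>= 0, < 2 * mean).
#' @param c_bracket search bracket for the compliance, m^3/Pa.
#' @return a [windkessel_params].
#' @export
tune_windkessel <- function(Q, target_mean_P, target_pulse_P,
                            c_bracket = c(1e-12, 1e-6)) {
  stopifnot(inherits(Q, "waveform"))
  stop_if(Q$kind != "flow", "'Q' must be a flow waveform")
  check_scalar(target_mean_P, "target_mean_P", positive = TRUE)
  check_scalar(target_pulse_P, "target_pulse_P", nonnegative = TRUE)
  stop_if(target_pulse_P >= 2 * target_mean_P,
          "'target_pulse_P' must be < 2 * target_mean_P")
  Qbar <- cycle_mean(Q)
  stop_if(Qbar <= 0, "mean flow must be > 0 to tune against a positive mean pressure")
  R <- target_mean_P / Qbar
  pulse_at <- function(C) {
    P <- wk_periodic(Q, R, C)
    max(P) - min(P)
  }
  p_lo <- pulse_at(c_bracket[1])  # small C: largest pulse
  p_hi <- pulse_at(c_bracket[2])  # large C: smallest pulse
  if (p_lo < 1e-9 * target_mean_P && target_pulse_P <= 0.005 * target_mean_P) {
    # effectively constant inflow: any compliance reproduces pulse ~ 0
    return(windkessel_params(R, sqrt(prod(c_bracket))))
  }
  stop_if(target_pulse_P > p_lo || target_pulse_P < p_hi,
          sprintf(paste0("no compliance in [%.3g, %.3g] m^3/Pa achieves pulse ",
                         "%.4g Pa (achievable range [%.4g, %.4g] Pa)"),
                  c_bracket[1], c_bracket[2], target_pulse_P, p_hi, p_lo))
  root <- stats::uniroot(function(lc) pulse_at(10^lc) - target_pulse_P,
                         log10(c_bracket), tol = 1e-12)
  C <- 10^root$root
  achieved <- pulse_at(C)
  stop_if(abs(achieved - target_pulse_P) > 0.005 * target_pulse_P,
          sprintf("compliance search did not converge: achieved pulse %.6g vs target %.6g Pa",
                  achieved, target_pulse_P))
  windkessel_params(R, C)
}

#' Quasi-steady wall shear stress time series along a graft
#'
#' Per station with current lumen radius `r`, the nominal (Newtonian)
#' Poiseuille wall shear rate is `gd_w(t) = 4 Q(t) / (pi r^3)` and the wall
#' shear stress is `tau(t) = mu(|gd_w|) * gd_w`. With
#' `consistency = "iterative"` the wall shear rate is corrected by a
#' Weissenberg-Rabinowitsch-Mooney fixed point,
#' `gd <- gd_nom * (3 + 1/n_loc(gd)) / 4` with `n_loc` the local power-law
#' exponent of the viscosity law, so the reported shear is consistent with a
#' fully developed generalized-Newtonian (Carreau-Yasuda) velocity profile;
#' the two modes coincide exactly for a Newtonian model. The sign of `tau`
#' follows the sign of `Q` (reverse flow gives negative wall shear).
#'
#' @param g a [graft_model].
#' @param Q a flow [waveform].
#' @param model a [viscosity_model].
#' @param consistency `"approximate"` or `"iterative"`.
#' @param n_time time samples per cycle (uniform grid).
#' @param tol,max_iter fixed-point tolerance (relative) and iteration cap.
#' @return an object of class `wss_field`: list with `stations` (arc
#'   positions m), `t` (cycle grid s), `period`, and matrix `tau`
#'   (stations x time, Pa, signed).
#' @export
wall_shear_series <- function(g, Q, model = viscosity_model(),
                              consistency = c("approximate", "iterative"),
                              n_time = 256, tol = 1e-8, max_iter = 100) {
  consistency <- match.arg(consistency)
  stopifnot(inherits(g, "graft_model"), inherits(Q, "waveform"),
            inherits(model, "viscosity_model"))
  stop_if(Q$kind != "flow", "'Q' must be a flow waveform")
  Qu <- resample_periodic(Q, n_time)
  r <- lumen_radius(g)
  gd_nom <- outer(4 / (pi * r^3), Qu$v)  # stations x time, signed
  gd <- gd_nom
  if (consistency == "iterative" && model$kind != "newtonian") {
    for (i in seq_len(nrow(gd))) {
      gi <- gd_nom[i, ]
      ok <- FALSE
      for (iter in seq_len(max_iter)) {
        n_loc <- local_flow_exponent(abs(gi), model)
        gi_new <- gd_nom[i, ] * (3 + 1 / n_loc) / 4
        delta <- max(abs(gi_new - gi) / pmax(abs(gi_new), 1e-300))
        gi <- gi_new
        if (delta < tol) { ok <- TRUE; break }
      }
      stop_if(!ok, sprintf(
        "wall shear fixed point failed to converge at station %d (s = %.4g m)",
        i, g$stations$s[i]))
      gd[i, ] <- gi
    }
  }
  tau <- matrix(effective_viscosity(abs(as.vector(gd)), model),
                nrow = nrow(gd)) * gd
  structure(list(stations = g$stations$s, t = Qu$t, period = Q$period,
                 tau = tau), class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d stations x %d time samples, period %.3g s\n",
              length(x$stations), length(x$t), x$period))
  cat(sprintf("  tau range [%.4g, %.4g] Pa\n", min(x$tau), max(x$tau)))
  invisible(x)
}

#' Construct a wall shear field from raw components
#'
#' Mainly for tests and for adapting externally computed data already in
#' memory; file-based import goes through [import_wss_field()].
#'
#' @param stations arc positions in m (strictly increasing).
#' @param t cycle time grid in s (half-open, `t[1] = 0`).
#' @param tau matrix (stations x time) of signed wall shear stress, Pa.
#' @param period cycle period, s.
#' @return a `wss_field`.
#' @export
wss_field <- function(stations, t, tau, period) {
  tau <- as.matrix(tau)
  stop_if(any(diff(stations) <= 0) && length(stations) > 1,
          "stations must be strictly increasing")
  check_scalar(period, "period", positive = TRUE)
  stop_if(any(diff(t) <= 0), "time grid must be strictly increasing")
  stop_if(abs(t[1]) > 1e-12 * period || t[length(t)] >= period,
          "time grid must cover [0, period)")
  stop_if(nrow(tau) != length(stations) || ncol(tau) != length(t),
          "'tau' must be a stations x time matrix")
  stop_if(anyNA(tau) || any(!is.finite(tau)), "'tau' must be finite")
  structure(list(stations = stations, t = t, period = period,
                 tau = unname(tau)), class = "wss_field")
}

#' Export a wall shear field to CSV
#'
#' Long format with header `station_s,time,tau` (SI units), one row per
#' (station, time) cell; round-trips through [import_wss_field()].
#'
#' @param f a `wss_field`.
#' @param path output path.
#' @param period_comment write the cycle period as a `#` comment (default
#'   TRUE; the importer recovers it from the uniform grid otherwise).
#' @return `path`, invisibly.
#' @export
export_wss_field <- function(f, path, period_comment = TRUE) {
  stopifnot(inherits(f, "wss_field"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt17 <- function(x) formatC(x, digits = 17, format = "g")
  if (period_comment) writeLines(sprintf("# period_s=%s", fmt17(f$period)), con)
  writeLines("station_s,time,tau", con)
  grid <- expand.grid(time = f$t, station_s = f$stations)
  tau <- as.vector(t(f$tau))
  writeLines(paste(fmt17(grid$station_s), fmt17(grid$time),
                   fmt17(tau), sep = ","), con)
  invisible(path)
}

#' Import a wall shear field from CSV
#'
#' Expects the long format written by [export_wss_field()]: header
#' `station_s,time,tau` in SI units on a complete station x time grid. For
#' externally computed 3D fields the wall shear vector must have been
#' projected onto a consistent direction beforehand (signed scalar contract).
#'
#' @param path CSV path.
#' @param period cycle period in s; if `NULL`, read from the `# period_s=`
#'   comment or inferred from a uniform time grid.
#' @return a `wss_field`.
#' @export
import_wss_field <- function(path, period = NULL) {
  stop_if(!file.exists(path), sprintf("WSS file not found: %s", path))
  first <- readLines(path, n = 1)
  if (is.null(period) && startsWith(first, "# period_s=")) {
    period <- as.numeric(sub("# period_s=", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("station_s", "time", "tau")
  stop_if(!all(need %in% names(df)),
          sprintf("WSS CSV '%s' must have header 'station_s,time,tau'", path))
  stations <- sort(unique(df$station_s))
  times <- sort(unique(df$time))
  key <- paste(match(df$station_s, stations), match(df$time, times))
  stop_if(anyDuplicated(key) > 0,
          sprintf("WSS CSV '%s' has duplicate (station,time) cells", path))
  full <- expand.grid(ti = seq_along(times), si = seq_along(stations))
  missing <- setdiff(paste(full$si, full$ti), key)
  stop_if(length(missing) > 0,
          sprintf("WSS CSV '%s' has a ragged grid; missing (station,time) cells: %s",
                  path, paste(utils::head(vapply(strsplit(missing, " "), function(p) {
                    sprintf("(%.4g, %.4g)", stations[as.integer(p[1])],
                            times[as.integer(p[2])])
                  }, character(1)), 10), collapse = ", ")))
  if (is.null(period)) {
    stop_if(length(times) < 2 || !is_uniform_grid(times, tol = 1e-6),
            "cannot infer the cycle period: supply 'period' or a uniform grid")
    period <- times[length(times)] + (times[2] - times[1])
  }
  tau <- matrix(NA_real_, length(stations), length(times))
  tau[cbind(match(df$station_s, stations), match(df$time, times))] <- df$tau
  wss_field(stations, times, tau, period)
}
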