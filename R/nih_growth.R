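# Per-station ODE model of neointimal hyperplasia: nitric oxide (N), growth
# factor (G), smooth muscle cells (S), collagen (C) and intimal area (A),
# driven by the local cycle-averaged shear index. Biochemical state variables
# are dimensionless densities; time inside this module is in days.

.nih_param_names <- c("k_N", "d_N", "k_G", "d_G", "p_S", "d_S", "S_max",
                      "alpha_N", "k_C", "d_C", "beta_S", "beta_C",
                      "tau_ref", "theta", "h")

.nih_presets <- list(
  # Calibrated so that a sustained low-shear stimulus of 0.1 Pa at an
  # anastomotic caliber (radius 3.5 mm) produces 50-70% area stenosis within
  # 8-24 months, while stimuli well above the 0.5 Pa threshold shut growth
  # down. Order-of-magnitude calibration, not a patient fit.
  "demo-2020" = c(k_N = 2, d_N = 2, k_G = 0.5, d_G = 0.5, p_S = 0.1,
                  d_S = 0.01, S_max = 1, alpha_N = 2, k_C = 0.05, d_C = 0.1,
                  beta_S = 1e-5, beta_C = 3.5e-5, tau_ref = 1, theta = 0.5,
                  h = 8)
)

#' Parameters of the NIH growth model
#'
#' Returns the named parameter vector of the intimal growth ODE system,
#' starting from a preset and applying any overrides. Rates are per day;
#' `beta_S` and `beta_C` are in m^2 per unit of (dimensionless) SMC density
#' and collagen; `tau_ref` (shear half-saturation of NO production) and
#' `theta` (low-shear activation threshold of the growth factor) are in Pa;
#' `h >= 1` is the Hill steepness of the threshold.
#'
#' @param preset name of a shipped preset; currently `"demo-2020"`.
#' @param ... named numeric overrides of individual parameters.
#' @return an object of class `nih_params` (named numeric vector).
#' @examples
#' p <- nih_params("demo-2020", p_S = 0.12)
#' p["theta"]
#' @export
nih_params <- function(preset = "demo-2020", ...) {
  stop_if(!preset %in% names(.nih_presets),
          sprintf("unknown preset '%s' (available: %s)", preset,
                  paste(names(.nih_presets), collapse = ", ")))
  p <- .nih_presets[[preset]]
  dots <- list(...)
  if (length(dots) > 0) {
    stop_if(is.null(names(dots)) || any(names(dots) == ""),
            "parameter overrides must be named")
    bad <- setdiff(names(dots), .nih_param_names)
    stop_if(length(bad) > 0,
            sprintf("unknown NIH parameter(s): %s", paste(bad, collapse = ", ")))
    p[names(dots)] <- vapply(dots, function(x)
      check_scalar(x, "override"), numeric(1))
  }
  validate_nih_params(p)
}

validate_nih_params <- function(p) {
  stop_if(!is.numeric(p) || !all(.nih_param_names %in% names(p)),
          sprintf("NIH parameters must include: %s",
                  paste(.nih_param_names, collapse = ", ")))
  p <- p[.nih_param_names]
  stop_if(anyNA(p) || any(!is.finite(p)), "NIH parameters must be finite")
  stop_if(any(p[c("k_N", "d_N", "k_G", "d_G", "p_S", "d_S", "alpha_N",
                  "k_C", "d_C", "beta_S", "beta_C")] < 0),
          "NIH rate parameters must be >= 0")
  stop_if(p[["S_max"]] <= 0, "'S_max' must be > 0")
  stop_if(p[["tau_ref"]] <= 0, "'tau_ref' must be > 0")
  stop_if(p[["theta"]] <= 0, "'theta' must be > 0")
  stop_if(p[["h"]] < 1, "'h' must be >= 1")
  structure(p, class = "nih_params")
}

#' @export
print.nih_params <- function(x, ...) {
  cat("<nih_params>\n")
  print(unclass(x))
  invisible(x)
}

#' Initial per-station biochemical state
#'
#' Default initial conditions: a small seed population of smooth muscle
#' cells (`S = 1e-3`, representing sparse medial cells activated by surgical
#' injury) with no nitric oxide, growth factor, collagen or intima. The
#' absorbing state `S = 0, C = 0` produces no spontaneous tissue.
#'
#' @param n_stations number of stations.
#' @param N,G,S,C,A_intima initial values, recycled across stations.
#' @return an `nih_state` matrix (stations x 5) with columns
#'   `N, G, S, C, A`.
#' @export
nih_state <- function(n_stations = 1, N = 0, G = 0, S = 1e-3, C = 0,
                      A_intima = 0) {
  m <- cbind(N = rep_len(N, n_stations), G = rep_len(G, n_stations),
             S = rep_len(S, n_stations), C = rep_len(C, n_stations),
             A = rep_len(A_intima, n_stations))
  stop_if(anyNA(m) || any(!is.finite(m)) || any(m < 0),
          "NIH state components must be finite and nonnegative")
  structure(m, class = c("nih_state", "matrix"))
}

#' Right-hand side of the NIH growth ODE system
#'
#' With stimulus `x` (the local shear index, Pa):
#' low-shear activation `Act(x) = theta^h / (theta^h + x^h)` (~1 at low
#' shear, ~0 at high shear), shear sensing `sig(x) = x / (x + tau_ref)`, and
#' \deqn{dN/dt = k_N sig(x) - d_N N}
#' \deqn{dG/dt = k_G Act(x) - d_G G}
#' \deqn{dS/dt = p_S G S (1 - S/S_{max}) / (1 + alpha_N N) - d_S S}
#' \deqn{dC/dt = k_C S - d_C C}
#' \deqn{dA/dt = max(0, beta_S dS/dt + beta_C dC/dt)}
#' Nitric oxide rises with shear and inhibits proliferation; the growth
#' factor is produced at low shear and drives logistic SMC turnover; SMCs
#' secrete collagen; the intima integrates the resulting volume gain and
#' never regresses.
#'
#' @param state an [nih_state] matrix (stations x 5) or numeric vector of 5.
#' @param stimulus local shear index per station, Pa (>= 0), recycled.
#' @param params an [nih_params] vector.
#' @return matrix (or vector) of time derivatives, per day.
#' @export
nih_rhs <- function(state, stimulus, params) {
  params <- validate_nih_params(params)
  vec_in <- is.null(dim(state))
  m <- if (vec_in) matrix(state, nrow = 1) else unclass(state)
  stop_if(ncol(m) != 5, "state must have 5 components (N, G, S, C, A)")
  x <- rep_len(stimulus, nrow(m))
  stop_if(any(x < 0), "'stimulus' must be >= 0")
  N <- m[, 1]; G <- m[, 2]; S <- m[, 3]; Cg <- m[, 4]
  th <- params[["theta"]]^params[["h"]]
  act <- th / (th + x^params[["h"]])
  sig <- x / (x + params[["tau_ref"]])
  dN <- params[["k_N"]] * sig - params[["d_N"]] * N
  dG <- params[["k_G"]] * act - params[["d_G"]] * G
  dS <- params[["p_S"]] * G * S * (1 - S / params[["S_max"]]) /
    (1 + params[["alpha_N"]] * N) - params[["d_S"]] * S
  dC <- params[["k_C"]] * S - params[["d_C"]] * Cg
  dA <- pmax(0, params[["beta_S"]] * dS + params[["beta_C"]] * dC)
  out <- cbind(N = dN, G = dG, S = dS, C = dC, A = dA)
  if (vec_in) out[1, ] else out
}

# deSolve-compatible RHS over the flattened (stations x 5) state
.nih_desolve_rhs <- function(t, y, parms) {
  m <- matrix(y, ncol = 5)
  list(as.vector(nih_rhs(m, parms$stimulus, parms$params)))
}

#' Advance the NIH growth system in time
#'
#' Integrates all stations jointly with an adaptive stiff-capable solver
#' (deSolve's `lsoda` by default). The system preserves nonnegativity by
#' construction from any nonnegative initial state (every loss term vanishes
#' with its own component), so no clipping is applied.
#'
#' @param state an [nih_state] matrix (stations x 5).
#' @param stimulus per-station shear index, Pa.
#' @param params an [nih_params] vector.
#' @param dt_days time to advance, days (> 0).
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method.
#' @return the advanced `nih_state` matrix.
#' @export
integrate_growth <- function(state, stimulus, params, dt_days,
                             rtol = 1e-6, atol = 1e-8, method = "lsoda") {
  check_scalar(dt_days, "dt_days", positive = TRUE)
  traj <- growth_trajectory(state, stimulus, params, times = c(0, dt_days),
                            rtol = rtol, atol = atol, method = method)
  structure(traj[[length(traj)]], class = c("nih_state", "matrix"))
}

#' NIH state trajectory at requested times
#'
#' As [integrate_growth()], but records the full state at each requested
#' time point (a single solver run with internal adaptive stepping).
#'
#' @inheritParams integrate_growth
#' @param times nondecreasing times in days; 0 is prepended if absent.
#' @return a named list of `nih_state` matrices, one per requested time
#'   (names are the times in days).
#' @export
growth_trajectory <- function(state, stimulus, params, times,
                              rtol = 1e-6, atol = 1e-8, method = "lsoda") {
  params <- validate_nih_params(params)
  m <- unclass(state)
  stop_if(is.null(dim(m)) || ncol(m) != 5,
          "'state' must be a stations x 5 matrix; see nih_state()")
  stop_if(any(m < 0), "initial NIH state must be nonnegative")
  stop_if(any(diff(times) < 0), "'times' must be nondecreasing")
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  x <- rep_len(stimulus, nrow(m))
  sol <- tryCatch(
    deSolve::ode(y = as.vector(m), times = times, func = .nih_desolve_rhs,
                 parms = list(stimulus = x, params = params),
                 method = method, rtol = rtol, atol = atol),
    warning = function(w) stop(sprintf(
      "growth integrator failed (%s); state snapshot: %s",
      conditionMessage(w),
      paste(sprintf("%.3g", utils::head(as.vector(m), 10)), collapse = ", ")),
      call. = FALSE)
  )
  out <- lapply(seq_len(nrow(sol)), function(i) {
    mm <- matrix(sol[i, -1], ncol = 5,
                 dimnames = list(NULL, c("N", "G", "S", "C", "A")))
    structure(mm, class = c("nih_state", "matrix"))
  })
  names(out) <- format(sol[, 1], trim = TRUE)
  if (prepend) out <- out[-1]
  out
}

#' Fit NIH growth parameters to intimal-area observations
#'
#' Least-squares fit (Levenberg-Marquardt, [minpack.lm::nls.lm()]) of a
#' named subset of growth parameters to observed intimal-area time series at
#' known constant stimuli. Free parameters are optimized on a log scale,
#' which keeps them positive.
#'
#' @param observations data frame with columns `stimulus` (Pa), `t_days`,
#'   `A_intima` (m^2); at least as many rows as free parameters.
#' @param p0 initial [nih_params].
#' @param free character vector of parameter names to fit (possibly empty).
#' @param state0 initial one-station state shared by all trajectories
#'   (default [nih_state()] defaults).
#' @param rtol,atol solver tolerances used during fitting.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return list with `params` (fitted [nih_params]), `residual_norm`
#'   (root-sum-of-squares), and `info` (the `nls.lm` convergence code).
#' @export
fit_growth_params <- function(observations, p0, free,
                              state0 = nih_state(1),
                              rtol = 1e-8, atol = 1e-10, max_iter = 100) {
  p0 <- validate_nih_params(p0)
  need <- c("stimulus", "t_days", "A_intima")
  stop_if(!is.data.frame(observations) || !all(need %in% names(observations)),
          sprintf("'observations' must have columns: %s",
                  paste(need, collapse = ", ")))
  stop_if(length(free) > 0 && !all(free %in% .nih_param_names),
          sprintf("unknown free parameter(s): %s",
                  paste(setdiff(free, .nih_param_names), collapse = ", ")))
  stop_if(nrow(observations) < length(free),
          "need at least as many observations as free parameters")
  predict_A <- function(p) {
    unlist(lapply(split(observations, observations$stimulus), function(obs) {
      tt <- sort(unique(obs$t_days))
      traj <- growth_trajectory(state0, obs$stimulus[1], p, times = tt,
                                rtol = rtol, atol = atol)
      A_at <- vapply(traj, function(s) s[1, "A"], numeric(1))
      A_at[match(obs$t_days, tt)]
    }), use.names = FALSE)
  }
  obs_sorted <- unlist(lapply(split(observations, observations$stimulus),
                              function(o) o$A_intima), use.names = FALSE)
  if (length(free) == 0) {
    res <- predict_A(p0) - obs_sorted
    return(list(params = p0, residual_norm = sqrt(sum(res^2)), info = 0L))
  }
  resid_fn <- function(logp) {
    p <- p0
    p[free] <- exp(logp)
    p <- validate_nih_params(unclass(p))
    predict_A(p) - obs_sorted
  }
  fit <- minpack.lm::nls.lm(par = log(unclass(p0)[free]), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  stop_if(fit$info %in% c(0L, 5L),
          sprintf("parameter fit did not converge (info %d, residual %.4g)",
                  fit$info, sqrt(sum(fit$fvec^2))))
  p_fit <- p0
  p_fit[free] <- exp(fit$par)
  list(params = validate_nih_params(unclass(p_fit)),
       residual_norm = sqrt(sum(fit$fvec^2)), info = fit$info)
}
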