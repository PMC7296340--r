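# The multiscale loop: hemodynamics -> shear indices -> growth -> geometry
# update, plus stenosis quantification and predictive-value scoring.

DAYS_PER_MONTH <- 365.25 / 12

#' Assemble a simulation configuration
#'
#' Bundles and validates everything one run needs. The cardiac-cycle and
#' growth time scales are separated quasi-statically: within one growth step
#' the shear stimulus is frozen. The `recoupling` policy controls how often
#' the hemodynamics are recomputed on the remodeled lumen: `"baseline"`
#' (default) computes the stimulus once on the baseline geometry and keeps
#' it for the whole run, `"every_step"` recomputes it at each growth step.
#'
#' @param graft a [graft_model]; its intimal areas are the initial state.
#' @param waveform a flow [waveform].
#' @param viscosity a [viscosity_model].
#' @param nih an [nih_params] vector.
#' @param stimulus_index `"holmes"` or `"tawss"`.
#' @param months total simulated duration in months (> 0; 1 month =
#'   365.25/12 days).
#' @param growth_step_days growth step in days (> 0, at most the total
#'   duration).
#' @param recoupling `"baseline"` or `"every_step"`.
#' @param state0 optional [nih_state] matrix matching the graft stations;
#'   default [nih_state()] seeds with `A_intima` taken from the graft.
#' @param windkessel optional [windkessel_params] for outlet pressure
#'   reporting (does not feed back on the shear stimulus).
#' @param consistency wall-shear consistency mode, see [wall_shear_series()].
#' @param n_time time samples per cardiac cycle.
#' @param occlusion_fraction area-loss fraction at which a station is
#'   declared near-occluded and its growth frozen (default 0.99).
#' @param seed integer seed recorded with the run (the core loop is
#'   deterministic; the seed matters for downstream stochastic add-ons).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(graft, waveform, viscosity = viscosity_model(),
                              nih = nih_params("demo-2020"),
                              stimulus_index = c("holmes", "tawss"),
                              months = 19, growth_step_days = 7,
                              recoupling = c("baseline", "every_step"),
                              state0 = NULL, windkessel = NULL,
                              consistency = "approximate",
                              n_time = 256, occlusion_fraction = 0.99,
                              seed = 1L) {
  stimulus_index <- match.arg(stimulus_index)
  recoupling <- match.arg(recoupling)
  stopifnot(inherits(graft, "graft_model"), inherits(waveform, "waveform"),
            inherits(viscosity, "viscosity_model"))
  nih <- validate_nih_params(nih)
  stop_if(waveform$kind != "flow",
          "'waveform' must be a flow waveform (see velocity_to_flow)")
  check_scalar(months, "months", positive = TRUE)
  check_scalar(growth_step_days, "growth_step_days", positive = TRUE)
  stop_if(growth_step_days > months * DAYS_PER_MONTH,
          "'growth_step_days' exceeds the total simulated duration")
  check_scalar(occlusion_fraction, "occlusion_fraction", positive = TRUE)
  stop_if(occlusion_fraction >= 1, "'occlusion_fraction' must be < 1")
  n_st <- nrow(graft$stations)
  if (is.null(state0)) {
    state0 <- nih_state(n_st, A_intima = graft$stations$A_intima)
  }
  stop_if(nrow(state0) != n_st,
          "'state0' must have one row per graft station")
  if (!is.null(windkessel)) stopifnot(inherits(windkessel, "windkessel_params"))
  structure(list(graft = graft, waveform = waveform, viscosity = viscosity,
                 nih = nih, stimulus_index = stimulus_index, months = months,
                 growth_step_days = growth_step_days, recoupling = recoupling,
                 state0 = state0, windkessel = windkessel,
                 consistency = consistency, n_time = n_time,
                 occlusion_fraction = occlusion_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d stations, %.3g months, step %.3g d, stimulus %s, recoupling %s\n",
    nrow(x$graft$stations), x$months, x$growth_step_days,
    x$stimulus_index, x$recoupling))
  invisible(x)
}

stimulus_from_graft <- function(cfg, graft) {
  f <- compute_indices(wall_shear_series(graft, cfg$waveform, cfg$viscosity,
                                         consistency = cfg$consistency,
                                         n_time = cfg$n_time))
  list(value = f[[cfg$stimulus_index]], field = f)
}

#' Run the coupled NIH growth simulation
#'
#' Quasi-static loop: at each growth step the wall shear field and shear
#' indices are taken on the current lumen radii (recomputed per step or
#' frozen at baseline per the `recoupling` policy), the per-station growth
#' ODEs are advanced with the stimulus frozen within the step, and the
#' intimal areas and lumen radii are updated. Media areas are never touched.
#' A station whose lumen would drop to 1% of baseline (or
#' `1 - occlusion_fraction`) is frozen and flagged `near_occluded` rather
#' than raising an error; the run completes. The run is deterministic for a
#' fixed configuration.
#'
#' @param cfg a [simulation_config].
#' @return an object of class `nih_simulation`: list with the `config`,
#'   `baseline` and `final` graft models, final `state`, per-step intimal
#'   area `history` (stations x steps+1), `times_days`, the baseline and
#'   final index fields (`indices0`, `indices`), logical `near_occluded`,
#'   optional outlet `pressure`, and the final [stenosis_profile()] `report`.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  baseline <- cfg$graft
  graft <- baseline
  state <- unclass(cfg$state0)
  n_st <- nrow(graft$stations)
  total_days <- cfg$months * DAYS_PER_MONTH
  n_steps <- ceiling(total_days / cfg$growth_step_days - 1e-9)
  step_ends <- pmin(seq_len(n_steps) * cfg$growth_step_days, total_days)
  base0 <- stimulus_from_graft(cfg, baseline)
  stim <- base0
  A_cap <- cfg$occlusion_fraction * graft$stations$A_base
  frozen <- rep(FALSE, n_st)
  history <- matrix(NA_real_, n_st, n_steps + 1L)
  history[, 1] <- state[, "A"]
  t_prev <- 0
  for (k in seq_len(n_steps)) {
    if (cfg$recoupling == "every_step" && k > 1) {
      stim <- stimulus_from_graft(cfg, graft)
    }
    dt <- step_ends[k] - t_prev
    t_prev <- step_ends[k]
    active <- which(!frozen)
    if (length(active) > 0) {
      adv <- integrate_growth(
        structure(state[active, , drop = FALSE], class = c("nih_state", "matrix")),
        stim$value[active], cfg$nih, dt_days = dt)
      # the intima never regresses; guard against solver round-off
      adv[, "A"] <- pmax(adv[, "A"], state[active, "A"])
      state[active, ] <- adv
    }
    hit <- state[, "A"] >= A_cap & !frozen
    if (any(hit)) {
      state[hit, "A"] <- A_cap[hit]
      frozen[hit] <- TRUE
    }
    graft$stations$A_intima <- state[, "A"]
    history[, k + 1L] <- state[, "A"]
  }
  final_stim <- if (cfg$recoupling == "every_step")
    stimulus_from_graft(cfg, graft) else stim
  pressure <- if (!is.null(cfg$windkessel)) {
    windkessel_pressure(cfg$waveform, cfg$windkessel,
                        P0 = cycle_mean(cfg$waveform) * cfg$windkessel$R,
                        n_cycles = 50)
  } else NULL
  report <- stenosis_profile(graft, baseline, near_occluded = frozen,
                             history = history,
                             times_days = c(0, step_ends))
  structure(list(config = cfg, baseline = baseline, final = graft,
                 state = structure(state, class = c("nih_state", "matrix")),
                 history = history, times_days = c(0, step_ends),
                 indices0 = base0$field, indices = final_stim$field,
                 near_occluded = frozen, pressure = pressure,
                 report = report),
            class = "nih_simulation")
}

#' @export
print.nih_simulation <- function(x, ...) {
  cat(sprintf("<nih_simulation> %d stations, %.3g months simulated\n",
              nrow(x$final$stations), x$config$months))
  print(x$report)
  invisible(x)
}

#' Stenosis profile of a remodeled graft
#'
#' Per-station percent area stenosis relative to the baseline configuration,
#' `100 * A_intima / A_base = 100 * (A_base - A_lumen) / A_base`, the worst
#' station per region (ties broken at the smallest arc position), and
#' significance flags at the >50% cutoff.
#'
#' @param remodeled a [graft_model] after growth, or an `nih_simulation`.
#' @param baseline the baseline [graft_model] sharing the same stations.
#' @param significant_pct significance cutoff in percent (default 50,
#'   strict inequality).
#' @param near_occluded optional logical per-station flags to carry through.
#' @param history,times_days optional per-step intimal-area matrix and time
#'   vector; when present, a `timeline` of stenosis at the worst stations is
#'   attached.
#' @return an object of class `stenosis_report`: list with `stations`
#'   (data frame `s,region,stenosis_pct,significant,near_occluded`), `worst`
#'   (one row per region), `significant_pct`, and optionally `timeline`.
#' @export
stenosis_profile <- function(remodeled, baseline = NULL,
                             significant_pct = 50, near_occluded = NULL,
                             history = NULL, times_days = NULL) {
  if (inherits(remodeled, "nih_simulation")) {
    return(remodeled$report)
  }
  stopifnot(inherits(remodeled, "graft_model"))
  if (is.null(baseline)) baseline <- remodeled
  stopifnot(inherits(baseline, "graft_model"))
  stop_if(nrow(remodeled$stations) != nrow(baseline$stations) ||
            any(abs(remodeled$stations$s - baseline$stations$s) >
                  1e-12 * max(baseline$stations$s)),
          "remodeled and baseline grafts must share stations")
  st <- remodeled$stations
  pct <- 100 * (baseline$stations$A_base - (st$A_base - st$A_intima)) /
    baseline$stations$A_base
  if (is.null(near_occluded)) near_occluded <- rep(FALSE, nrow(st))
  stations <- data.frame(s = st$s, region = st$region, stenosis_pct = pct,
                         significant = pct > significant_pct,
                         near_occluded = near_occluded,
                         stringsAsFactors = FALSE)
  worst <- do.call(rbind, lapply(split(stations, stations$region),
                                 function(d) {
    d[which.max(d$stenosis_pct), c("region", "s", "stenosis_pct",
                                   "significant")]
  }))
  worst <- worst[order(worst$s), ]
  rownames(worst) <- NULL
  out <- list(stations = stations, worst = worst,
              significant_pct = significant_pct)
  if (!is.null(history)) {
    widx <- match(worst$s, stations$s)
    tl <- data.frame(t_days = times_days,
                     t(100 * history[widx, , drop = FALSE] /
                         baseline$stations$A_base[widx]))
    names(tl)[-1] <- paste0(worst$region, "_pct")
    out$timeline <- tl
  }
  structure(out, class = "stenosis_report")
}

#' @export
print.stenosis_report <- function(x, ...) {
  cat(sprintf("<stenosis_report> worst stations (significant > %g%%):\n",
              x$significant_pct))
  print(transform(x$worst, stenosis_pct = round(stenosis_pct, 1)),
        row.names = FALSE)
  if (any(x$stations$near_occluded)) {
    cat(sprintf("  %d station(s) frozen at near-occlusion\n",
                sum(x$stations$near_occluded)))
  }
  invisible(x)
}

#' Predictive values of significant-stenosis calls
#'
#' Compares predicted against observed significant-stenosis labels (e.g. per
#' region) and returns the 2x2 table summaries. Undefined ratios (zero
#' denominator) are reported as `NA` rather than 0.
#'
#' @param predicted logical vector of predicted labels.
#' @param observed logical vector of observed labels, same length.
#' @return list with `ppv`, `npv`, `sensitivity`, `specificity`, and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
predictive_values <- function(predicted, observed) {
  stop_if(length(predicted) == 0, "empty label vectors")
  stop_if(length(predicted) != length(observed),
          "'predicted' and 'observed' must have equal length")
  predicted <- as.logical(predicted)
  observed <- as.logical(observed)
  stop_if(anyNA(predicted) || anyNA(observed), "labels must not be NA")
  tp <- sum(predicted & observed)
  fp <- sum(predicted & !observed)
  tn <- sum(!predicted & !observed)
  fn <- sum(!predicted & observed)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
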