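# Cycle-averaged wall shear indices: TAWSS, OSI and HOLMES, plus the
# low-shear classification that feeds the growth model.

# periodic trapezoid integral of each row of m over the closed cycle
cycle_integral <- function(m, t, period) {
  tc <- c(t, period)
  mc <- cbind(m, m[, 1])
  dt <- diff(tc)
  as.vector((mc[, -ncol(mc), drop = FALSE] +
               mc[, -1, drop = FALSE]) %*% dt) / 2
}

#' Compute TAWSS, OSI and HOLMES per station
#'
#' With cycle period `T` and signed wall shear `tau(t)`:
#' `TAWSS = (1/T) * int |tau| dt`,
#' `OSI = 0.5 * (1 - |int tau dt| / int |tau| dt)` (0 where the shear is
#' identically zero over the cycle, avoiding 0/0), and
#' `HOLMES = TAWSS * (0.5 - OSI)`, the index that jointly penalizes low and
#' oscillating shear. Integrals are trapezoidal on the cycle grid with the
#' periodic wrap-around segment included. OSI is 0 whenever `tau` does not
#' change sign, and HOLMES equals `TAWSS/2` in that case.
#'
#' @param w a [wss_field].
#' @return an object of class `shear_index_field`: list with `stations`,
#'   `tawss` (Pa), `osi` (in `[0, 0.5]`), `holmes` (Pa), and `zero_flag`
#'   marking stations with identically zero shear.
#' @examples
#' f <- wss_field(stations = 0, t = seq(0, 0.99, 0.01),
#'                tau = matrix(sin(2 * pi * seq(0, 0.99, 0.01)), 1),
#'                period = 1)
#' idx <- compute_indices(f)
#' idx$osi     # 0.5: purely oscillatory
#' idx$holmes  # 0
#' @export
compute_indices <- function(w) {
  stopifnot(inherits(w, "wss_field"))
  int_tau <- cycle_integral(w$tau, w$t, w$period)
  int_abs <- cycle_integral(abs(w$tau), w$t, w$period)
  tawss <- int_abs / w$period
  zero <- int_abs <= 0
  osi <- ifelse(zero, 0, 0.5 * (1 - abs(int_tau) / int_abs))
  osi <- pmin(pmax(osi, 0), 0.5)
  holmes <- tawss * (0.5 - osi)
  if (any(zero)) {
    message(sprintf("OSI set to 0 at %d station(s) with identically zero shear",
                    sum(zero)))
  }
  structure(list(stations = w$stations, tawss = tawss, osi = osi,
                 holmes = holmes, zero_flag = zero),
            class = "shear_index_field")
}

#' @export
print.shear_index_field <- function(x, ...) {
  cat(sprintf("<shear_index_field> %d stations\n", length(x$stations)))
  cat(sprintf("  TAWSS [%.4g, %.4g] Pa, OSI [%.3g, %.3g], HOLMES [%.4g, %.4g] Pa\n",
              min(x$tawss), max(x$tawss), min(x$osi), max(x$osi),
              min(x$holmes), max(x$holmes)))
  invisible(x)
}

#' Classify low-shear stations
#'
#' A station is low-shear where the chosen index is strictly below the
#' threshold; 0.5 Pa is the conventional cutoff below which TAWSS and HOLMES
#' are considered low.
#'
#' @param f a `shear_index_field` from [compute_indices()].
#' @param index `"holmes"` or `"tawss"`.
#' @param threshold threshold in Pa (>= 0).
#' @return logical mask, TRUE at low-shear stations.
#' @export
classify_low_shear <- function(f, index = c("holmes", "tawss"),
                               threshold = 0.5) {
  index <- match.arg(index)
  stopifnot(inherits(f, "shear_index_field"))
  stop_if(!is.numeric(threshold) || length(threshold) != 1 ||
            !is.finite(threshold) || threshold < 0,
          "'threshold' must be a single number >= 0")
  f[[index]] < threshold
}

#' Export shear indices to CSV
#'
#' Header `station_s,tawss,osi,holmes,low_shear`, with the low-shear column
#' computed by [classify_low_shear()].
#'
#' @param f a `shear_index_field`.
#' @param path output path.
#' @param index,threshold passed to [classify_low_shear()].
#' @return `path`, invisibly.
#' @export
export_indices <- function(f, path, index = "holmes", threshold = 0.5) {
  stopifnot(inherits(f, "shear_index_field"))
  low <- classify_low_shear(f, index, threshold)
  df <- data.frame(station_s = fmt_num(f$stations), tawss = fmt_num(f$tawss),
                   osi = fmt_num(f$osi), holmes = fmt_num(f$holmes),
                   low_shear = tolower(as.character(low)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
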