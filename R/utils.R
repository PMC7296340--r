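# Internal validation and unit-conversion helpers.
# Internal units are SI throughout (s, m, m^2, m^3/s, Pa); clinical units are
# converted at the boundary with fixed constants.

PA_PER_MMHG <- 133.322
PA_PER_DYN_CM2 <- 0.1

.time_units <- c("s" = 1, "ms" = 1e-3)
.velocity_units <- c("m/s" = 1, "cm/s" = 1e-2)
.flow_units <- c("m3/s" = 1, "mL/s" = 1e-6)

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  if (positive) stop_if(x <= 0, sprintf("'%s' must be > 0", name))
  if (nonnegative) stop_if(x < 0, sprintf("'%s' must be >= 0", name))
  invisible(x)
}

#' Convert a pressure to pascals
#'
#' @param x numeric pressure values.
#' @param unit one of `"Pa"`, `"mmHg"`.
#' @return pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
as_pascal <- function(x, unit = c("Pa", "mmHg")) {
  unit <- match.arg(unit)
  if (unit == "mmHg") x * PA_PER_MMHG else x
}

#' Convert a wall shear stress to pascals
#'
#' @param x numeric shear values.
#' @param unit one of `"Pa"`, `"dyn/cm2"`.
#' @return shear stress in Pa (1 dyn/cm2 = 0.1 Pa).
#' @export
shear_as_pascal <- function(x, unit = c("Pa", "dyn/cm2")) {
  unit <- match.arg(unit)
  if (unit == "dyn/cm2") x * PA_PER_DYN_CM2 else x
}

# relative difference with guard for zero scale
rel_diff <- function(a, b) {
  s <- max(abs(a), abs(b), .Machine$double.xmin)
  abs(a - b) / s
}

is_uniform_grid <- function(t, tol = 1e-9) {
  d <- diff(t)
  max(d) - min(d) <= tol * max(d)
}

# format a numeric for deterministic CSV output (12 significant digits)
fmt_num <- function(x) formatC(x, digits = 12, format = "g")
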