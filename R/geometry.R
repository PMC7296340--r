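# Graft geometry: 3D centerlines, axial stations with lumen/intima/media
# areas, Frenet metrics (curvature, torsion), tortuosity, and the synthetic
# axisymmetric bypass builder.

#' Construct a centerline
#'
#' @param points numeric matrix (n x 3) of ordered 3D coordinates in m,
#'   n >= 4, consecutive points distinct.
#' @return an object of class `centerline` with fields `points` and `arc`
#'   (cumulative chordal arc length, `arc[1] = 0`).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  stop_if(!is.numeric(points) || ncol(points) != 3,
          "'points' must be an n x 3 numeric matrix")
  stop_if(anyNA(points) || any(!is.finite(points)),
          "centerline coordinates must be finite")
  stop_if(nrow(points) < 4, "a centerline needs at least 4 points")
  seg <- sqrt(rowSums(diff(points)^2))
  stop_if(any(seg == 0), "consecutive centerline points must be distinct")
  structure(list(points = unname(points), arc = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.4g m\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' Tortuosity of a centerline
#'
#' Arc length over endpoint chord minus one, `L/D - 1`: zero for a straight
#' segment, invariant under rigid-body motion.
#'
#' @param c3 a [centerline].
#' @return dimensionless tortuosity (>= 0).
#' @export
tortuosity <- function(c3) {
  stopifnot(inherits(c3, "centerline"))
  n <- nrow(c3$points)
  D <- sqrt(sum((c3$points[n, ] - c3$points[1, ])^2))
  stop_if(D < 1e-12, "tortuosity undefined: coincident endpoints (D = 0)")
  max(c3$arc) / D - 1
}

# Derivatives of one coordinate block by sliding-window polynomial fit.
# For each point a degree-<=5 polynomial is fitted by least squares to the
# (up to) 9 nearest samples of (arc, xyz), scaled for conditioning; first,
# second and third derivatives are read off the coefficients. Local
# polynomial fits keep the noise-amplifying third derivative stable where
# spline differentiation of raw points would not be.
frenet_derivatives <- function(arc, pts, half_window = 4L, degree = 5L) {
  n <- length(arc)
  d1 <- d2 <- d3 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half_window, n - 2L * half_window))
    hi <- min(n, lo + 2L * half_window)
    lo <- max(1L, hi - 2L * half_window)
    idx <- lo:hi
    u <- arc[idx] - arc[i]
    h <- max(abs(u))
    xi <- u / h
    p <- min(degree, length(idx) - 1L)
    V <- outer(xi, 0:p, `^`)
    coef <- qr.coef(qr(V), pts[idx, , drop = FALSE] - rep(pts[i, ],
                                                          each = length(idx)))
    d1[i, ] <- coef[2, ] / h
    if (p >= 2) d2[i, ] <- 2 * coef[3, ] / h^2
    if (p >= 3) d3[i, ] <- 6 * coef[4, ] / h^3
  }
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Curvature, torsion and tortuosity of a centerline
#'
#' Computes per-point Frenet curvature `kappa = |g' x g''| / |g'|^3` and
#' torsion `tau = (g' x g'') . g''' / |g' x g''|^2` from local polynomial
#' fits of the (optionally smoothed) coordinates against arc length. Where
#' `|g' x g''|` falls below `eps` the curve is locally straight/planar in the
#' Frenet sense, torsion is reported as 0 and `planar_flag` is set so
#' undefined points cannot poison summaries.
#'
#' @param c3 a [centerline].
#' @param smoothing smoothing factor in `[0, 1]`; 0 (default) differentiates
#'   the points directly, larger values pre-smooth each coordinate with
#'   [stats::smooth.spline()] (`spar = smoothing`) before differentiation.
#' @param eps threshold on `|g' x g''|` below which torsion is undefined.
#' @return an object of class `geometry_metrics`: list with per-point
#'   `curvature` (1/m, >= 0), `torsion` (1/m), logical `planar_flag`, and the
#'   scalar `tortuosity`.
#' @examples
#' th <- seq(0, pi, length.out = 100)
#' half_circle <- centerline(cbind(0.05 * cos(th), 0.05 * sin(th), 0))
#' m <- frenet_metrics(half_circle)
#' summary(m$curvature)  # ~ 1/0.05 = 20 per metre
#' @export
frenet_metrics <- function(c3, smoothing = 0, eps = 1e-10) {
  stopifnot(inherits(c3, "centerline"))
  check_scalar(smoothing, "smoothing", nonnegative = TRUE)
  pts <- c3$points
  arc <- c3$arc
  if (smoothing > 0) {
    pts <- vapply(1:3, function(j) {
      stats::predict(stats::smooth.spline(arc, pts[, j], spar = smoothing),
                     arc)$y
    }, numeric(nrow(pts)))
  }
  d <- frenet_derivatives(arc, pts)
  cr <- cbind(d$d1[, 2] * d$d2[, 3] - d$d1[, 3] * d$d2[, 2],
              d$d1[, 3] * d$d2[, 1] - d$d1[, 1] * d$d2[, 3],
              d$d1[, 1] * d$d2[, 2] - d$d1[, 2] * d$d2[, 1])
  cr_norm <- sqrt(rowSums(cr^2))
  speed <- sqrt(rowSums(d$d1^2))
  curvature <- cr_norm / pmax(speed, .Machine$double.xmin)^3
  planar <- cr_norm < eps
  torsion <- ifelse(planar, 0, rowSums(cr * d$d3) / pmax(cr_norm, eps)^2)
  structure(list(curvature = curvature, torsion = torsion,
                 planar_flag = planar, tortuosity = tortuosity(c3)),
            class = "geometry_metrics")
}

#' @export
print.geometry_metrics <- function(x, ...) {
  cat(sprintf(
    "<geometry_metrics> %d points: kappa [%.3g, %.3g] 1/m, tau [%.3g, %.3g] 1/m\n",
    length(x$curvature), min(x$curvature), max(x$curvature),
    min(x$torsion), max(x$torsion)))
  cat(sprintf("  tortuosity %.4g, %d planar-flagged points\n",
              x$tortuosity, sum(x$planar_flag)))
  invisible(x)
}

#' Construct a graft model
#'
#' A graft is a centerline plus axial stations, each carrying a baseline
#' lumen area, the current intimal area, and a media area. The media area is
#' held constant through remodeling; the intima may grow but never fills the
#' lumen completely.
#'
#' @param c3 a [centerline].
#' @param stations data frame with columns `s` (arc position m, strictly
#'   increasing, within the centerline arc range), `A_base` (baseline lumen
#'   area m^2), `A_intima` (intimal area m^2, `0 <= A_intima < A_base`),
#'   `A_media` (media area m^2, > 0), `region` (one of
#'   `"proximal_anastomosis"`, `"mid_graft"`, `"distal_anastomosis"`).
#' @return an object of class `graft_model`.
#' @export
graft_model <- function(c3, stations) {
  stopifnot(inherits(c3, "centerline"))
  need <- c("s", "A_base", "A_intima", "A_media", "region")
  stop_if(!is.data.frame(stations) || !all(need %in% names(stations)),
          sprintf("'stations' must be a data frame with columns: %s",
                  paste(need, collapse = ", ")))
  stations <- stations[need]
  stop_if(nrow(stations) < 1, "at least one station is required")
  stop_if(any(diff(stations$s) <= 0),
          "station arc positions must be strictly increasing")
  stop_if(stations$s[1] < -1e-12 ||
            stations$s[nrow(stations)] > max(c3$arc) * (1 + 1e-9),
          "station arc positions must lie within the centerline arc range")
  stop_if(any(stations$A_base <= 0), "baseline lumen areas must be > 0")
  stop_if(any(stations$A_intima < 0) ||
            any(stations$A_intima >= stations$A_base),
          "intimal area must satisfy 0 <= A_intima < A_base at every station")
  stop_if(any(stations$A_media <= 0), "media area must be > 0")
  regions <- c("proximal_anastomosis", "mid_graft", "distal_anastomosis")
  stop_if(!all(stations$region %in% regions),
          sprintf("station regions must be one of: %s",
                  paste(regions, collapse = ", ")))
  rownames(stations) <- NULL
  structure(list(centerline = c3, stations = stations), class = "graft_model")
}

#' @export
print.graft_model <- function(x, ...) {
  st <- x$stations
  cat(sprintf("<graft_model> %d stations over %.4g m\n",
              nrow(st), max(st$s) - min(st$s)))
  cat(sprintf("  lumen radius [%.3g, %.3g] mm, max stenosis %.1f%%\n",
              min(lumen_radius(x)) * 1e3, max(lumen_radius(x)) * 1e3,
              max(100 * st$A_intima / st$A_base)))
  invisible(x)
}

#' Current lumen radius at graft stations
#'
#' `r = sqrt((A_base - A_intima) / pi)` under the axisymmetric (circular
#' lumen, concentric intima) assumption.
#'
#' @param g a [graft_model].
#' @param station optional station indices; default all.
#' @return lumen radii in m.
#' @export
lumen_radius <- function(g, station = NULL) {
  stopifnot(inherits(g, "graft_model"))
  st <- g$stations
  if (!is.null(station)) {
    stop_if(any(station < 1) || any(station > nrow(st)),
            "invalid station index")
    st <- st[station, , drop = FALSE]
  }
  sqrt((st$A_base - st$A_intima) / pi)
}

# planar bowed centerline with exact arc length L: curve
# (x, bow*sin(pi*x/X), 0), X solved so the arc length equals L
bowed_centerline <- function(L, bow, s_stations) {
  if (bow <= 0) {
    return(centerline(cbind(s_stations, 0, 0)))
  }
  arc_of <- function(X) {
    u <- seq(0, X, length.out = 4097)
    dy <- bow * pi / X * cos(pi * u / X)
    sum(sqrt(1 + dy^2)) * X / 4096 -
      (sqrt(1 + dy[1]^2) + sqrt(1 + dy[4097]^2)) * X / 8192
  }
  X <- stats::uniroot(function(X) arc_of(X) - L, c(L / 4, L),
                      tol = 1e-12)$root
  u <- seq(0, X, length.out = 4097)
  y <- bow * sin(pi * u / X)
  s_fine <- c(0, cumsum(sqrt(diff(u)^2 + diff(y)^2)))
  s_fine <- s_fine / max(s_fine) * L
  ux <- stats::approx(s_fine, u, xout = pmin(s_stations, L))$y
  pts <- cbind(ux, bow * sin(pi * ux / X), 0)
  # scale so the chordal arc of the station-resolution polyline is exactly L
  chord_arc <- sum(sqrt(rowSums(diff(pts)^2)))
  centerline(pts * (L / chord_arc))
}

#' Build a synthetic axisymmetric bypass graft
#'
#' Stands in for a segmented patient geometry: a single conduit whose radius
#' tapers with a smooth cosine transition from the anastomosis caliber at
#' both ends to the body caliber in between, with zero intima everywhere and
#' a constant-thickness media annulus. Region labels are assigned by arc
#' position: stations within one transition length of either end are the
#' proximal/distal anastomoses.
#'
#' @param graft_length total centerline length in m.
#' @param body_radius mid-graft lumen radius in m.
#' @param anastomosis_radius lumen radius at both anastomoses in m.
#' @param transition_length length of each cosine taper in m.
#' @param spacing station spacing in m.
#' @param media_thickness media wall thickness in m (constant annulus).
#' @param bow_height out-of-axis bow of the centerline in m (planar arc;
#'   0 gives a straight conduit).
#' @return a [graft_model] with `A_intima = 0` at every station.
#' @examples
#' g <- build_synthetic_graft()
#' g
#' @export
build_synthetic_graft <- function(graft_length = 0.4,
                                  body_radius = 2.5e-3,
                                  anastomosis_radius = 3.5e-3,
                                  transition_length = 0.03,
                                  spacing = 5e-3,
                                  media_thickness = 5e-4,
                                  bow_height = 0.02) {
  check_scalar(graft_length, "graft_length", positive = TRUE)
  check_scalar(body_radius, "body_radius", positive = TRUE)
  check_scalar(anastomosis_radius, "anastomosis_radius", positive = TRUE)
  check_scalar(transition_length, "transition_length", nonnegative = TRUE)
  check_scalar(spacing, "spacing", positive = TRUE)
  check_scalar(media_thickness, "media_thickness", positive = TRUE)
  check_scalar(bow_height, "bow_height", nonnegative = TRUE)
  stop_if(2 * transition_length > graft_length,
          "transition lengths exceed the graft length")
  n_seg <- round(graft_length / spacing)
  s <- seq(0, n_seg) * spacing
  s[length(s)] <- min(s[length(s)], graft_length)
  taper <- function(dist_from_end) {
    w <- numeric(length(dist_from_end))
    if (transition_length > 0) {
      inside <- dist_from_end < transition_length
      w[inside] <- 0.5 * (1 + cos(pi * dist_from_end[inside] /
                                    transition_length))
    } else {
      w[dist_from_end == 0] <- 1
    }
    w
  }
  w <- pmin(1, taper(s) + taper(graft_length - s))
  r <- body_radius + (anastomosis_radius - body_radius) * w
  region <- rep("mid_graft", length(s))
  region[s <= transition_length] <- "proximal_anastomosis"
  region[s >= graft_length - transition_length] <- "distal_anastomosis"
  if (transition_length == 0) {
    region[1] <- "proximal_anastomosis"
    region[length(s)] <- "distal_anastomosis"
  }
  stations <- data.frame(
    s = s,
    A_base = pi * r^2,
    A_intima = 0,
    A_media = pi * ((r + media_thickness)^2 - r^2),
    region = region,
    stringsAsFactors = FALSE
  )
  graft_model(bowed_centerline(graft_length, bow_height, s), stations)
}

#' Read a graft model from a centerline/radius CSV
#'
#' Expected header `x,y,z,radius` (SI units); optional columns `A_intima`,
#' `A_media` and `region` are honored, otherwise the intima starts at zero,
#' the media is a constant-thickness annulus, and regions are labeled by arc
#' position with anastomoses covering `anastomosis_fraction` of the length at
#' either end.
#'
#' @param path CSV path.
#' @param media_thickness media thickness in m used when no `A_media` column
#'   is present.
#' @param anastomosis_fraction fraction of arc length labeled as anastomosis
#'   at each end when no `region` column is present.
#' @return a [graft_model].
#' @export
read_graft_csv <- function(path, media_thickness = 5e-4,
                           anastomosis_fraction = 0.1) {
  stop_if(!file.exists(path), sprintf("graft file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("x", "y", "z", "radius")
  stop_if(!all(need %in% names(df)),
          sprintf("graft CSV '%s' must have header 'x,y,z,radius'", path))
  c3 <- centerline(as.matrix(df[, c("x", "y", "z")]))
  L <- max(c3$arc)
  r <- df$radius
  stop_if(any(r <= 0), "graft radii must be > 0")
  region <- if ("region" %in% names(df)) df$region else {
    reg <- rep("mid_graft", length(r))
    reg[c3$arc <= anastomosis_fraction * L] <- "proximal_anastomosis"
    reg[c3$arc >= (1 - anastomosis_fraction) * L] <- "distal_anastomosis"
    reg
  }
  A_intima <- if ("A_intima" %in% names(df)) df$A_intima else 0
  A_media <- if ("A_media" %in% names(df)) df$A_media else {
    pi * ((r + media_thickness)^2 - r^2)
  }
  graft_model(c3, data.frame(s = c3$arc, A_base = pi * r^2,
                             A_intima = A_intima, A_media = A_media,
                             region = region, stringsAsFactors = FALSE))
}

#' Write a graft model to CSV
#'
#' Round-trips through [read_graft_csv()]: columns `x,y,z,radius` plus
#' `A_intima,A_media,region`. The radius written is the baseline lumen radius
#' `sqrt(A_base/pi)` so that the baseline geometry survives the round trip;
#' the current lumen state is carried by `A_intima`.
#'
#' @param g a [graft_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graft_csv <- function(g, path) {
  stopifnot(inherits(g, "graft_model"))
  pts <- vapply(1:3, function(j) {
    stats::approx(g$centerline$arc, g$centerline$points[, j],
                  xout = g$stations$s, rule = 2)$y
  }, numeric(nrow(g$stations)))
  df <- data.frame(x = fmt_num(pts[, 1]), y = fmt_num(pts[, 2]),
                   z = fmt_num(pts[, 3]),
                   radius = fmt_num(sqrt(g$stations$A_base / pi)),
                   A_intima = fmt_num(g$stations$A_intima),
                   A_media = fmt_num(g$stations$A_media),
                   region = g$stations$region)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
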