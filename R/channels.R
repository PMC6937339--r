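#' Construct a sensor stream
#'
#' One body-worn tri-axial accelerometer record. Samples are irregularly
#' spaced in time: the hardware reports at 29 Hz roughly 70% of the time and
#' at 58 Hz otherwise, depending on radio synchronisation.
#'
#' @param t Numeric vector of timestamps in seconds from session start,
#'   strictly increasing, length >= 2.
#' @param a Numeric matrix with `length(t)` rows and 3 columns (x, y, z
#'   acceleration in units of g; a hanging sensor at rest reads about
#'   (0, -1, 0)).
#' @param sensor_id Identifier string.
#' @param placement Body-segment label, e.g. `"thigh_L"`.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(t, a, sensor_id = placement, placement) {
  t <- as.numeric(t)
  a <- as.matrix(a)
  if (length(t) < 2) stop("sensor stream needs at least 2 samples", call. = FALSE)
  if (ncol(a) != 3 || nrow(a) != length(t)) {
    stop("'a' must be a length(t) x 3 matrix", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("timestamps must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  colnames(a) <- c("ax", "ay", "az")
  structure(list(t = t, a = a, sensor_id = sensor_id, placement = placement),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf("<sensor_stream> %s (%s): %d samples over %.1f s (mean %.1f Hz)\n",
              x$sensor_id, x$placement, length(x$t), dur,
              (length(x$t) - 1) / dur))
  invisible(x)
}

#' Resample a sensor stream onto a uniform grid
#'
#' Linearly interpolates each axis onto an arithmetic time grid at `rate_hz`
#' spanning the original record; no extrapolation beyond the recorded span.
#' On a stream that is already uniform at `rate_hz` this is the identity at
#' the shared grid points.
#'
#' @param stream A [sensor_stream()].
#' @param rate_hz Target sampling rate in Hz (default 29, the dominant native
#'   rate; 58 Hz segments are down-sampled rather than the 29 Hz segments
#'   up-sampled, so no data is invented).
#' @return A `sensor_stream` on the uniform grid.
#' @export
resample_uniform <- function(stream, rate_hz = 29) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("'rate_hz' must be a positive number", call. = FALSE)
  }
  grid <- uniform_grid(stream$t[1], stream$t[length(stream$t)], rate_hz)
  a <- vapply(1:3, function(j) {
    stats::approx(stream$t, stream$a[, j], xout = grid)$y
  }, numeric(length(grid)))
  sensor_stream(grid, a, stream$sensor_id, stream$placement)
}

uniform_grid <- function(t0, t1, rate_hz) {
  n <- floor((t1 - t0) * rate_hz + 1e-9) + 1
  t0 + (seq_len(n) - 1) / rate_hz
}

#' Inclination angle of a sensor from its gravity reading
#'
#' Resolves the gravity direction within a declared sensor plane via the
#' two-argument arctangent. With the default x--y convention the angle is 0
#' degrees when the sensor y-axis is anti-parallel to gravity (hanging limb,
#' reading (0, -1, 0)) and +/-90 degrees when perpendicular; range
#' (-180, 180].
#'
#' Samples whose in-plane gravity component is below `floor_g` are
#' ill-conditioned (gravity nearly orthogonal to the measurement plane) and
#' returned as `NA` so they can be gap-filled downstream.
#'
#' @param a Numeric length-3 vector, or an n x 3 matrix of readings in g.
#' @param plane Two-character axis-pair: `"xy"` (lateral) or `"zy"`
#'   (sagittal). The first axis supplies the sine component, the second the
#'   cosine component.
#' @param sign +1 or -1, orients the positive (avatar-up) direction.
#' @param floor_g Minimum in-plane gravity magnitude in g (default 0.05).
#' @return Angle(s) in degrees, `NA` where ill-conditioned.
#' @export
#' @examples
#' inclination_angle(c(0, -1, 0))            # 0: hanging
#' inclination_angle(c(-1, 0, 0))            # 90: perpendicular
inclination_angle <- function(a, plane = "xy", sign = 1, floor_g = 0.05) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = FALSE)
  idx <- plane_axes(plane)
  u <- a[, idx[1]]
  v <- a[, idx[2]]
  ang <- sign * atan2(-u, -v) * 180 / pi
  ang[sqrt(u^2 + v^2) < floor_g] <- NA_real_
  if (length(ang) == 1) ang <- as.numeric(ang)
  ang
}

plane_axes <- function(plane) {
  ax <- c(x = 1L, y = 2L, z = 3L)
  p <- strsplit(plane, "")[[1]]
  if (length(p) != 2 || !all(p %in% names(ax))) {
    stop("unknown axis plane '", plane, "'", call. = FALSE)
  }
  unname(ax[p])
}

#' Joint channel: an angle trace on a uniform grid
#'
#' @param t_grid Uniform time vector in seconds.
#' @param angle Angle trace in degrees, finite everywhere.
#' @param name Channel label from the fixed vocabulary.
#' @param rate_hz Sampling rate of `t_grid`.
#' @return Object of class `joint_channel`.
#' @export
joint_channel <- function(t_grid, angle, name, rate_hz) {
  t_grid <- as.numeric(t_grid)
  angle <- as.numeric(angle)
  stopifnot(length(t_grid) == length(angle))
  if (length(t_grid) >= 3) {
    dt <- diff(t_grid)
    if (max(abs(dt - 1 / rate_hz)) > 1e-9) {
      stop("'t_grid' is not uniform at rate_hz", call. = FALSE)
    }
  }
  if (any(!is.finite(angle))) {
    stop("channel angle trace contains non-finite values", call. = FALSE)
  }
  structure(list(t = t_grid, angle = angle, name = name, rate_hz = rate_hz),
            class = "joint_channel")
}

#' @export
print.joint_channel <- function(x, ...) {
  cat(sprintf("<joint_channel> %s: %d samples @ %g Hz, range [%.1f, %.1f] deg\n",
              x$name, length(x$t), x$rate_hz, min(x$angle), max(x$angle)))
  invisible(x)
}

#' @export
plot.joint_channel <- function(x, ...) {
  graphics::plot(x$t, x$angle, type = "l", xlab = "time (s)",
                 ylab = "angle (deg)", main = x$name, ...)
  invisible(x)
}

#' Joint angle from a proximal--distal sensor pair
#'
#' The proximal sensor acts as reference for the distal one: the joint angle
#' is the pointwise difference distal - proximal, so any rigid co-movement of
#' the whole pair (proximal compensation, e.g. shoulder anteversion during
#' elbow play) cancels exactly and cannot steer the avatar.
#'
#' @param proximal,distal Numeric angle traces (degrees) on the identical
#'   uniform grid.
#' @return Numeric trace of distal - proximal.
#' @export
pair_angle <- function(proximal, distal) {
  if (length(proximal) != length(distal)) {
    stop("proximal and distal traces are on different grids", call. = FALSE)
  }
  distal - proximal
}

#' Zero-phase low-pass filter of a joint channel
#'
#' Forward-backward (zero-phase) 2nd-order Butterworth low-pass. The trace is
#' extended by edge reflection before filtering so start/end transients do not
#' leak into the analysis window. Constant traces pass unchanged.
#'
#' @param channel A [joint_channel()] (or bare numeric trace with `rate_hz`
#'   supplied).
#' @param cutoff_hz Cutoff frequency, must be below the Nyquist rate
#'   (default 3 Hz: voluntary joint movement lives well below 3 Hz).
#' @param rate_hz Required when `channel` is a bare numeric vector.
#' @return Filtered object of the same kind as the input.
#' @export
lowpass_filter <- function(channel, cutoff_hz = 3, rate_hz = NULL) {
  if (inherits(channel, "joint_channel")) {
    y <- lowpass_vec(channel$angle, cutoff_hz, channel$rate_hz)
    return(joint_channel(channel$t, y, channel$name, channel$rate_hz))
  }
  if (is.null(rate_hz)) stop("'rate_hz' required for a bare trace", call. = FALSE)
  lowpass_vec(as.numeric(channel), cutoff_hz, rate_hz)
}

lowpass_vec <- function(x, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2) {
    stop("cutoff must be below the Nyquist frequency (", rate_hz / 2, " Hz)",
         call. = FALSE)
  }
  n <- length(x)
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * rate_hz))
  if (pad > 0) {
    # reflect about the end points so the padded signal is continuous
    head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(bf, xp)
  y[seq(pad + 1, pad + n)]
}

#' Time derivative of a joint channel
#'
#' Central differences in the interior, one-sided at the ends. A constant
#' trace differentiates to exactly zero everywhere: a player who holds a
#' wrong but constant posture in a non-target joint is not penalized, since
#' the involuntary-movement metric looks at changes in joint position, not
#' absolute position.
#'
#' @param channel A [joint_channel()] or bare numeric trace.
#' @param rate_hz Required for a bare trace.
#' @return Numeric trace in deg/s.
#' @export
channel_derivative <- function(channel, rate_hz = NULL) {
  if (inherits(channel, "joint_channel")) {
    x <- channel$angle
    rate_hz <- channel$rate_hz
  } else {
    if (is.null(rate_hz)) stop("'rate_hz' required for a bare trace", call. = FALSE)
    x <- as.numeric(channel)
  }
  n <- length(x)
  if (n < 3) stop("derivative needs at least 3 samples", call. = FALSE)
  h <- 1 / rate_hz
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / h
  d[n] <- (x[n] - x[n - 1]) / h
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d
}

# Fill NA runs up to max_gap_s by linear interpolation; returns list(y, ok).
# ok = FALSE when a longer gap (or an un-bridgeable edge gap) remains.
fill_gaps <- function(y, rate_hz, max_gap_s = 0.5) {
  if (!anyNA(y)) return(list(y = y, ok = TRUE))
  idx <- which(!is.na(y))
  if (length(idx) < 2) return(list(y = y, ok = FALSE))
  runs <- rle(is.na(y))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  max_run <- max(runs$lengths[runs$values])
  edge_na <- is.na(y[1]) || is.na(y[length(y)])
  if (max_run / rate_hz > max_gap_s || edge_na) {
    return(list(y = y, ok = FALSE))
  }
  yi <- stats::approx(idx, y[idx], xout = seq_along(y))$y
  list(y = yi, ok = TRUE)
}

#' Compute all joint channels of a session
#'
#' Runs the full sensor-to-angle pipeline for every channel in the
#' extremity's table: both pair members are resampled onto a common uniform
#' grid, converted to inclination angles in the channel's measurement plane,
#' differenced (distal - proximal) and zero-phase low-pass filtered.
#' Ill-conditioned samples are gap-filled by linear interpolation up to
#' `max_gap_s`; longer gaps, or a missing sensor, mark the channel missing
#' rather than failing the session.
#'
#' @param streams List of [sensor_stream()] objects (any order); matched to
#'   the channel table by their `placement` labels.
#' @param extremity `"LE"` or `"UE"`.
#' @param rate_hz Uniform processing rate (default 29 Hz).
#' @param cutoff_hz Low-pass cutoff (default 3 Hz).
#' @param floor_g Ill-conditioning floor for [inclination_angle()].
#' @param max_gap_s Longest ill-conditioned gap bridged by interpolation.
#' @param table Channel table; defaults to [channel_table()] for the
#'   extremity.
#' @return Object of class `channel_set`: list with `channels` (named list of
#'   [joint_channel()]), `missing` (character vector of channels that could
#'   not be computed), `t` (the common grid) and `rate_hz`.
#' @export
compute_joint_channels <- function(streams, extremity, rate_hz = 29,
                                   cutoff_hz = 3, floor_g = 0.05,
                                   max_gap_s = 0.5, table = NULL) {
  if (is.null(table)) table <- channel_table(extremity)
  names(streams) <- vapply(streams, function(s) s$placement, character(1))
  have <- names(streams)
  t0 <- max(vapply(streams, function(s) s$t[1], numeric(1)))
  t1 <- min(vapply(streams, function(s) s$t[length(s$t)], numeric(1)))
  if (t1 <= t0) stop("sensor streams do not overlap in time", call. = FALSE)
  grid <- uniform_grid(t0, t1, rate_hz)

  # resample + inclination once per (sensor, plane) combination
  incl_cache <- new.env(parent = emptyenv())
  sensor_angle <- function(placement, plane) {
    key <- paste(placement, plane)
    if (!is.null(incl_cache[[key]])) return(incl_cache[[key]])
    s <- streams[[placement]]
    a <- vapply(1:3, function(j) stats::approx(s$t, s$a[, j], xout = grid)$y,
                numeric(length(grid)))
    ang <- inclination_angle(a, plane = plane, floor_g = floor_g)
    incl_cache[[key]] <- ang
    ang
  }

  channels <- list()
  missing <- character()
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (!(row$proximal %in% have) || !(row$distal %in% have)) {
      missing <- c(missing, row$channel)
      next
    }
    prox <- sensor_angle(row$proximal, row$plane)
    dist <- sensor_angle(row$distal, row$plane)
    raw <- row$sign * pair_angle(prox, dist)
    filled <- fill_gaps(raw, rate_hz, max_gap_s)
    if (!filled$ok) {
      missing <- c(missing, row$channel)
      next
    }
    ang <- lowpass_vec(filled$y, cutoff_hz, rate_hz)
    channels[[row$channel]] <- joint_channel(grid, ang, row$channel, rate_hz)
  }
  structure(list(channels = channels, missing = missing, t = grid,
                 rate_hz = rate_hz, extremity = extremity),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %s: %d channels on %d-sample grid @ %g Hz\n",
              x$extremity, length(x$channels), length(x$t), x$rate_hz))
  if (length(x$missing)) {
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
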