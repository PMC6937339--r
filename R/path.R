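#' Generate the 30 s target path
#'
#' The path the avatar must follow, expressed in percent of the calibrated
#' active range of motion. It is designed to challenge the player within 90%
#' of the calibrated range, realised as the centred band \[5, 95\]: a smooth
#' cubic interpolation through waypoints that reaches at least once below 10
#' and above 90. Deterministic: the same waypoints (or the same seed, when
#' waypoints are drawn randomly) always produce the identical path.
#'
#' @param duration_s Path duration in seconds (default 30).
#' @param rate_hz Grid rate (default 29 Hz).
#' @param waypoints Data frame with columns `time_s`, `percent`; defaults to
#'   the built-in set ([default_waypoints()]). All percents must lie in
#'   \[5, 95\].
#' @param seed Optional integer; when given and `waypoints` is `NULL`, a
#'   random waypoint set touching both band extremes is drawn reproducibly.
#' @param star_every_s Spacing of the (cosmetic) star timestamps.
#' @return Object of class `target_path`: list with `t` (uniform grid over
#'   \[0, duration\]), `p_star` (percent, in \[5, 95\]), `star_times`,
#'   `rate_hz`, `waypoints`.
#' @export
generate_target_path <- function(duration_s = 30, rate_hz = 29,
                                 waypoints = NULL, seed = NULL,
                                 star_every_s = 2) {
  if (is.null(waypoints)) {
    if (is.null(seed)) {
      waypoints <- default_waypoints()
    } else {
      waypoints <- random_waypoints(duration_s, seed)
    }
  }
  stopifnot(is.data.frame(waypoints),
            all(c("time_s", "percent") %in% names(waypoints)))
  if (any(waypoints$percent < 5 - 1e-9) || any(waypoints$percent > 95 + 1e-9)) {
    stop("waypoints must lie within the [5, 95] percent band", call. = FALSE)
  }
  grid <- (seq_len(round(duration_s * rate_hz) + 1) - 1) / rate_hz
  if (nrow(waypoints) == 1) {
    p <- rep(waypoints$percent[1], length(grid))
  } else {
    f <- stats::splinefun(waypoints$time_s, waypoints$percent,
                          method = "natural")
    p <- f(grid)
    # a natural cubic spline may overshoot between waypoints; the game screen
    # clamps the path to the playable band
    p <- pmin(95, pmax(5, p))
  }
  structure(list(t = grid, p_star = p,
                 star_times = seq(0, duration_s, by = star_every_s),
                 rate_hz = rate_hz, waypoints = waypoints),
            class = "target_path")
}

random_waypoints <- function(duration_s, seed) {
  set.seed(seed)
  times <- seq(0, duration_s, by = 3)
  n <- length(times)
  percent <- stats::runif(n, 5, 95)
  # guarantee the path spans the band
  lo_at <- sample(2:(n - 1), 1)
  hi_at <- sample(setdiff(2:(n - 1), lo_at), 1)
  percent[lo_at] <- stats::runif(1, 5, 8)
  percent[hi_at] <- stats::runif(1, 92, 95)
  data.frame(time_s = times, percent = percent)
}

#' @export
print.target_path <- function(x, ...) {
  cat(sprintf("<target_path> %.0f s @ %g Hz, range [%.1f, %.1f] %%\n",
              max(x$t), x$rate_hz, min(x$p_star), max(x$p_star)))
  invisible(x)
}

#' @export
plot.target_path <- function(x, ...) {
  graphics::plot(x$t, x$p_star, type = "l", ylim = c(0, 100),
                 xlab = "time (s)", ylab = "target position (% aROM)", ...)
  graphics::abline(h = c(5, 95), lty = 3)
  graphics::points(x$star_times,
                   stats::approx(x$t, x$p_star, xout = x$star_times)$y,
                   pch = 8)
  invisible(x)
}

#' Avatar position from the target-joint angle
#'
#' Maps the target-joint angle to screen position as percent of the
#' calibrated active range of motion:
#' `p(t) = 100 * (theta(t) - arom_min) / (arom_max - arom_min)`, clipped to
#' \[0, 100\] (the avatar cannot leave the screen). Because the calibration
#' bounds and the angle shift together under recalibration, the percentage is
#' invariant to a common offset.
#'
#' @param target_channel A [joint_channel()] of the target joint (or bare
#'   numeric angle trace).
#' @param calibration A playable [arom_calibration()].
#' @return Object of class `avatar_trace` (list with `t`, `p`) when given a
#'   `joint_channel`; bare numeric percent trace otherwise.
#' @export
avatar_position <- function(target_channel, calibration) {
  stopifnot(inherits(calibration, "arom_calibration"))
  if (!isTRUE(calibration$playable)) {
    stop("target joint '", calibration$joint, "' is not playable: ",
         calibration$reason, call. = FALSE)
  }
  span <- calibration$arom_max - calibration$arom_min
  to_pct <- function(theta) {
    pmin(100, pmax(0, 100 * (theta - calibration$arom_min) / span))
  }
  if (inherits(target_channel, "joint_channel")) {
    structure(list(t = target_channel$t, p = to_pct(target_channel$angle)),
              class = "avatar_trace")
  } else {
    to_pct(as.numeric(target_channel))
  }
}

#' Restrict a trace to the analysis window
#'
#' The last seconds of play keep the player engaged until the end but are not
#' analyzed: the analysis window is the first `duration_s - discard_tail_s`
#' seconds (default: first 25 s of the 30 s recording).
#'
#' @param x A [joint_channel()], [target_path()], `avatar_trace`, or bare
#'   numeric trace (then interpreted on a grid at `rate_hz` starting at its
#'   first element's time 0).
#' @param duration_s Full recording duration expected (default 30).
#' @param discard_tail_s Seconds discarded at the end (default 5).
#' @param rate_hz Needed for bare numeric traces.
#' @return The windowed object, same class as the input.
#' @export
analysis_window <- function(x, duration_s = 30, discard_tail_s = 5,
                            rate_hz = NULL) {
  keep_s <- duration_s - discard_tail_s
  window_idx <- function(t) {
    if (max(t) < duration_s - 1e-9) {
      stop("trace covers only ", round(max(t), 2), " s but the analysis ",
           "window requires ", duration_s, " s", call. = FALSE)
    }
    if (discard_tail_s <= 0) return(seq_along(t))
    which(t - t[1] < keep_s - 1e-9)
  }
  if (inherits(x, "joint_channel")) {
    i <- window_idx(x$t)
    return(joint_channel(x$t[i], x$angle[i], x$name, x$rate_hz))
  }
  if (inherits(x, "target_path")) {
    i <- window_idx(x$t)
    out <- x
    out$t <- x$t[i]
    out$p_star <- x$p_star[i]
    return(out)
  }
  if (inherits(x, "avatar_trace")) {
    i <- window_idx(x$t)
    return(structure(list(t = x$t[i], p = x$p[i]), class = "avatar_trace"))
  }
  if (is.null(rate_hz)) stop("'rate_hz' required for a bare trace", call. = FALSE)
  t <- (seq_along(x) - 1) / rate_hz
  x[window_idx(t)]
}
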