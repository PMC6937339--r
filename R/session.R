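#' Process a recorded session into scoring inputs
#'
#' Runs the whole signal pipeline for one play-through: sensor streams to
#' filtered joint channels, analysis windowing, avatar position of the target
#' joint, and joint-angle derivatives of every monitored channel.
#'
#' @param streams List of [sensor_stream()] objects, or a [sim_session()]
#'   (whose streams, calibration, path and metadata are then used).
#' @param extremity `"LE"` or `"UE"`.
#' @param target_joint Channel label of the played joint.
#' @param calibration A playable [arom_calibration()] for the target joint.
#' @param path The session's [target_path()].
#' @param duration_s,discard_tail_s Analysis window (defaults 30 s, last 5 s
#'   discarded).
#' @param rate_hz,cutoff_hz Processing rate and low-pass cutoff.
#' @param meta Optional named list of session metadata (id, age, group, side).
#' @return Object of class `svmc_session`: `t` (windowed grid), `avatar_p`
#'   (percent), `p_star`, `derivs` (matrix, one column per available
#'   channel, deg/s), `missing` channels, plus the inputs echoed back.
#' @export
process_session <- function(streams, extremity = NULL, target_joint = NULL,
                            calibration = NULL, path = NULL,
                            duration_s = 30, discard_tail_s = 5,
                            rate_hz = 29, cutoff_hz = 3, meta = list()) {
  if (inherits(streams, "sim_session")) {
    sim <- streams
    if (is.null(extremity)) extremity <- sim$extremity
    if (is.null(target_joint)) target_joint <- sim$target_joint
    if (is.null(calibration)) calibration <- sim$calibration
    if (is.null(path)) path <- sim$path
    if (!length(meta)) meta <- sim$meta
    streams <- sim$streams
  }
  stopifnot(!is.null(extremity), !is.null(target_joint),
            inherits(calibration, "arom_calibration"),
            inherits(path, "target_path"))
  if (!isTRUE(calibration$playable)) {
    stop("target joint '", target_joint, "' is not playable: ",
         calibration$reason, call. = FALSE)
  }
  cs <- compute_joint_channels(streams, extremity, rate_hz = rate_hz,
                               cutoff_hz = cutoff_hz)
  if (target_joint %in% cs$missing) {
    stop("target channel '", target_joint, "' could not be computed",
         call. = FALSE)
  }
  wch <- lapply(cs$channels, analysis_window, duration_s = duration_s,
                discard_tail_s = discard_tail_s)
  wpath <- analysis_window(path, duration_s, discard_tail_s)
  tgt <- wch[[target_joint]]
  if (length(tgt$t) != length(wpath$t)) {
    stop("channel grid and path grid disagree (", length(tgt$t), " vs ",
         length(wpath$t), " samples); streams must cover [0, ", duration_s,
         "] s", call. = FALSE)
  }
  avatar <- avatar_position(tgt, calibration)
  derivs <- vapply(wch, channel_derivative, numeric(length(tgt$t)))
  structure(list(t = tgt$t, rate_hz = rate_hz, extremity = extremity,
                 target_joint = target_joint, calibration = calibration,
                 avatar_p = avatar$p, p_star = wpath$p_star,
                 derivs = derivs, missing = cs$missing, meta = meta),
            class = "svmc_session")
}

#' @export
print.svmc_session <- function(x, ...) {
  cat(sprintf("<svmc_session> %s target %s: %d channels, %d samples @ %g Hz\n",
              x$extremity, x$target_joint, ncol(x$derivs), length(x$t),
              x$rate_hz))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
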