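#' Calibrate the active range of motion of a target joint
#'
#' During the 10 s calibration recording the player moves the target joint
#' through its active range. The measured span is first capped at the joint's
#' maximum allowed movement (hip 45, knee 90, ankle 90 degrees; shoulder 70,
#' elbow 110, forearm 135, wrist 135; fingers uncapped), the cap being applied
#' symmetrically about the midpoint of the measured span, and then 5 degrees
#' are pruned off the top and bottom. A joint is playable only when the
#' remaining range reaches the minimum playable span (about 20 degrees) —
#' below that the steering resolution is too coarse for meaningful play.
#'
#' @param channel A [joint_channel()] holding the calibration recording (or a
#'   bare numeric angle trace).
#' @param joint Channel label of the target joint (determines the cap).
#' @param prune_deg Degrees removed from each end after capping (default 5;
#'   set 0 to disable).
#' @param min_playable_deg Minimum pruned span for a playable joint
#'   (default 20).
#' @param min_duration_s Minimum calibration length in seconds (default 5);
#'   ignored for bare traces without a time base.
#' @return Object of class `arom_calibration` with fields `joint`,
#'   `raw_min`, `raw_max`, `arom_min`, `arom_max`, `capped`, `playable`,
#'   `reason`.
#' @export
#' @examples
#' cal <- calibrate_arom(seq(0, 100, length.out = 300), "knee_L")
#' cal$arom_min; cal$arom_max   # capped to a 90-degree span, then pruned
calibrate_arom <- function(channel, joint, prune_deg = 5,
                           min_playable_deg = 20, min_duration_s = 5) {
  if (inherits(channel, "joint_channel")) {
    if (diff(range(channel$t)) < min_duration_s) {
      stop("calibration recording shorter than ", min_duration_s, " s",
           call. = FALSE)
    }
    trace <- channel$angle
  } else {
    trace <- as.numeric(channel)
  }
  raw_min <- min(trace)
  raw_max <- max(trace)
  cap <- joint_cap(joint)
  lo <- raw_min
  hi <- raw_max
  capped <- FALSE
  if (is.finite(cap) && (hi - lo) > cap) {
    mid <- (lo + hi) / 2
    lo <- mid - cap / 2
    hi <- mid + cap / 2
    capped <- TRUE
  }
  reason <- NA_character_
  if ((hi - lo) <= 2 * prune_deg) {
    # pruning would leave a non-positive range
    playable <- FALSE
    reason <- sprintf("span %.1f deg <= %.0f deg pruning allowance",
                      hi - lo, 2 * prune_deg)
    arom_min <- arom_max <- NA_real_
  } else {
    arom_min <- lo + prune_deg
    arom_max <- hi - prune_deg
    playable <- (arom_max - arom_min) >= min_playable_deg
    if (!playable) {
      reason <- sprintf("pruned span %.1f deg below minimum playable %.0f deg",
                        arom_max - arom_min, min_playable_deg)
    }
  }
  structure(list(joint = joint, raw_min = raw_min, raw_max = raw_max,
                 arom_min = arom_min, arom_max = arom_max,
                 capped = capped, playable = playable, reason = reason),
            class = "arom_calibration")
}

#' @export
print.arom_calibration <- function(x, ...) {
  cat(sprintf("<arom_calibration> %s: raw [%.1f, %.1f] deg%s\n",
              x$joint, x$raw_min, x$raw_max,
              if (x$capped) " (capped)" else ""))
  if (x$playable) {
    cat(sprintf("  playable aROM [%.1f, %.1f] deg (span %.1f)\n",
                x$arom_min, x$arom_max, x$arom_max - x$arom_min))
  } else {
    cat("  NOT playable:", x$reason, "\n")
  }
  invisible(x)
}

#' Construct a calibration directly from known bounds
#'
#' Convenience constructor used by the simulator and in tests when the active
#' range is known rather than measured; applies the same cap-and-prune rules
#' as [calibrate_arom()].
#' @param joint Target joint label.
#' @param raw_min,raw_max Measured extrema in degrees.
#' @inheritParams calibrate_arom
#' @return An `arom_calibration`.
#' @export
arom_from_bounds <- function(joint, raw_min, raw_max, prune_deg = 5,
                             min_playable_deg = 20) {
  calibrate_arom(c(raw_min, raw_max), joint, prune_deg = prune_deg,
                 min_playable_deg = min_playable_deg)
}
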