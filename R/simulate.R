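#' Impairment profile for the session simulator
#'
#' Parameterizes how a simulated player deviates from ideal selective play.
#' The phenomenology covers the main clinically described involuntary
#' movement classes: mirror movements of the contralateral homologous joint,
#' synergistic co-movement of other joints, trunk sway, and tremor, plus
#' imperfect tracking of the target path itself.
#'
#' @param tracking_noise_sd SD of smoothed tracking noise on the avatar
#'   position, in percent of aROM.
#' @param tracking_lag_s Delay between the target path and the player's
#'   response, in seconds.
#' @param mirror_gain Coupling of the contralateral homologue's angular
#'   velocity to the target joint's, dimensionless in \[0, 1.5\].
#' @param synergy_gains Named numeric vector: per-channel coupling of that
#'   channel's angular velocity to the target joint's.
#' @param trunk_sway_amp,trunk_sway_hz Amplitude (degrees) and frequency (Hz)
#'   of sinusoidal trunk sway.
#' @param tremor_amp,tremor_hz Amplitude (degrees) and frequency (Hz) of
#'   tremor added to the target joint.
#' @return Object of class `impairment_profile`.
#' @export
impairment_profile <- function(tracking_noise_sd = 0, tracking_lag_s = 0,
                               mirror_gain = 0, synergy_gains = NULL,
                               trunk_sway_amp = 0, trunk_sway_hz = 0.25,
                               tremor_amp = 0, tremor_hz = 5) {
  if (is.null(synergy_gains)) synergy_gains <- stats::setNames(numeric(0), character(0))
  stopifnot(tracking_noise_sd >= 0, tracking_lag_s >= 0,
            mirror_gain >= 0, mirror_gain <= 1.5,
            all(synergy_gains >= 0), trunk_sway_amp >= 0, trunk_sway_hz >= 0,
            tremor_amp >= 0, tremor_hz >= 0)
  structure(list(tracking_noise_sd = tracking_noise_sd,
                 tracking_lag_s = tracking_lag_s, mirror_gain = mirror_gain,
                 synergy_gains = synergy_gains,
                 trunk_sway_amp = trunk_sway_amp,
                 trunk_sway_hz = trunk_sway_hz,
                 tremor_amp = tremor_amp, tremor_hz = tremor_hz),
            class = "impairment_profile")
}

#' @export
print.impairment_profile <- function(x, ...) {
  cat(sprintf(paste0("<impairment_profile> noise %.1f%%, lag %.2f s, ",
                     "mirror %.2f, trunk %.1f deg @ %.2f Hz, tremor %.1f deg\n"),
              x$tracking_noise_sd, x$tracking_lag_s, x$mirror_gain,
              x$trunk_sway_amp, x$trunk_sway_hz, x$tremor_amp))
  if (length(x$synergy_gains)) {
    cat("  synergies:", paste(sprintf("%s=%.2f", names(x$synergy_gains),
                                      x$synergy_gains), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Contralateral homologue of a limb channel
#' @param channel Channel label ending in `_L` or `_R`.
#' @return The same joint on the other side.
#' @export
mirror_channel <- function(channel) {
  if (grepl("_L$", channel)) return(sub("_L$", "_R", channel))
  if (grepl("_R$", channel)) return(sub("_R$", "_L", channel))
  stop("channel '", channel, "' has no contralateral homologue", call. = FALSE)
}

# the next-proximal joint on the same side: the physiologically most likely
# synergy partner for a given target
synergy_partner <- function(target_joint) {
  side <- sub("^.*_", "", target_joint)
  stem <- sub("_[LR]$", "", target_joint)
  partner <- switch(stem,
    ankle = "knee", knee = "hip_flexion", hip_flexion = NA,
    hip_rotation = "hip_flexion",
    fingers = "wrist", wrist = "elbow", forearm_prosup = "elbow",
    elbow = "shoulder_abd", shoulder_abd = NA,
    NA)
  if (is.na(partner)) return(NA_character_)
  paste0(partner, "_", side)
}

#' Simulate ground-truth joint kinematics for one session
#'
#' The simulated player steers the target joint after the path (with lag,
#' smoothed tracking noise and optional tremor); the contralateral homologue
#' and any synergy channels move with angular velocity proportional to the
#' target's (so their derivative traces are exact scalings of the target
#' derivative); the trunk sways sinusoidally; all remaining channels hold
#' their neutral posture. All components are band-limited well below 5 Hz,
#' consistent with voluntary human movement.
#'
#' @param path A [target_path()].
#' @param calibration Playable [arom_calibration()] of the target joint.
#' @param target_joint Channel label being played.
#' @param extremity `"LE"` or `"UE"`.
#' @param profile An [impairment_profile()].
#' @param seed Optional integer; when non-`NULL`, seeds the RNG.
#' @return Object of class `sim_truth`: `t`, `rate_hz`, `angles` (matrix,
#'   one named column per channel, degrees), `p_played` (the noiseless-clip
#'   avatar percent actually executed).
#' @export
simulate_kinematics <- function(path, calibration, target_joint,
                                extremity = "LE",
                                profile = impairment_profile(),
                                seed = NULL) {
  stopifnot(inherits(path, "target_path"),
            inherits(calibration, "arom_calibration"),
            inherits(profile, "impairment_profile"))
  if (!isTRUE(calibration$playable)) {
    stop("calibration is not playable: ", calibration$reason, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- path$t
  n <- length(t)
  rate <- path$rate_hz

  p <- stats::approx(t, path$p_star, xout = t - profile$tracking_lag_s,
                     rule = 2)$y
  if (profile$tracking_noise_sd > 0) {
    eps <- lowpass_vec(stats::rnorm(n), 1.5, rate)
    eps <- eps / stats::sd(eps) * profile$tracking_noise_sd
    p <- p + eps
  }
  p <- pmin(100, pmax(0, p))
  span <- calibration$arom_max - calibration$arom_min
  theta <- calibration$arom_min + span * p / 100
  if (profile$tremor_amp > 0) {
    theta <- theta + profile$tremor_amp *
      sin(2 * pi * profile$tremor_hz * t + stats::runif(1, 0, 2 * pi))
  }

  rest <- rest_angles(extremity)
  angles <- matrix(rep(rest, each = n), nrow = n,
                   dimnames = list(NULL, names(rest)))
  angles[, target_joint] <- theta

  excursion <- theta - theta[1]
  if (profile$mirror_gain > 0) {
    mc <- mirror_channel(target_joint)
    angles[, mc] <- rest[mc] + profile$mirror_gain * excursion
  }
  for (ch in names(profile$synergy_gains)) {
    if (!ch %in% colnames(angles)) {
      stop("synergy channel '", ch, "' is not in the ", extremity,
           " channel table", call. = FALSE)
    }
    angles[, ch] <- angles[, ch] + profile$synergy_gains[[ch]] * excursion
  }
  if (profile$trunk_sway_amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    angles[, "trunk_lateral"] <- angles[, "trunk_lateral"] +
      profile$trunk_sway_amp * sin(2 * pi * profile$trunk_sway_hz * t + ph[1])
    angles[, "trunk_ventral"] <- angles[, "trunk_ventral"] +
      0.8 * profile$trunk_sway_amp *
        sin(2 * pi * profile$trunk_sway_hz * t + ph[2])
  }
  structure(list(t = t, rate_hz = rate, angles = angles, p_played = p,
                 target_joint = target_joint, extremity = extremity),
            class = "sim_truth")
}

#' Render ground-truth kinematics as accelerometer streams
#'
#' Quasi-static sensor model: each sensor reads the unit gravity vector
#' rotated by its cumulative segment orientation (the sum of all channel
#' angles along its proximal chain, sagittal and lateral planes composed in
#' sequence), plus white noise. This is justified by bench behaviour of the
#' hardware: movement-induced accelerations within the game's speed range are
#' a few percent of gravity. Timestamps are shared by all sensors (the radio
#' transmits only when every sensor has a reading) and alternate between
#' 29 Hz and 58 Hz segments with expected time fractions 0.7 / 0.3.
#'
#' @param truth A [simulate_kinematics()] result.
#' @param noise_sd Accelerometer white-noise SD in g (default 0.005, consistent with the bench repeatability of the hardware).
#' @param seed Optional integer seed.
#' @param compensation Optional list with numeric traces `zy` and/or `xy`
#'   (degrees, length of `truth$t`): a rigid rotation of the whole body added
#'   to every sensor, e.g. the player shifting on the seat. By construction
#'   it must not change any joint channel.
#' @param segment_dur_range Range (s) of the irregular-rate segments.
#' @param p58 Probability that a segment runs at 58 Hz.
#' @return List of [sensor_stream()] objects, one per sensor of the
#'   extremity's placement map.
#' @export
kinematics_to_accel <- function(truth, noise_sd = 0.005, seed = NULL,
                                compensation = NULL,
                                segment_dur_range = c(0.5, 2), p58 = 0.3) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  t <- truth$t
  duration <- t[length(t)]
  ts <- irregular_timestamps(duration, segment_dur_range, p58)
  chains <- sensor_chains(truth$extremity)

  comp_zy <- if (!is.null(compensation$zy)) compensation$zy else numeric(length(t))
  comp_xy <- if (!is.null(compensation$xy)) compensation$xy else numeric(length(t))

  streams <- lapply(names(chains), function(sensor) {
    ch <- chains[[sensor]]
    beta <- comp_zy
    alpha <- comp_xy
    for (c in ch$zy) beta <- beta + truth$angles[, c]
    for (c in ch$xy) alpha <- alpha + truth$angles[, c]
    a_rad <- stats::approx(t, alpha, xout = ts)$y * pi / 180
    b_rad <- stats::approx(t, beta, xout = ts)$y * pi / 180
    a <- cbind(-sin(a_rad),
               -cos(a_rad) * cos(b_rad),
               -sin(b_rad) * cos(a_rad))
    a <- a + matrix(stats::rnorm(length(ts) * 3, sd = noise_sd), ncol = 3)
    sensor_stream(ts, a, sensor_id = sensor, placement = sensor)
  })
  names(streams) <- names(chains)
  streams
}

# shared irregular timestamp vector: alternating-rate segments
irregular_timestamps <- function(duration, segment_dur_range = c(0.5, 2),
                                 p58 = 0.3) {
  ts <- numeric(0)
  t_cur <- 0
  while (t_cur < duration) {
    dur <- stats::runif(1, segment_dur_range[1], segment_dur_range[2])
    rate <- if (stats::runif(1) < p58) 58 else 29
    t_end <- min(t_cur + dur, duration)
    seg <- seq(t_cur, t_end, by = 1 / rate)
    ts <- c(ts, seg)
    t_cur <- seg[length(seg)] + 1 / rate
  }
  ts <- unique(c(ts, duration))
  ts[ts <= duration]
}

#' Simulate one complete session
#'
#' Convenience wrapper: generates (or accepts) the path and calibration,
#' simulates ground-truth kinematics under the given impairment profile, and
#' renders the accelerometer streams. Fully reproducible from `seed`.
#'
#' @inheritParams simulate_kinematics
#' @inheritParams kinematics_to_accel
#' @param calibration Defaults to a raw 0--40 degree active range for the
#'   target joint (a typical playable range well inside every cap).
#' @param path Defaults to the built-in waypoint path.
#' @param meta Named list of session metadata (id, age, group, side).
#' @param seed Integer seed driving every random element of the session.
#' @return Object of class `sim_session`: `streams`, `truth`, `path`,
#'   `calibration`, `target_joint`, `extremity`, `profile`, `meta`, `seed`.
#' @export
simulate_session <- function(target_joint = "ankle_L", extremity = "LE",
                             profile = impairment_profile(), seed = 1,
                             path = NULL, calibration = NULL,
                             noise_sd = 0.005, compensation = NULL,
                             meta = list()) {
  if (is.null(path)) path <- generate_target_path()
  if (is.null(calibration)) {
    calibration <- arom_from_bounds(target_joint, 0, 40)
  }
  set.seed(seed)
  truth <- simulate_kinematics(path, calibration, target_joint, extremity,
                               profile, seed = NULL)
  streams <- kinematics_to_accel(truth, noise_sd = noise_sd, seed = NULL,
                                 compensation = compensation)
  structure(list(streams = streams, truth = truth, path = path,
                 calibration = calibration, target_joint = target_joint,
                 extremity = extremity, profile = profile, meta = meta,
                 seed = seed),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s target %s, seed %d, %d sensors\n",
              x$extremity, x$target_joint, x$seed, length(x$streams)))
  print(x$profile)
  invisible(x)
}

#' Draw an impairment profile from a group-level prior
#'
#' The group priors are synthetic, tunable distributions that exist to
#' exercise the scoring pipeline, not to model real populations: `NIA`
#' (neurologically intact adults) have minimal impairment, `NIC` (intact
#' children) have mirror coupling that decreases with age (mirror movements
#' are physiological in young children and fade around age 10), and `P`
#' (patients) draw elevated, heterogeneous gains.
#'
#' @param group `"NIA"`, `"NIC"` or `"P"`.
#' @param age Age in years (drives the NIC mirror gain).
#' @param target_joint Target joint (selects the synergy partner channels).
#' @return An [impairment_profile()]. Uses the ambient RNG stream.
#' @export
draw_profile <- function(group = c("NIA", "NIC", "P"), age = 30,
                         target_joint = "ankle_L") {
  group <- match.arg(group)
  partner <- synergy_partner(target_joint)
  syn <- function(g) {
    if (is.na(partner) || g <= 0) return(NULL)
    stats::setNames(g, partner)
  }
  if (group == "NIA") {
    impairment_profile(
      tracking_noise_sd = stats::runif(1, 2, 4),
      tracking_lag_s = stats::runif(1, 0.1, 0.2),
      mirror_gain = min(1.5, abs(stats::rnorm(1, 0.02, 0.01))),
      synergy_gains = syn(abs(stats::rnorm(1, 0.03, 0.015))),
      trunk_sway_amp = stats::runif(1, 0.5, 1.5),
      trunk_sway_hz = stats::runif(1, 0.2, 0.35))
  } else if (group == "NIC") {
    impairment_profile(
      tracking_noise_sd = stats::runif(1, 3, 6),
      tracking_lag_s = stats::runif(1, 0.1, 0.3),
      mirror_gain = min(1.5, max(0, 0.35 - 0.03 * (age - 6)) +
                          abs(stats::rnorm(1, 0, 0.05))),
      synergy_gains = syn(abs(stats::rnorm(1, 0.05, 0.03))),
      trunk_sway_amp = stats::runif(1, 1, 2.5),
      trunk_sway_hz = stats::runif(1, 0.2, 0.35))
  } else {
    gains <- c(stats::runif(1, 0.1, 0.5), stats::runif(1, 0, 0.3))
    contra <- if (!is.na(partner)) mirror_channel(partner) else NA
    syn_g <- stats::setNames(gains, c(partner, contra))
    syn_g <- syn_g[!is.na(names(syn_g))]
    impairment_profile(
      tracking_noise_sd = stats::runif(1, 4, 10),
      tracking_lag_s = stats::runif(1, 0.15, 0.4),
      mirror_gain = stats::runif(1, 0.2, 1.0),
      synergy_gains = syn_g,
      trunk_sway_amp = stats::runif(1, 1, 6),
      trunk_sway_hz = stats::runif(1, 0.2, 0.35))
  }
}

#' True composite impairment of a profile
#'
#' Scalar severity index used to check that the scoring pipeline recovers the
#' simulated impairment ranking: each component is scaled by the upper end of
#' its patient-prior range so the three involuntary-movement classes
#' contribute on comparable scales, then summed.
#'
#' @param profile An [impairment_profile()].
#' @return Non-negative scalar.
#' @export
composite_impairment <- function(profile) {
  syn <- if (length(profile$synergy_gains)) mean(profile$synergy_gains) else 0
  profile$mirror_gain / 1.0 + syn / 0.5 + profile$trunk_sway_amp / 6
}

#' Simulate a cohort of sessions
#'
#' Draws per-participant ages and impairment profiles from the group prior
#' and simulates one session each, all on the same path and calibration (so
#' the cohort can serve directly as a reference cohort or a scoring cohort).
#' Reproducible from `seed`.
#'
#' @param n Number of participants.
#' @param group `"NIA"`, `"NIC"` or `"P"`.
#' @inheritParams simulate_session
#' @param age_range Age range to draw from; defaults to 18--50 years for
#'   adults and 6--18 for children/patients.
#' @return List of [simulate_session()] objects with `meta` filled in
#'   (`id`, `age`, `group`).
#' @export
simulate_cohort <- function(n, group = c("NIA", "NIC", "P"),
                            target_joint = "ankle_L", extremity = "LE",
                            seed = 1, path = NULL, calibration = NULL,
                            age_range = NULL, noise_sd = 0.005) {
  group <- match.arg(group)
  stopifnot(n >= 1)
  if (is.null(path)) path <- generate_target_path()
  if (is.null(calibration)) calibration <- arom_from_bounds(target_joint, 0, 40)
  if (is.null(age_range)) {
    age_range <- if (group == "NIA") c(18, 50) else c(6, 18)
  }
  set.seed(seed)
  seeds <- sample.int(2^30, n)
  ages <- stats::runif(n, age_range[1], age_range[2])
  profiles <- lapply(seq_len(n), function(i) {
    draw_profile(group, ages[i], target_joint)
  })
  lapply(seq_len(n), function(i) {
    simulate_session(target_joint, extremity, profiles[[i]],
                     seed = seeds[i], path = path, calibration = calibration,
                     noise_sd = noise_sd,
                     meta = list(id = sprintf("%s_%02d", group, i),
                                 age = ages[i], group = group))
  })
}
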