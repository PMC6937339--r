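#' Channel tables, joint caps and aggregation units
#'
#' The assessment monitors a fixed vocabulary of joint/trunk channels per
#' extremity. Each channel is defined by a proximal-reference sensor, a distal
#' sensor, a measurement plane (which pair of sensor axes the gravity vector is
#' resolved in) and a sign that orients "steers the avatar upward" as positive.
#' The per-joint angle conventions are deliberately isolated in this one
#' editable table so that alternative formulas can be swapped in without
#' touching the pipeline.
#'
#' @param extremity `"LE"` (lower extremity) or `"UE"` (upper extremity).
#' @return A data frame with one row per channel and columns `channel`,
#'   `proximal`, `distal`, `plane` (`"zy"` sagittal or `"xy"` lateral),
#'   `sign`, `unit` (aggregation unit the channel belongs to), and `side`
#'   (`"L"`, `"R"` or `"M"` for midline).
#' @seealso [joint_cap()], [aggregation_units()]
#' @export
#' @examples
#' channel_table("LE")
channel_table <- function(extremity = c("LE", "UE")) {
  extremity <- match.arg(extremity)
  if (extremity == "LE") {
    tab <- data.frame(
      channel = c("trunk_lateral", "trunk_ventral",
                  "hip_flexion_L", "hip_flexion_R",
                  "hip_rotation_L", "hip_rotation_R",
                  "knee_L", "knee_R", "ankle_L", "ankle_R"),
      proximal = c("pelvis", "pelvis", "pelvis", "pelvis", "pelvis", "pelvis",
                   "thigh_L", "thigh_R", "shank_L", "shank_R"),
      distal = c("sternum", "sternum", "thigh_L", "thigh_R",
                 "thigh_rot_L", "thigh_rot_R",
                 "shank_L", "shank_R", "foot_L", "foot_R"),
      plane = c("xy", "zy", "zy", "zy", "xy", "xy", "zy", "zy", "zy", "zy"),
      sign = rep(1, 10),
      unit = c("trunk", "trunk", "hip_L", "hip_R", "hip_L", "hip_R",
               "knee_L", "knee_R", "ankle_L", "ankle_R"),
      side = c("M", "M", "L", "R", "L", "R", "L", "R", "L", "R"),
      stringsAsFactors = FALSE
    )
  } else {
    sides <- c("L", "R")
    limb <- do.call(rbind, lapply(sides, function(s) {
      data.frame(
        channel = paste0(c("shoulder_abd_", "elbow_", "forearm_prosup_",
                           "wrist_", "fingers_"), s),
        proximal = paste0(c("sternum", "upper_arm_", "forearm_", "forearm_",
                            "hand_"), c("", s, s, s, s)),
        distal = paste0(c("upper_arm_", "forearm_", "prosup_", "hand_",
                          "finger_"), s),
        plane = c("zy", "zy", "xy", "zy", "zy"),
        sign = rep(1, 5),
        unit = paste0(c("shoulder_", "elbow_", "forearm_", "wrist_",
                        "fingers_"), s),
        side = rep(s, 5),
        stringsAsFactors = FALSE
      )
    }))
    trunk <- data.frame(
      channel = c("trunk_lateral", "trunk_ventral"),
      proximal = c("pelvis", "pelvis"),
      distal = c("sternum", "sternum"),
      plane = c("xy", "zy"),
      sign = c(1, 1),
      unit = c("trunk", "trunk"),
      side = c("M", "M"),
      stringsAsFactors = FALSE
    )
    tab <- rbind(trunk, limb)
    rownames(tab) <- NULL
  }
  tab
}

#' Maximum calibrated span per target joint
#'
#' Active range-of-motion spans are capped so that play does not become too
#' strenuous: hip 45, knee 90, ankle 90 degrees for the lower extremity;
#' shoulder 70, elbow 110, forearm pro/supination 135, wrist 135 degrees for
#' the upper extremity. Finger flexion/extension has no stated cap and is
#' left uncapped.
#'
#' @param joint A channel label, e.g. `"knee_L"`.
#' @return The cap in degrees (`Inf` when uncapped).
#' @export
joint_cap <- function(joint) {
  stem <- sub("_[LR]$", "", joint)
  caps <- c(hip_flexion = 45, hip_rotation = 45, knee = 90, ankle = 90,
            shoulder_abd = 70, elbow = 110, forearm_prosup = 135,
            wrist = 135, fingers = Inf)
  if (!stem %in% names(caps)) {
    stop("no range-of-motion cap defined for joint '", joint,
         "' (not a target joint)", call. = FALSE)
  }
  unname(caps[[stem]])
}

#' Aggregation units for the involuntary-movement score
#'
#' Channel errors are first averaged within joint units (trunk lateral +
#' ventral; hip flexion + rotation per side; single-channel joints stand
#' alone), then the units are averaged with equal weight into the involuntary
#' movement score. The target channel is always excluded; a unit emptied by
#' the exclusion is dropped.
#'
#' @param extremity `"LE"` or `"UE"`.
#' @param target_joint Channel label of the target joint.
#' @return Named list mapping unit name to character vector of member
#'   channels, target channel already removed.
#' @export
#' @examples
#' # ankle-target example: trunk, both hips, both knees, contralateral ankle
#' names(aggregation_units("LE", "ankle_L"))
aggregation_units <- function(extremity, target_joint) {
  tab <- channel_table(extremity)
  if (!target_joint %in% tab$channel) {
    stop("unknown target joint '", target_joint, "' for ", extremity,
         call. = FALSE)
  }
  tab <- tab[tab$channel != target_joint, ]
  units <- split(tab$channel, tab$unit)
  # keep the table's unit ordering (trunk first, then joints)
  units[unique(tab$unit)]
}

#' All valid target joints for an extremity
#' @param extremity `"LE"` or `"UE"`.
#' @return Character vector of channel labels that can be played as targets.
#' @export
target_joints <- function(extremity) {
  tab <- channel_table(extremity)
  tab$channel[tab$side != "M"]
}

# Per-sensor kinematic chains used by the simulator: which channel angles sum
# into a sensor's sagittal (beta, zy) and lateral (alpha, xy) orientation.
# The proximal compensation trace, when present, is added to every sensor.
sensor_chains <- function(extremity) {
  tab <- channel_table(extremity)
  sensors <- unique(c(tab$proximal, tab$distal))
  chains <- lapply(sensors, function(s) list(zy = character(), xy = character()))
  names(chains) <- sensors
  if (extremity == "LE") {
    chains$sternum <- list(zy = "trunk_ventral", xy = "trunk_lateral")
    for (s in c("L", "R")) {
      hf <- paste0("hip_flexion_", s)
      chains[[paste0("thigh_", s)]] <- list(zy = hf, xy = character())
      chains[[paste0("thigh_rot_", s)]] <-
        list(zy = character(), xy = paste0("hip_rotation_", s))
      chains[[paste0("shank_", s)]] <-
        list(zy = c(hf, paste0("knee_", s)), xy = character())
      chains[[paste0("foot_", s)]] <-
        list(zy = c(hf, paste0("knee_", s), paste0("ankle_", s)),
             xy = character())
    }
  } else {
    chains$sternum <- list(zy = "trunk_ventral", xy = "trunk_lateral")
    for (s in c("L", "R")) {
      sh <- c("trunk_ventral", paste0("shoulder_abd_", s))
      el <- c(sh, paste0("elbow_", s))
      chains[[paste0("upper_arm_", s)]] <- list(zy = sh, xy = character())
      chains[[paste0("forearm_", s)]] <- list(zy = el, xy = character())
      chains[[paste0("prosup_", s)]] <-
        list(zy = character(), xy = paste0("forearm_prosup_", s))
      chains[[paste0("hand_", s)]] <-
        list(zy = c(el, paste0("wrist_", s)), xy = character())
      chains[[paste0("finger_", s)]] <-
        list(zy = c(el, paste0("wrist_", s), paste0("fingers_", s)),
             xy = character())
    }
  }
  chains
}

#' Default target-path waypoints
#'
#' A built-in waypoint set spanning the full playable band: values in percent
#' of calibrated active range of motion, inside the \[5, 95\] band (90% of the
#' range, centred), touching both extremes of the band at least once over the
#' 30 s of play.
#'
#' @return Data frame with columns `time_s` and `percent`.
#' @export
default_waypoints <- function() {
  data.frame(
    time_s = c(0, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30),
    percent = c(50, 90, 35, 75, 8, 60, 92, 25, 70, 10, 50)
  )
}

#' Resting (neutral) angle of each channel in degrees
#'
#' Hanging-limb / upright-trunk neutral posture; all conventions place the
#' neutral posture at 0 degrees.
#' @param extremity `"LE"` or `"UE"`.
#' @return Named numeric vector, one entry per channel.
#' @export
rest_angles <- function(extremity) {
  tab <- channel_table(extremity)
  stats::setNames(numeric(nrow(tab)), tab$channel)
}

#' Serialize a channel table to/from JSON
#'
#' The channel table (placement map + per-channel axis conventions) is
#' JSON-serializable so the per-joint conventions can be edited without
#' touching code and passed back into [compute_joint_channels()].
#' @param table A channel table data frame.
#' @param file JSON path.
#' @return `read_channel_table_json()` returns the data frame.
#' @export
write_channel_table_json <- function(table, file) {
  jsonlite::write_json(table, file, digits = NA)
  invisible(file)
}

#' @rdname write_channel_table_json
#' @export
read_channel_table_json <- function(file) {
  df <- jsonlite::read_json(file, simplifyVector = TRUE)
  need <- c("channel", "proximal", "distal", "plane", "sign", "unit", "side")
  if (!all(need %in% names(df))) {
    stop("channel table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(df)
}
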