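#' Read and write sensor-stream CSV files
#'
#' Long format, one row per sample: columns `t` (seconds), `ax`, `ay`, `az`
#' (g units) and `sensor_id` (the placement label). All numeric output is
#' written at full double precision so files round-trip bit-exactly.
#'
#' @param streams List of [sensor_stream()] objects.
#' @param file Path to the CSV file.
#' @return `read_sensor_csv()` returns a named list of `sensor_stream`s.
#' @export
write_sensor_csv <- function(streams, file) {
  rows <- lapply(streams, function(s) {
    data.frame(t = s$t, ax = s$a[, 1], ay = s$a[, 2], az = s$a[, 3],
               sensor_id = s$placement)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format_full(df), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az", "sensor_id")
  if (!all(need %in% names(df))) {
    stop("sensor CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$sensor_id)
  streams <- lapply(ids, function(id) {
    d <- df[df$sensor_id == id, ]
    sensor_stream(d$t, cbind(d$ax, d$ay, d$az), sensor_id = id,
                  placement = id)
  })
  names(streams) <- ids
  streams
}

#' Serialize a calibration result to/from JSON
#' @param calibration An [arom_calibration()].
#' @param file JSON path.
#' @return `read_calibration_json()` returns the `arom_calibration`.
#' @export
write_calibration_json <- function(calibration, file) {
  jsonlite::write_json(unclass(calibration), file, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(file)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$reason <- if (is.null(x$reason)) NA_character_ else x$reason
  for (f in c("arom_min", "arom_max")) {
    if (is.null(x[[f]])) x[[f]] <- NA_real_
  }
  structure(x[c("joint", "raw_min", "raw_max", "arom_min", "arom_max",
                "capped", "playable", "reason")],
            class = "arom_calibration")
}

#' Serialize a target path to/from JSON (by its waypoints)
#' @param path A [target_path()].
#' @param file JSON path.
#' @return `read_path_json()` regenerates the identical `target_path`.
#' @export
write_path_json <- function(path, file) {
  jsonlite::write_json(list(duration_s = max(path$t), rate_hz = path$rate_hz,
                            waypoints = path$waypoints),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_path_json
#' @export
read_path_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  generate_target_path(duration_s = x$duration_s, rate_hz = x$rate_hz,
                       waypoints = as.data.frame(x$waypoints))
}

#' Serialize the adult reference database to/from JSON
#'
#' Versioned header (`format`, package version) plus all per-timepoint
#' traces at full precision.
#' @param ref An [build_reference()] result.
#' @param file JSON path.
#' @return `read_reference_json()` returns the `svmc_reference`.
#' @export
write_reference_json <- function(ref, file) {
  payload <- list(
    format = "svmc_reference/1",
    package_version = as.character(utils::packageVersion("svmcgame")),
    target_joint = ref$target_joint, extremity = ref$extremity,
    rate_hz = ref$rate_hz, n_adults = ref$n_adults, sd_floor = ref$sd_floor,
    t = ref$t, p_star = ref$p_star, sigma_path = ref$sigma_path,
    channels = ref$channels)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "svmc_reference/1") {
    stop("not a recognised reference database: ", file, call. = FALSE)
  }
  channels <- lapply(x$channels, function(c) list(mu = c$mu, sigma = c$sigma))
  structure(list(target_joint = x$target_joint, extremity = x$extremity,
                 t = x$t, p_star = x$p_star, rate_hz = x$rate_hz,
                 sigma_path = x$sigma_path, channels = channels,
                 n_adults = x$n_adults, sd_floor = x$sd_floor),
            class = "svmc_reference")
}

#' Session manifest
#'
#' Metadata identifying one play-through: participant, age, cohort group,
#' extremity, target joint and tested side, plus an optional therapist sum
#' score (0 = fully selective movement to 3 = involuntary movements at
#' trunk, contralateral side and other joints).
#'
#' @param id Participant identifier.
#' @param age Age in years (decimal).
#' @param group `"NIA"`, `"NIC"` or `"P"`.
#' @param extremity `"LE"` or `"UE"`.
#' @param target_joint Channel label.
#' @param side Tested side `"L"` or `"R"`.
#' @param therapist_score Optional integer 0--3.
#' @return Named list of class `session_manifest`.
#' @export
session_manifest <- function(id, age, group, extremity, target_joint,
                             side = sub("^.*_", "", target_joint),
                             therapist_score = NULL) {
  if (!group %in% c("NIA", "NIC", "P")) {
    stop("group must be one of NIA, NIC, P", call. = FALSE)
  }
  if (!extremity %in% c("LE", "UE")) {
    stop("extremity must be LE or UE", call. = FALSE)
  }
  if (!target_joint %in% channel_table(extremity)$channel) {
    stop("unknown target joint '", target_joint, "' for ", extremity,
         call. = FALSE)
  }
  if (!is.null(therapist_score) && !therapist_score %in% 0:3) {
    stop("therapist score must be in 0..3", call. = FALSE)
  }
  structure(list(id = id, age = age, group = group, extremity = extremity,
                 target_joint = target_joint, side = side,
                 therapist_score = therapist_score),
            class = "session_manifest")
}

#' @rdname session_manifest
#' @param manifest A `session_manifest`.
#' @param file JSON path.
#' @export
write_manifest_json <- function(manifest, file) {
  jsonlite::write_json(unclass(manifest), file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname session_manifest
#' @export
read_manifest_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(session_manifest, x[!vapply(x, is.null, logical(1))])
}

#' Flatten scores into one tidy row
#'
#' One row per (participant, side, target joint), directly consumable by
#' mixed-model tooling: raw outcomes, z-scores when present, per-unit columns
#' and the missing-channel list.
#'
#' @param scores An [score_session()] result.
#' @param manifest Optional [session_manifest()] supplying identity columns.
#' @return A one-row data frame.
#' @export
scores_row <- function(scores, manifest = NULL) {
  meta <- if (!is.null(manifest)) unclass(manifest) else scores$meta
  base <- data.frame(
    id = meta$id %||% NA_character_,
    age = meta$age %||% NA_real_,
    group = meta$group %||% NA_character_,
    side = meta$side %||% sub("^.*_", "", scores$target_joint),
    extremity = scores$extremity,
    target_joint = scores$target_joint,
    accuracy = scores$accuracy,
    involuntary = scores$involuntary,
    z_accuracy = scores$z_accuracy %||% NA_real_,
    z_involuntary = scores$z_involuntary %||% NA_real_,
    n_units = length(scores$per_unit),
    missing_channels = paste(scores$missing_channels, collapse = ";"),
    stringsAsFactors = FALSE)
  units <- as.data.frame(as.list(scores$per_unit))
  if (ncol(units)) names(units) <- paste0("unit_", names(scores$per_unit))
  cbind(base, units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read the tidy score table
#' @param rows Data frame (e.g. rbind of [scores_row()] outputs).
#' @param file CSV path.
#' @return `read_scores_csv()` returns the data frame.
#' @export
write_scores_csv <- function(rows, file) {
  utils::write.csv(format_full(rows), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
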