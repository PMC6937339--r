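#' Target-joint accuracy score
#'
#' The standardized tracking error: at every timepoint the absolute
#' difference between the avatar position and the target path is divided by
#' the adult SD around the path, and the standardized deviations are averaged
#' over the analysis window. The score reads as "how many adult SDs away from
#' the target path the player was on average"; 0 means perfect tracking.
#'
#' @param avatar An `avatar_trace` or bare numeric percent trace.
#' @param path A [target_path()] (already windowed) or bare numeric trace.
#' @param ref An [build_reference()] result, or a bare numeric `sigma_path`
#'   trace.
#' @param order `"standardize_first"` (default: pointwise standardize, then
#'   average) or `"average_first"` (average deviation and SD over time, then
#'   divide) — the latter is provided for sensitivity analysis only.
#' @return Non-negative scalar in adult-SD units.
#' @export
accuracy_score <- function(avatar, path, ref,
                           order = c("standardize_first", "average_first")) {
  order <- match.arg(order)
  p <- if (inherits(avatar, "avatar_trace")) avatar$p else as.numeric(avatar)
  ps <- if (inherits(path, "target_path")) path$p_star else as.numeric(path)
  sp <- if (inherits(ref, "svmc_reference")) ref$sigma_path else as.numeric(ref)
  if (length(p) != length(ps) || length(p) != length(sp)) {
    stop("avatar, path and reference are on different grids", call. = FALSE)
  }
  if (order == "standardize_first") {
    mean(abs(p - ps) / sp)
  } else {
    mean(abs(p - ps)) / mean(sp)
  }
}

#' Standardized error of one involuntary-movement channel
#'
#' Compares a channel's joint-angle derivative against the adult reference:
#' mean over time of `|d(t) - mu_c(t)| / sigma_c(t)`. Centering on the adult
#' mean derivative means a perfectly physiological co-movement scores 0, and
#' holding any constant posture (zero derivative) is compared only against
#' how much adults themselves moved.
#'
#' @param deriv Numeric derivative trace in deg/s.
#' @param mu,sigma Adult mean and SD traces on the identical grid.
#' @inheritParams accuracy_score
#' @return Non-negative scalar in adult-SD units.
#' @export
involuntary_channel_error <- function(deriv, mu, sigma,
                                      order = c("standardize_first",
                                                "average_first")) {
  order <- match.arg(order)
  if (length(deriv) != length(mu) || length(deriv) != length(sigma)) {
    stop("derivative and reference traces are on different grids",
         call. = FALSE)
  }
  if (order == "standardize_first") {
    mean(abs(deriv - mu) / sigma)
  } else {
    mean(abs(deriv - mu)) / mean(sigma)
  }
}

#' Resolve missing channels before aggregation
#'
#' The default policy drops missing channels, so unit averages are taken over
#' the available members only. `strategy = "fail"` raises instead, for
#' pipelines that must not score partial sessions. Externally imputed values
#' (e.g. from a multiple-imputation model fitted elsewhere) can be supplied
#' through `imputed` and are merged in before the policy applies.
#'
#' @param errors Named numeric vector of per-channel standardized errors.
#' @param missing Character vector of channel names without a value.
#' @param strategy `"drop"` or `"fail"`.
#' @param imputed Optional named numeric vector filling in missing channels.
#' @return Named numeric vector of usable per-channel errors.
#' @export
handle_missing_channels <- function(errors, missing = character(),
                                    strategy = c("drop", "fail"),
                                    imputed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(imputed)) {
    fill <- intersect(names(imputed), missing)
    errors[fill] <- imputed[fill]
    missing <- setdiff(missing, fill)
  }
  if (length(missing) && strategy == "fail") {
    stop("missing channels under strategy 'fail': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(errors)) stop("no channels available to score", call. = FALSE)
  errors[!is.na(errors)]
}

#' Aggregate channel errors into the involuntary-movement score
#'
#' Two-level averaging: channel errors are first averaged within joint units
#' (trunk lateral + ventral; hip flexion + rotation per side; the remaining
#' joints stand alone), then all units are averaged with equal weight. The
#' target channel is always excluded, and a unit with no available channel is
#' dropped.
#'
#' @param errors Named numeric vector of per-channel standardized errors
#'   (missing channels simply absent).
#' @param extremity `"LE"` or `"UE"`.
#' @param target_joint The played channel, excluded from aggregation.
#' @param units Optional explicit unit table (named list channel-vectors),
#'   defaulting to [aggregation_units()].
#' @return List with `score` (scalar) and `per_unit` (named numeric).
#' @export
#' @examples
#' e <- c(trunk_lateral = 1, trunk_ventral = 3, hip_flexion_L = 2,
#'        hip_rotation_L = 2, hip_flexion_R = 0, hip_rotation_R = 4,
#'        knee_L = 5, knee_R = 1, ankle_R = 6)
#' aggregate_involuntary(e, "LE", "ankle_L")$score  # 3
aggregate_involuntary <- function(errors, extremity, target_joint,
                                  units = NULL) {
  if (is.null(units)) units <- aggregation_units(extremity, target_joint)
  errors <- errors[setdiff(names(errors), target_joint)]
  per_unit <- vapply(units, function(members) {
    have <- intersect(members, names(errors))
    if (!length(have)) return(NA_real_)
    mean(errors[have])
  }, numeric(1))
  per_unit <- per_unit[!is.na(per_unit)]
  if (!length(per_unit)) {
    stop("no aggregation unit has any available channel", call. = FALSE)
  }
  list(score = mean(per_unit), per_unit = per_unit)
}

#' Score one session against the adult reference
#'
#' Computes both outcome metrics for a processed session: the target-joint
#' accuracy score and the involuntary-movement score with its per-channel and
#' per-unit decomposition.
#'
#' @param session A [process_session()] result.
#' @param ref An [build_reference()] for the same target joint and grid.
#' @param strategy Missing-channel policy, see [handle_missing_channels()].
#' @param imputed Optional externally imputed channel errors.
#' @inheritParams accuracy_score
#' @return Object of class `svmc_scores` with fields `accuracy`,
#'   `involuntary`, `per_channel`, `per_unit`, `missing_channels`,
#'   `z_accuracy`/`z_involuntary` (filled by [age_normalize()]), and `meta`.
#' @export
score_session <- function(session, ref, strategy = c("drop", "fail"),
                          imputed = NULL,
                          order = c("standardize_first", "average_first")) {
  strategy <- match.arg(strategy)
  order <- match.arg(order)
  stopifnot(inherits(session, "svmc_session"),
            inherits(ref, "svmc_reference"))
  if (session$target_joint != ref$target_joint) {
    stop("session target joint (", session$target_joint,
         ") does not match the reference (", ref$target_joint, ")",
         call. = FALSE)
  }
  if (length(session$t) != length(ref$t) ||
      max(abs(session$p_star - ref$p_star)) > 1e-9) {
    stop("session and reference are on different paths or grids",
         call. = FALSE)
  }
  accuracy <- accuracy_score(session$avatar_p, session$p_star, ref,
                             order = order)

  monitored <- setdiff(names(ref$channels), session$target_joint)
  errors <- stats::setNames(rep(NA_real_, length(monitored)), monitored)
  missing <- character()
  for (ch in monitored) {
    if (ch %in% colnames(session$derivs)) {
      errors[ch] <- involuntary_channel_error(
        session$derivs[, ch], ref$channels[[ch]]$mu, ref$channels[[ch]]$sigma,
        order = order)
    } else {
      missing <- c(missing, ch)
    }
  }
  usable <- handle_missing_channels(errors, missing, strategy, imputed)
  agg <- aggregate_involuntary(usable, session$extremity,
                               session$target_joint)
  structure(list(accuracy = accuracy, involuntary = agg$score,
                 per_channel = usable, per_unit = agg$per_unit,
                 missing_channels = missing,
                 target_joint = session$target_joint,
                 extremity = session$extremity,
                 z_accuracy = NULL, z_involuntary = NULL,
                 meta = session$meta),
            class = "svmc_scores")
}

#' @export
print.svmc_scores <- function(x, ...) {
  cat(sprintf("<svmc_scores> target %s (%s)\n", x$target_joint, x$extremity))
  cat(sprintf("  accuracy:    %.3f adult SD\n", x$accuracy))
  cat(sprintf("  involuntary: %.3f adult SD (%d units)\n", x$involuntary,
              length(x$per_unit)))
  if (!is.null(x$z_accuracy)) {
    cat(sprintf("  z-scores: accuracy %+.2f, involuntary %+.2f\n",
                x$z_accuracy, x$z_involuntary))
  }
  if (length(x$missing_channels)) {
    cat("  missing:", paste(x$missing_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.svmc_scores <- function(object, ...) {
  cat(sprintf("Scores for target %s (%s)\n", object$target_joint,
              object$extremity))
  cat(sprintf("accuracy %.3f | involuntary %.3f\n", object$accuracy,
              object$involuntary))
  cat("\nper-unit breakdown (adult SD units):\n")
  print(round(sort(object$per_unit, decreasing = TRUE), 3))
  cat("\nper-channel breakdown:\n")
  print(round(sort(object$per_channel, decreasing = TRUE), 3))
  invisible(object)
}

#' @export
plot.svmc_scores <- function(x, ...) {
  graphics::barplot(sort(x$per_unit, decreasing = TRUE),
                    las = 2, ylab = "standardized error (adult SD)",
                    main = sprintf("%s target: involuntary = %.2f",
                                   x$target_joint, x$involuntary), ...)
  graphics::abline(h = x$involuntary, lty = 2)
  invisible(x)
}

#' Age-normalized z-score against a peer group
#'
#' Children and patients are compared against neurologically intact children
#' whose integer age lies within one year of the participant's integer age
#' (a 7.2-year-old's peers are the intact children aged 6, 7 or 8); adults
#' are compared against the whole adult reference group without subgrouping.
#' z = (score - peer mean) / peer SD, so a positive z is worse than the peer
#' average.
#'
#' @param score The participant's raw outcome score.
#' @param age Participant age in years (decimal).
#' @param group `"NIA"` (adult), `"NIC"` (intact child) or `"P"` (patient).
#' @param cohort Data frame of normative scores with columns `age`, `group`,
#'   `score`; only `NIC` rows form child peer groups, only `NIA` rows the
#'   adult group.
#' @param min_peer Minimum peer-group size (default 3).
#' @return List with `z` (`NA` when not computable), `peer_n`, `peer_mean`,
#'   `peer_sd`, `reason`.
#' @export
age_normalize <- function(score, age, group, cohort, min_peer = 3) {
  stopifnot(all(c("age", "group", "score") %in% names(cohort)))
  if (!group %in% c("NIA", "NIC", "P")) {
    stop("unknown group '", group, "'", call. = FALSE)
  }
  if (group == "NIA") {
    peers <- cohort$score[cohort$group == "NIA"]
  } else {
    ia <- floor(age)
    sel <- cohort$group == "NIC" & abs(floor(cohort$age) - ia) <= 1
    peers <- cohort$score[sel]
  }
  if (length(peers) < min_peer) {
    return(list(z = NA_real_, peer_n = length(peers), peer_mean = NA_real_,
                peer_sd = NA_real_,
                reason = sprintf("peer group has %d members (< %d)",
                                 length(peers), min_peer)))
  }
  m <- mean(peers)
  s <- stats::sd(peers)
  if (s == 0) {
    return(list(z = NA_real_, peer_n = length(peers), peer_mean = m,
                peer_sd = 0, reason = "zero peer-group SD"))
  }
  list(z = (score - m) / s, peer_n = length(peers), peer_mean = m,
       peer_sd = s, reason = NA_character_)
}

#' Add age-normalized z-scores to a tidy score table
#'
#' @param scores Data frame with at least `age`, `group`, and the outcome
#'   columns named in `outcomes`.
#' @param outcomes Columns to normalize (default both outcome metrics).
#' @param min_peer Minimum peer-group size.
#' @return `scores` with `z_<outcome>` columns appended (`NA` where no valid
#'   peer group exists).
#' @export
add_z_scores <- function(scores, outcomes = c("accuracy", "involuntary"),
                         min_peer = 3) {
  for (oc in outcomes) {
    cohort <- data.frame(age = scores$age, group = scores$group,
                         score = scores[[oc]])
    scores[[paste0("z_", oc)]] <- vapply(seq_len(nrow(scores)), function(i) {
      age_normalize(scores[[oc]][i], scores$age[i], scores$group[i],
                    cohort, min_peer)$z
    }, numeric(1))
  }
  scores
}
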