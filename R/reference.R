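#' Build the adult reference for one target joint
#'
#' Fits the normative model both outcome scores are standardized against.
#' From a cohort of neurologically intact adults who played the identical
#' path, it estimates, per timepoint of the analysis window:
#' \itemize{
#'   \item `sigma_path(t)`: the SD across adults of the avatar deviation from
#'     the target path (percent of aROM). Dividing a player's deviation by it
#'     expresses tracking error relative to path difficulty — a harder
#'     stretch of path widens the adult spread and is penalized less.
#'   \item per monitored channel `c`: `mu_c(t)` and `sigma_c(t)`, the mean and
#'     SD across adults of the joint-angle derivative (deg/s). Centering on
#'     the adult mean, rather than on zero, avoids penalizing physiological
#'     co-movements (e.g. slight knee flexion accompanying hip flexion, which
#'     shortens the lever arm).
#' }
#' All SDs are floored at `sd_floor` so near-deterministic adult behaviour
#' cannot blow up the standardized errors.
#'
#' @param sessions List of [process_session()] results for the adult cohort;
#'   all must share the target joint and the analysis grid.
#' @param sd_floor Lower bound on every SD, in native units (percent for the
#'   path, deg/s for derivatives); default 0.5.
#' @return Object of class `svmc_reference`.
#' @export
build_reference <- function(sessions, sd_floor = 0.5) {
  if (length(sessions) < 2) {
    stop("need at least 2 adult sessions to build a reference", call. = FALSE)
  }
  stopifnot(all(vapply(sessions, inherits, logical(1), "svmc_session")))
  tj <- unique(vapply(sessions, `[[`, character(1), "target_joint"))
  ex <- unique(vapply(sessions, `[[`, character(1), "extremity"))
  if (length(tj) != 1 || length(ex) != 1) {
    stop("all reference sessions must share extremity and target joint",
         call. = FALSE)
  }
  t0 <- sessions[[1]]$t
  p0 <- sessions[[1]]$p_star
  for (s in sessions[-1]) {
    if (length(s$t) != length(t0) || max(abs(s$t - t0)) > 1e-6 ||
        max(abs(s$p_star - p0)) > 1e-9) {
      stop("reference sessions were scored on different paths or grids",
           call. = FALSE)
    }
  }
  dev <- t(vapply(sessions, function(s) s$avatar_p - s$p_star,
                  numeric(length(t0))))
  sigma_path <- pmax(apply(dev, 2, stats::sd), sd_floor)

  all_names <- unique(unlist(lapply(sessions, function(s) colnames(s$derivs))))
  channels <- list()
  for (ch in all_names) {
    rows <- lapply(sessions, function(s) {
      if (ch %in% colnames(s$derivs)) s$derivs[, ch] else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) < 2) next  # not enough adults measured this channel
    m <- do.call(rbind, rows)
    channels[[ch]] <- list(mu = colMeans(m),
                           sigma = pmax(apply(m, 2, stats::sd), sd_floor))
  }
  structure(list(target_joint = tj, extremity = ex, t = t0, p_star = p0,
                 rate_hz = sessions[[1]]$rate_hz, sigma_path = sigma_path,
                 channels = channels, n_adults = length(sessions),
                 sd_floor = sd_floor),
            class = "svmc_reference")
}

#' @export
print.svmc_reference <- function(x, ...) {
  cat(sprintf(
    "<svmc_reference> %s target %s: n = %d adults, %d channels, %d timepoints\n",
    x$extremity, x$target_joint, x$n_adults, length(x$channels), length(x$t)))
  cat(sprintf("  sigma_path: median %.2f%% (floor %.2f)\n",
              stats::median(x$sigma_path), x$sd_floor))
  invisible(x)
}

#' @export
summary.svmc_reference <- function(object, ...) {
  chan <- t(vapply(object$channels, function(c) {
    c(mu_mean = mean(c$mu), sigma_median = stats::median(c$sigma))
  }, numeric(2)))
  out <- list(target_joint = object$target_joint,
              extremity = object$extremity,
              n_adults = object$n_adults,
              sigma_path = summary(object$sigma_path),
              channels = chan)
  class(out) <- "summary.svmc_reference"
  out
}

#' @export
print.summary.svmc_reference <- function(x, ...) {
  cat(sprintf("Adult reference for %s (%s), n = %d\n",
              x$target_joint, x$extremity, x$n_adults))
  cat("sigma_path (% aROM):\n")
  print(x$sigma_path)
  cat("channel derivative statistics (deg/s):\n")
  print(round(x$channels, 2))
  invisible(x)
}

#' @export
plot.svmc_reference <- function(x, ...) {
  graphics::plot(x$t, x$p_star, type = "l", ylim = c(0, 100),
                 xlab = "time (s)", ylab = "position (% aROM)",
                 main = paste("Adult reference band,", x$target_joint), ...)
  graphics::polygon(c(x$t, rev(x$t)),
                    c(x$p_star + 2 * x$sigma_path,
                      rev(x$p_star - 2 * x$sigma_path)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$t, x$p_star)
  invisible(x)
}
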