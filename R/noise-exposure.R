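# ISO 9612 style noise-exposure arithmetic. All decibel averaging happens
# in the power (10^(L/10)) domain; nothing is rounded before presentation.

#' Logarithmic (energetic) mean of sound pressure levels
#'
#' `10 * log10(mean(10^(L/10)))` over one-minute equivalent levels measured
#' repeatedly at a point. Always lies between the minimum and the maximum
#' input and is never below the arithmetic mean.
#'
#' @param levels_db Non-empty numeric vector of levels in dBA.
#' @return The energetically averaged level in dBA.
#' @examples
#' log_mean(c(50, 60))      # 57.40
#' log_mean(c(50, 60, 70))  # 65.69
#' @export
log_mean <- function(levels_db) {
  if (length(levels_db) == 0L) stop("'levels_db' must be non-empty")
  if (any(!is.finite(levels_db))) stop("'levels_db' must be finite")
  10 * log10(mean(10^(levels_db / 10)))
}

#' Exposure category of a daily personal noise exposure level
#'
#' Levels below 50 dBA are `low`, levels in the closed interval
#' \[50, 60\] dBA are `moderate`, and levels above 60 dBA are `high`.
#'
#' @param lep_d_db Numeric vector of LEP,d values in dBA.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
categorize_exposure <- function(lep_d_db) {
  if (any(!is.finite(lep_d_db))) stop("'lep_d_db' must be finite")
  factor(ifelse(lep_d_db < 50, "low", ifelse(lep_d_db > 60, "high", "moderate")),
         levels = c("low", "moderate", "high"))
}

#' Daily personal noise exposure level from workstation contributions
#'
#' Combines task contributions (workstation level, time spent) into the
#' A-weighted equivalent level over the effective duration `Te = sum(t_i)`,
#'
#'   `LAeq,Te = 10 * log10( sum((t_i/Te) * 10^(L_i/10)) )`,
#'
#' and normalises it to the reference working day `T0` (8 h by default):
#'
#'   `LEP,d = LAeq,Te + 10 * log10(Te / T0)`.
#'
#' @param level_db Numeric vector of workstation levels in dBA.
#' @param duration_h Numeric vector of positive task durations in hours
#'   (recycled against `level_db` must match in length).
#' @param t0_h Reference duration in hours (default 8).
#' @return A one-row data frame with `te_h`, `laeq_te_db`, `lep_d_db` and
#'   the exposure `category` (see [categorize_exposure()]).
#' @examples
#' personal_daily_exposure(c(60, 50), c(4, 4))  # LEP,d 57.40, moderate
#' @export
personal_daily_exposure <- function(level_db, duration_h, t0_h = 8) {
  if (length(level_db) == 0L) stop("at least one workstation contribution is required")
  if (length(level_db) != length(duration_h))
    stop("'level_db' and 'duration_h' must have equal length")
  if (any(!is.finite(level_db)) || any(!is.finite(duration_h)))
    stop("levels and durations must be finite")
  if (any(duration_h <= 0)) stop("durations must be positive")
  te <- sum(duration_h)
  laeq <- 10 * log10(sum((duration_h / te) * 10^(level_db / 10)))
  lep_d <- laeq + 10 * log10(te / t0_h)
  data.frame(te_h = te, laeq_te_db = laeq, lep_d_db = lep_d,
             category = categorize_exposure(lep_d))
}

#' Collapse a repeated-measurement grid into a noise map
#'
#' One output row per measurement point, whose mapped level is the
#' [log_mean()] of the point's repeated one-minute equivalent levels.
#'
#' @param grid Data frame with columns `point_id`, `department`, `leq_db`
#'   and optionally `x`, `y` coordinates (metres). A `point_id` appearing
#'   with conflicting coordinates or departments is an error.
#' @return Data frame with columns `point_id`, `department` (and `x`, `y`
#'   when present), `n_repeats`, `mapped_level_db`.
#' @export
build_noise_map <- function(grid) {
  need <- c("point_id", "department", "leq_db")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop(sprintf("grid is missing column(s): %s", paste(miss, collapse = ", ")))
  keys <- c("department", intersect(c("x", "y"), names(grid)))
  meta <- unique(grid[, c("point_id", keys), drop = FALSE])
  if (anyDuplicated(meta$point_id)) {
    dup <- meta$point_id[duplicated(meta$point_id)][1L]
    stop(sprintf("point '%s' appears with conflicting coordinates/department", dup))
  }
  lv <- split(grid$leq_db, grid$point_id)
  out <- meta[match(names(lv), meta$point_id), , drop = FALSE]
  out$n_repeats <- vapply(lv, length, 1L)
  out$mapped_level_db <- vapply(lv, log_mean, 1)
  rownames(out) <- NULL
  out
}

#' Per-nurse exposure from a noise map and workstation assignments
#'
#' Recomputes every nurse's LEP,d by looking each assigned workstation up
#' in the noise map and combining the contributions with
#' [personal_daily_exposure()].
#'
#' @param noise_map Output of [build_noise_map()].
#' @param assignments Data frame with columns `nurse_id`, `point_id`,
#'   `duration_h`.
#' @param t0_h Reference duration in hours (default 8).
#' @return Data frame with one row per nurse: `nurse_id`, `te_h`,
#'   `laeq_te_db`, `lep_d_db`, `category`.
#' @export
nurse_exposure <- function(noise_map, assignments, t0_h = 8) {
  need <- c("nurse_id", "point_id", "duration_h")
  miss <- setdiff(need, names(assignments))
  if (length(miss)) stop(sprintf("assignments missing column(s): %s", paste(miss, collapse = ", ")))
  lev <- noise_map$mapped_level_db[match(assignments$point_id, noise_map$point_id)]
  if (any(is.na(lev))) {
    bad <- assignments$point_id[which(is.na(lev))[1L]]
    stop(sprintf("workstation point '%s' is not on the noise map", bad))
  }
  parts <- split(data.frame(level = lev, dur = assignments$duration_h),
                 assignments$nurse_id)
  out <- do.call(rbind, lapply(parts, function(d)
    personal_daily_exposure(d$level, d$dur, t0_h = t0_h)))
  out <- cbind(nurse_id = names(parts), out)
  rownames(out) <- NULL
  out
}
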