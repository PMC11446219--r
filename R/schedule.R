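#' Housing phase schedule
#'
#' Defines the dark/light cycle of the VBS housing period. An experimental
#' day starts at dark onset (18:00 by convention) and spans two calendar
#' days: dark from 18:00 to 05:59, light from 06:00 to 17:59.
#'
#' @param start POSIXct, first dark onset (start of housing). Defaults to an
#'   arbitrary 18:00 UTC; only the offset from `start` matters downstream.
#' @param phase_hours Length of each phase in hours (12 for a 12/12 cycle).
#' @param n_days Number of experimental days (default 5).
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(start = as.POSIXct("2023-03-06 18:00:00", tz = "UTC"),
                           phase_hours = 12, n_days = 5) {
  stopifnot(inherits(start, "POSIXct"), phase_hours > 0, n_days >= 1)
  structure(
    list(start = start, phase_hours = phase_hours, n_days = n_days),
    class = "phase_schedule"
  )
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "Phase schedule: %d day(s) of %g h dark / %g h light from %s\n",
    x$n_days, x$phase_hours, x$phase_hours,
    format(x$start, "%Y-%m-%d %H:%M %Z")
  ))
  invisible(x)
}

#' Total housing window in hours
#'
#' @param schedule A [phase_schedule()].
#' @return Hours from first dark onset to the end of the last light phase.
#' @export
housing_hours <- function(schedule) {
  2 * schedule$phase_hours * schedule$n_days
}

#' Assign experimental day and phase to timestamps
#'
#' Maps absolute timestamps onto the experimental-day/phase grid of a
#' schedule. Day `d` covers `[start + (d-1)*24h, start + d*24h)`; within a
#' day the dark phase comes first. The mapping partitions the housing
#' window, so every in-window timestamp receives exactly one `(day, phase)`.
#'
#' @param time POSIXct vector of timestamps.
#' @param schedule A [phase_schedule()].
#' @param strict If `TRUE` (default), timestamps outside the housing window
#'   are an error; otherwise they yield `NA` day/phase.
#' @return A tibble with columns `day` (integer), `phase` ("dark"/"light"),
#'   `mins` (minutes since first dark onset) and `phase_hour` (1-based hour
#'   within the phase).
#' @export
#' @examples
#' sched <- phase_schedule()
#' assign_phase(sched$start + 3600, sched) # day 1, dark, hour 2
assign_phase <- function(time, schedule, strict = TRUE) {
  stopifnot(inherits(time, "POSIXct"))
  mins <- as.numeric(difftime(time, schedule$start, units = "mins"))
  total <- housing_hours(schedule) * 60
  out <- !is.na(mins) & (mins < 0 | mins >= total)
  if (any(out)) {
    if (strict) {
      stop(sum(out), " timestamp(s) outside the housing window")
    }
    mins[out] <- NA_real_
  }
  day_mins <- 2 * schedule$phase_hours * 60
  day <- as.integer(floor(mins / day_mins) + 1)
  within <- mins - (day - 1) * day_mins
  dark <- within < schedule$phase_hours * 60
  phase <- ifelse(dark, "dark", "light")
  phase_min <- ifelse(dark, within, within - schedule$phase_hours * 60)
  tibble::tibble(
    day = day, phase = phase, mins = mins,
    phase_hour = as.integer(floor(phase_min / 60) + 1)
  )
}

#' Video sampling plan
#'
#' Describes the intermittent video recording and scoring protocol: short
#' videos recorded at a fixed interval, of which only those falling in the
#' first hours of each phase are scored.
#'
#' @param video_length_s Length of each video in seconds (default 30).
#' @param interval_min Minutes between video start times (default 10).
#' @param scored_window_h Hours from phase onset that are scored (default 4).
#' @param phases_per_day Scored phases per experimental day (default 2).
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(video_length_s = 30, interval_min = 10,
                          scored_window_h = 4, phases_per_day = 2) {
  stopifnot(
    video_length_s > 0, interval_min > 0,
    scored_window_h >= 0, phases_per_day > 0
  )
  structure(
    list(
      video_length_s = video_length_s, interval_min = interval_min,
      scored_window_h = scored_window_h, phases_per_day = phases_per_day
    ),
    class = "sampling_plan"
  )
}

#' Number of scored videos implied by a sampling plan
#'
#' Videos start at minute 0 of the phase and every `interval_min` after;
#' both endpoints of the scored window count, so a 4 h window sampled every
#' 10 min yields 25 videos per phase and, with 2 phases over 5 days, 250
#' scored videos per group.
#'
#' @param plan A [sampling_plan()].
#' @param schedule A [phase_schedule()].
#' @return A list with `per_phase`, `per_day` and `total` video counts.
#' @export
#' @examples
#' scored_video_count(sampling_plan(), phase_schedule())
scored_video_count <- function(plan = sampling_plan(),
                               schedule = phase_schedule()) {
  per_phase <- floor(plan$scored_window_h * 60 / plan$interval_min) + 1
  per_day <- per_phase * plan$phases_per_day
  list(
    per_phase = per_phase,
    per_day = per_day,
    total = per_day * schedule$n_days
  )
}

#' Scored-window membership and scored observation time
#'
#' `in_scored_window()` flags timestamps that fall within the scored part of
#' a phase (its first `scored_window_h` hours). `scored_minutes()` converts
#' an in-window timestamp to cumulative scored observation time: minutes of
#' scored footage elapsed before it, skipping unscored gaps. Attack
#' latencies are measured on this clock, since behavior is only observable
#' while videos are scored.
#'
#' @param time POSIXct vector.
#' @param schedule A [phase_schedule()].
#' @param plan A [sampling_plan()].
#' @return Logical vector (`in_scored_window`) or numeric minutes vector
#'   (`scored_minutes`; `NA` for timestamps outside scored windows).
#' @export
in_scored_window <- function(time, schedule, plan = sampling_plan()) {
  ph <- assign_phase(time, schedule, strict = FALSE)
  day_mins <- 2 * schedule$phase_hours * 60
  within <- ph$mins - (ph$day - 1) * day_mins
  phase_min <- ifelse(ph$phase == "dark", within,
                      within - schedule$phase_hours * 60)
  !is.na(phase_min) & phase_min <= plan$scored_window_h * 60
}

#' @rdname in_scored_window
#' @export
scored_minutes <- function(time, schedule, plan = sampling_plan()) {
  ph <- assign_phase(time, schedule, strict = FALSE)
  day_mins <- 2 * schedule$phase_hours * 60
  within <- ph$mins - (ph$day - 1) * day_mins
  phase_min <- ifelse(ph$phase == "dark", within,
                      within - schedule$phase_hours * 60)
  w <- plan$scored_window_h * 60
  ok <- !is.na(phase_min) & phase_min <= w
  prior_phases <- (ph$day - 1) * 2 + ifelse(ph$phase == "dark", 0, 1)
  out <- prior_phases * w + phase_min
  out[!ok] <- NA_real_
  out
}
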