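#' Read and write ethogram event tables
#'
#' The ethogram CSV dialect has one row per scored behavior occurrence with
#' columns `group_id`, `animal_id`, `target_id` (empty for non-social
#' behaviors), `behavior`, `start_time` (ISO 8601), `duration_s`,
#' `location`. Internally events use the shorter names `actor`, `target`,
#' `start`.
#'
#' @param path Path to a CSV file.
#' @param tz Time zone for parsing timestamps (default UTC).
#' @return `read_ethogram()`: a tibble of events.
#' @export
read_ethogram <- function(path, tz = "UTC") {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      group_id = readr::col_character(),
      animal_id = readr::col_character(),
      target_id = readr::col_character(),
      behavior = readr::col_character(),
      start_time = readr::col_datetime(),
      duration_s = readr::col_double(),
      location = readr::col_character()
    ),
    progress = FALSE
  )
  attr(x$start_time, "tzone") <- tz
  tibble::tibble(
    group_id = x$group_id, actor = x$animal_id, target = x$target_id,
    behavior = x$behavior, start = x$start_time,
    duration_s = x$duration_s, location = x$location
  )
}

#' @param events A tibble of events as returned by [read_ethogram()] or
#'   [simulate_group()].
#' @rdname read_ethogram
#' @export
write_ethogram <- function(events, path) {
  out <- tibble::tibble(
    group_id = events$group_id, animal_id = events$actor,
    target_id = events$target, behavior = events$behavior,
    start_time = format(events$start, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    duration_s = events$duration_s, location = events$location
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write RFID event streams
#'
#' The RFID CSV dialect has one row per reader activation: `timestamp`
#' (ISO 8601), `animal_id`, `reader_id` (integer index into the grid),
#' `duration_ms`.
#'
#' @param path Path to a CSV file.
#' @param tz Time zone for parsing timestamps (default UTC).
#' @return `read_rfid()`: a tibble with columns `time`, `animal`, `reader`,
#'   `duration_ms`, sorted by animal then time.
#' @export
read_rfid <- function(path, tz = "UTC") {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      animal_id = readr::col_character(),
      reader_id = readr::col_integer(),
      duration_ms = readr::col_double()
    ),
    progress = FALSE
  )
  attr(x$timestamp, "tzone") <- tz
  out <- tibble::tibble(
    time = x$timestamp, animal = x$animal_id,
    reader = x$reader_id, duration_ms = x$duration_ms
  )
  dplyr::arrange(out, .data$animal, .data$time)
}

#' @param rfid A tibble of RFID events as returned by [read_rfid()].
#' @rdname read_rfid
#' @export
write_rfid <- function(rfid, path) {
  out <- tibble::tibble(
    timestamp = format(rfid$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    animal_id = rfid$animal, reader_id = rfid$reader,
    duration_ms = rfid$duration_ms
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
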