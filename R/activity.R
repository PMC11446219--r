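#' Hourly distance traveled per animal
#'
#' Reconstructs locomotor activity from the RFID stream: for each animal the
#' events are sorted by time and each transition between two different
#' readers contributes the Euclidean distance between their centers.
#' Repeated detections on the same reader contribute nothing. A transition
#' spanning an hour boundary is credited to the hour of the later event.
#'
#' Hours with no detections for an animal are reported with distance 0 and
#' flagged `no_detection = TRUE`, so that downstream averages can exclude
#' them instead of treating sensor dropout as immobility.
#'
#' @param rfid RFID events (see [read_rfid()]).
#' @param grid A [reader_grid()].
#' @param schedule A [phase_schedule()].
#' @return A tibble with one row per (animal, day, phase, phase_hour):
#'   `distance_m`, `n_events`, `no_detection`.
#' @export
distance_per_hour <- function(rfid, grid, schedule) {
  stopifnot(nrow(rfid) > 0)
  if (!all(rfid$reader %in% grid$reader)) {
    stop("unknown reader index in RFID stream")
  }
  ph <- assign_phase(rfid$time, schedule)
  d <- tibble::tibble(
    animal = rfid$animal,
    mins = ph$mins,
    day = ph$day, phase = ph$phase, phase_hour = ph$phase_hour,
    x = grid$x[match(rfid$reader, grid$reader)],
    y = grid$y[match(rfid$reader, grid$reader)]
  )
  d <- dplyr::arrange(d, .data$animal, .data$mins)
  d <- dplyr::mutate(
    dplyr::group_by(d, .data$animal),
    step = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                  (.data$y - dplyr::lag(.data$y))^2)
  )
  d <- dplyr::ungroup(d)
  d$step[is.na(d$step)] <- 0
  hourly <- dplyr::summarise(
    dplyr::group_by(d, .data$animal, .data$day, .data$phase, .data$phase_hour),
    distance_m = sum(.data$step), n_events = dplyr::n(), .groups = "drop"
  )
  # full (animal x hour) scaffold so silent hours are visible
  scaffold <- tidyr::expand_grid(
    animal = sort(unique(rfid$animal)),
    day = seq_len(schedule$n_days),
    phase = c("dark", "light"),
    phase_hour = seq_len(schedule$phase_hours)
  )
  out <- dplyr::left_join(
    scaffold, hourly,
    by = c("animal", "day", "phase", "phase_hour")
  )
  out$no_detection <- is.na(out$n_events)
  out$distance_m[out$no_detection] <- 0
  out$n_events[out$no_detection] <- 0L
  dplyr::arrange(out, .data$animal, .data$day,
                 dplyr::desc(.data$phase), .data$phase_hour)
}

#' Place-preference map from RFID activations
#'
#' Computes the relative frequency (%) with which each reader of the grid
#' was activated, optionally restricted to one phase. By default each
#' activation counts once ("frequency of activation"); `weight =
#' "duration"` weights activations by their event duration instead.
#'
#' @param rfid RFID events.
#' @param grid A [reader_grid()].
#' @param schedule A [phase_schedule()]; required when `phase` is given.
#' @param phase Optional phase filter ("dark" or "light").
#' @param weight `"count"` (default) or `"duration"`.
#' @return An object of class `place_preference`: the grid tibble with an
#'   added `percent` column summing to 100.
#' @export
place_preference <- function(rfid, grid, schedule = NULL, phase = NULL,
                             weight = c("count", "duration")) {
  weight <- match.arg(weight)
  if (!all(rfid$reader %in% grid$reader)) {
    stop("unknown reader index in RFID stream")
  }
  sel <- rfid
  if (!is.null(phase)) {
    if (is.null(schedule)) stop("`schedule` is required to filter by phase")
    ph <- assign_phase(sel$time, schedule)
    sel <- sel[ph$phase == phase, ]
  }
  if (nrow(sel) == 0) {
    stop("no RFID events left after filtering; cannot build a preference map")
  }
  w <- if (weight == "duration") sel$duration_ms else rep(1, nrow(sel))
  totals <- tapply(w, factor(sel$reader, levels = grid$reader), sum)
  totals[is.na(totals)] <- 0
  out <- tibble::as_tibble(grid)
  out$percent <- as.numeric(totals) / sum(totals) * 100
  structure(out, class = c("place_preference", class(out)),
            weight = weight, phase = phase %||% "all")
}

#' Contrast two place-preference maps
#'
#' Elementwise difference (`map_a - map_b`) of two preference maps built on
#' the same grid, plus per-area summaries obtained by summing member
#' readers — the open-vs-burrow contrast used to compare genotypes.
#'
#' @param map_a,map_b Objects from [place_preference()] on the same grid.
#' @return A list with `delta` (grid tibble with `delta_percent`) and
#'   `area_summary` (tibble: `area`, `percent_a`, `percent_b`, `delta`).
#' @export
zone_contrast <- function(map_a, map_b) {
  if (nrow(map_a) != nrow(map_b) ||
      !all(map_a$reader == map_b$reader) ||
      !all(map_a$zone == map_b$zone)) {
    stop("preference maps were built on different grids")
  }
  delta <- tibble::as_tibble(map_a[, c("reader", "row", "col", "zone", "area")])
  delta$delta_percent <- map_a$percent - map_b$percent
  area <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(area = map_a$area, a = map_a$percent, b = map_b$percent),
      .data$area
    ),
    percent_a = sum(.data$a), percent_b = sum(.data$b),
    delta = sum(.data$a) - sum(.data$b), .groups = "drop"
  )
  list(delta = delta, area_summary = area)
}

#' Heatmap of a place-preference map
#'
#' Renders the preference map as the familiar grid heatmap: one tile per
#' reader in its physical position, shaded by relative activation.
#'
#' @param map A [place_preference()] result.
#' @return A ggplot object.
#' @export
plot_place_preference <- function(map) {
  ggplot2::ggplot(
    tibble::as_tibble(map),
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$percent)
  ) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "% activations") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Place preference (%s phase)", attr(map, "phase"))
    ) +
    ggplot2::theme_minimal()
}
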