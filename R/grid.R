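#' RFID reader grid geometry and zone map
#'
#' The VBS floor is monitored by a grid of RFID readers (24 by default,
#' laid out 4 rows x 6 columns). Each reader maps to a functional zone of
#' the cage and to one of two areas: the exposed open area (columns 1-4:
#' feeder and water access, risky center, "safer" wall strip next to the
#' burrow partition) and the sheltered burrow area (columns 5-6: one burrow
#' reached through two tunnels in the top half, a second burrow with a
#' single tunnel in the bottom half).
#'
#' Reader indices run row-major: reader `(r-1)*ncol + c` sits at row `r`,
#' column `c`. Physical positions are `(col*pitch, row*pitch)`; the default
#' pitch of 0.08 m between reader centers matches a bench-scale VBS floor.
#' Real installations can supply their own `zone_map`.
#'
#' @param nrow,ncol Grid dimensions (default 4 x 6).
#' @param pitch Distance in meters between adjacent reader centers.
#' @param zone_map Optional data frame with columns `reader`, `row`, `col`,
#'   `zone`, `area` overriding the default layout; must cover every reader
#'   exactly once.
#' @return An object of class `reader_grid`: a tibble with columns `reader`,
#'   `row`, `col`, `x`, `y` (meters), `zone`, `area`, plus attributes
#'   `nrow`, `ncol`, `pitch`.
#' @export
#' @examples
#' g <- reader_grid()
#' table(g$area)
reader_grid <- function(nrow = 4, ncol = 6, pitch = 0.08, zone_map = NULL) {
  stopifnot(nrow >= 1, ncol >= 1, pitch > 0)
  if (is.null(zone_map)) {
    if (nrow != 4 || ncol != 6) {
      stop("the default zone map is defined for a 4 x 6 grid; ",
           "supply `zone_map` for other layouts")
    }
    zone_map <- default_zone_map()
  }
  zone_map <- tibble::as_tibble(zone_map)
  n <- nrow * ncol
  stopifnot(
    all(c("reader", "row", "col", "zone", "area") %in% names(zone_map)),
    setequal(zone_map$reader, seq_len(n)),
    !anyDuplicated(zone_map$reader),
    all(zone_map$area %in% c("open", "burrow"))
  )
  g <- dplyr::arrange(zone_map, .data$reader)
  g$x <- g$col * pitch
  g$y <- g$row * pitch
  g <- g[, c("reader", "row", "col", "x", "y", "zone", "area")]
  structure(g, class = c("reader_grid", class(g)),
            nrow = nrow, ncol = ncol, pitch = pitch)
}

# Default 4 x 6 layout: column 1 carries the feeder (top) and water spout
# (bottom); columns 2-3 are the open center; column 4 is the wall strip at
# the burrow partition; columns 5-6 are the burrow half, split into a
# two-tunnel burrow (rows 1-2) and a one-tunnel burrow (rows 3-4).
default_zone_map <- function() {
  idx <- function(r, c) (r - 1L) * 6L + c
  rows <- rep(1:4, each = 6)
  cols <- rep(1:6, times = 4)
  zone <- character(24)
  area <- character(24)
  for (k in seq_len(24)) {
    r <- rows[k]; c <- cols[k]
    if (c <= 4) {
      area[k] <- "open"
      zone[k] <- if (c == 1) {
        if (r <= 2) "feeder" else "water"
      } else if (c == 4) "wall" else "center"
    } else {
      area[k] <- "burrow"
      zone[k] <- if (r <= 2) {
        if (c == 5) "tunnel1" else "burrow1"
      } else {
        if (c == 5 && r == 3) "tunnel2" else "burrow2"
      }
    }
  }
  tibble::tibble(reader = seq_len(24), row = rows, col = cols,
                 zone = zone, area = area)
}

#' Map reader zones to ethogram location labels
#'
#' Ethogram locations use a coarser vocabulary than the reader zone map:
#' burrow readers are "chamber" or "tunnel", open readers keep their zone
#' name (`feeder`, `water`, `center`, `wall`).
#'
#' @param grid A [reader_grid()].
#' @return Character vector of location labels, indexed by reader.
#' @export
reader_locations <- function(grid) {
  loc <- grid$zone
  loc[grepl("^burrow", loc)] <- "chamber"
  loc[grepl("^tunnel", loc)] <- "tunnel"
  loc
}
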