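#' The default VBS behavior catalog (ethogram)
#'
#' Returns the catalog of social and non-social mouse behaviors scored in the
#' visible burrow system. Each behavior belongs to one domain, is flagged as
#' social (requires a target animal) or not, and may carry a location
#' constraint: some behaviors are only meaningful in particular zones of the
#' cage (huddling is scored in the burrow chambers only, struggling at the
#' feeder happens at the feeder by definition), and some are explicitly not
#' scored in the chambers where visibility is limited.
#'
#' Location constraints are encoded as comma-separated zone lists in
#' `allowed_locations` (event must be in one of these) and
#' `forbidden_locations` (event must not be in any of these); `NA` means
#' unconstrained. Zone vocabulary: `feeder`, `water`, `center`, `wall` (open
#' area) and `chamber`, `tunnel` (burrow area).
#'
#' @return A tibble with columns `behavior`, `domain`
#'   (affiliative/defensive/offensive/approach/maintenance/activity),
#'   `social` (logical), `allowed_locations`, `forbidden_locations`.
#' @export
#' @examples
#' default_catalog()
default_catalog <- function() {
  tibble::tribble(
    ~behavior,            ~domain,       ~social, ~allowed_locations, ~forbidden_locations,
    "allogrooming",       "affiliative", TRUE,    NA,                 NA,
    "huddle",             "affiliative", TRUE,    "chamber",          NA,
    "flight",             "defensive",   TRUE,    NA,                 NA,
    "chasing",            "offensive",   TRUE,    NA,                 NA,
    "contact",            "offensive",   TRUE,    NA,                 "chamber",
    "struggle",           "offensive",   TRUE,    NA,                 NA,
    "struggle_at_feeder", "offensive",   TRUE,    "feeder",           NA,
    "mounting",           "offensive",   TRUE,    NA,                 NA,
    "biting",             "offensive",   TRUE,    NA,                 NA,
    "approach_to_front",  "approach",    TRUE,    NA,                 NA,
    "approach_to_back",   "approach",    TRUE,    NA,                 NA,
    "following",          "approach",    TRUE,    NA,                 NA,
    "sniffing",           "approach",    TRUE,    NA,                 "chamber",
    "drinking",           "maintenance", FALSE,   "water",            NA,
    "eating",             "maintenance", FALSE,   "feeder",           NA,
    "grooming",           "maintenance", FALSE,   NA,                 NA,
    "moving",             "activity",    FALSE,   NA,                 NA,
    "immobile",           "activity",    FALSE,   NA,                 NA
  )
}

#' Build a behavior catalog
#'
#' Constructs (and checks) a behavior catalog from a data frame with the same
#' columns as [default_catalog()]. Social behaviors must belong to a social
#' domain (affiliative, defensive, offensive or approach) and names must be
#' unique.
#'
#' @param x A data frame with columns `behavior`, `domain`, `social`, and
#'   optionally `allowed_locations`, `forbidden_locations`.
#' @return A validated catalog tibble.
#' @export
behavior_catalog <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("behavior", "domain", "social")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"allowed_locations" %in% names(x)) x$allowed_locations <- NA_character_
  if (!"forbidden_locations" %in% names(x)) x$forbidden_locations <- NA_character_
  if (anyDuplicated(x$behavior)) {
    stop("behavior names must be unique within a catalog")
  }
  social_domains <- c("affiliative", "defensive", "offensive", "approach")
  bad <- x$social & !(x$domain %in% social_domains)
  if (any(bad)) {
    stop(
      "social behaviors must have a social domain: ",
      paste(x$behavior[bad], collapse = ", ")
    )
  }
  x
}

split_zones <- function(z) {
  if (is.na(z)) character(0) else trimws(strsplit(z, ",")[[1]])
}

#' Validate ethogram events against a catalog
#'
#' Checks every event against the structural rules of the ethogram: the
#' behavior label must exist in the catalog; social behaviors carry a target
#' animal and non-social behaviors do not; an animal cannot target itself;
#' durations are non-negative; and the event location must satisfy the
#' behavior's location constraint (e.g. huddle is scored in chambers only,
#' struggle at feeder at the feeder only).
#'
#' Rather than failing on the first bad row, all violations are collected
#' into a report so a whole scoring session can be audited at once.
#'
#' @param events A data frame of behavior events with columns `actor`,
#'   `target`, `behavior`, `duration_s`, `location` (see [read_ethogram()]).
#' @param catalog A behavior catalog, by default [default_catalog()].
#' @return An object of class `vbs_validation`: a list with `events` (the
#'   input), `report` (tibble with `row`, `rule`, `detail`; zero rows when
#'   everything is valid) and `valid` (logical).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   actor = "m1", target = "m2", behavior = "huddle",
#'   duration_s = 30, location = "open"
#' )
#' validate_events(ev)$report # huddle outside chambers -> violation
validate_events <- function(events, catalog = default_catalog()) {
  events <- tibble::as_tibble(events)
  catalog <- behavior_catalog(catalog)
  report <- list()
  add <- function(rows, rule, detail) {
    if (length(rows) > 0) {
      report[[length(report) + 1]] <<- tibble::tibble(
        row = rows, rule = rule, detail = detail
      )
    }
  }

  if (nrow(events) > 0) {
    idx <- seq_len(nrow(events))
    known <- events$behavior %in% catalog$behavior
    add(idx[!known], "unknown_behavior",
        paste0("behavior '", events$behavior[!known], "' not in catalog"))

    cat_row <- match(events$behavior, catalog$behavior)
    social <- catalog$social[cat_row]
    has_target <- !is.na(events$target) & events$target != ""

    miss <- known & social & !has_target
    add(idx[miss], "missing_target", "social behavior without a target animal")
    extra <- known & !social & has_target
    add(idx[extra], "unexpected_target", "non-social behavior with a target")
    selfd <- has_target & !is.na(events$actor) & events$target == events$actor
    add(idx[selfd], "self_target", "actor and target are the same animal")

    negd <- !is.na(events$duration_s) & events$duration_s < 0
    add(idx[negd], "negative_duration", "duration is negative")

    for (i in idx[known]) {
      allowed <- split_zones(catalog$allowed_locations[cat_row[i]])
      forbidden <- split_zones(catalog$forbidden_locations[cat_row[i]])
      loc <- events$location[i]
      if (length(allowed) > 0 && !(loc %in% allowed)) {
        add(i, "location_constraint",
            paste0("'", events$behavior[i], "' only scored in: ",
                   paste(allowed, collapse = ", ")))
      }
      if (length(forbidden) > 0 && loc %in% forbidden) {
        add(i, "location_constraint",
            paste0("'", events$behavior[i], "' not scored in: ",
                   paste(forbidden, collapse = ", ")))
      }
    }
  }

  report <- if (length(report) > 0) {
    dplyr::arrange(dplyr::bind_rows(report), .data$row)
  } else {
    tibble::tibble(row = integer(0), rule = character(0), detail = character(0))
  }
  structure(
    list(events = events, report = report, valid = nrow(report) == 0),
    class = "vbs_validation"
  )
}

#' @export
print.vbs_validation <- function(x, ...) {
  if (x$valid) {
    cat("All", nrow(x$events), "events valid.\n")
  } else {
    cat(nrow(x$report), "violation(s) in", nrow(x$events), "events:\n")
    print(x$report, ...)
  }
  invisible(x)
}
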