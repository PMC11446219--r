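#' Behavior occurrence totals
#'
#' Tallies scored occurrences per animal, phase and behavior, either pooled
#' over experimental days or kept per day. Every behavior of the catalog
#' appears in the output, with count 0 when never observed, so downstream
#' feature tables have a fixed shape.
#'
#' @param events Validated behavior events.
#' @param schedule A [phase_schedule()] used to annotate events with day and
#'   phase.
#' @param catalog Behavior catalog (defaults to [default_catalog()]).
#' @param per_day If `TRUE`, keep a `day` column; otherwise pool days.
#' @param animals Optional character vector of animals to include (so that
#'   animals with zero events still get rows); defaults to the actors seen.
#' @return A tibble with columns `animal`, (`day`,) `phase`, `behavior`,
#'   `n`.
#' @export
behavior_totals <- function(events, schedule, catalog = default_catalog(),
                            per_day = FALSE, animals = NULL) {
  catalog <- behavior_catalog(catalog)
  animals <- animals %||% sort(unique(events$actor))
  ph <- if (nrow(events) > 0) {
    assign_phase(events$start, schedule)
  } else {
    tibble::tibble(day = integer(0), phase = character(0))
  }
  d <- tibble::tibble(
    animal = events$actor, day = ph$day, phase = ph$phase,
    behavior = events$behavior
  )
  keys <- if (per_day) c("animal", "day", "phase", "behavior") else
    c("animal", "phase", "behavior")
  counts <- dplyr::count(d, dplyr::across(dplyr::all_of(keys)))
  scaffold <- tidyr::expand_grid(
    animal = animals,
    day = if (per_day) seq_len(schedule$n_days) else NA,
    phase = c("dark", "light"),
    behavior = catalog$behavior
  )
  if (!per_day) scaffold$day <- NULL
  out <- dplyr::left_join(scaffold, counts, by = keys)
  out$n[is.na(out$n)] <- 0L
  out
}

#' Latency to first attack
#'
#' Time, in minutes of scored observation, from entry into the VBS to each
#' animal's first attack. Attacks default to the three-behavior filter
#' (struggle, struggle at feeder, chasing). Latency is measured on the
#' scored-footage clock (see [scored_minutes()]): behavior is only
#' observable during scored video windows, so unscored gaps do not count.
#' Animals that never attack are censored at the total scored observation
#' time and flagged, never silently reported as a plain number.
#'
#' @param events Behavior events.
#' @param schedule A [phase_schedule()].
#' @param plan A [sampling_plan()] defining the scored windows.
#' @param attack_set Behaviors counting as attacks for the latency filter.
#' @param animals Animals to report (default: all actors seen).
#' @return A tibble `animal`, `latency_min`, `censored`, with the group
#'   minimum in attribute `"group_min"`.
#' @export
attack_latency <- function(events, schedule, plan = sampling_plan(),
                           attack_set = c("struggle", "struggle_at_feeder",
                                          "chasing"),
                           animals = NULL) {
  animals <- animals %||% sort(unique(events$actor))
  total_scored <- plan$scored_window_h * 60 * plan$phases_per_day *
    schedule$n_days
  atk <- events[events$behavior %in% attack_set, ]
  sm <- if (nrow(atk) > 0) scored_minutes(atk$start, schedule, plan) else numeric(0)
  out <- tibble::tibble(animal = animals, latency_min = NA_real_,
                        censored = TRUE)
  for (i in seq_along(animals)) {
    mine <- sm[atk$actor == animals[i] & !is.na(sm)]
    if (length(mine) > 0) {
      out$latency_min[i] <- min(mine)
      out$censored[i] <- FALSE
    }
  }
  out$latency_min[out$censored] <- total_scored
  attr(out, "group_min") <- if (any(!out$censored)) {
    min(out$latency_min[!out$censored])
  } else {
    NA_real_
  }
  out
}

#' Fight/threat ratio
#'
#' Ratio of overt fights (struggle + struggle at feeder) to threats
#' (chasing + following + approach to back) per animal; a proxy for the
#' loss of ritualized de-escalation — the lower the ratio, the more threats
#' suffice to settle conflicts. Degenerate denominators are flagged rather
#' than thrown: positive fights with zero threats give an `infinite` flag,
#' 0/0 gives `undefined`.
#'
#' @param events Behavior events.
#' @param animals Animals to report (default: all actors seen).
#' @param fight_set,threat_set Behavior labels counted in the numerator and
#'   denominator.
#' @return A tibble `animal`, `fights`, `threats`, `ratio`, `flag`
#'   (`"ok"`, `"infinite"` or `"undefined"`).
#' @export
fight_threat_ratio <- function(events, animals = NULL,
                               fight_set = c("struggle", "struggle_at_feeder"),
                               threat_set = c("chasing", "following",
                                              "approach_to_back")) {
  animals <- animals %||% sort(unique(events$actor))
  out <- tibble::tibble(
    animal = animals,
    fights = vapply(animals, function(a) {
      sum(events$actor == a & events$behavior %in% fight_set)
    }, integer(1), USE.NAMES = FALSE),
    threats = vapply(animals, function(a) {
      sum(events$actor == a & events$behavior %in% threat_set)
    }, integer(1), USE.NAMES = FALSE)
  )
  out$ratio <- ifelse(out$threats > 0, out$fights / out$threats, NA_real_)
  out$flag <- dplyr::case_when(
    out$threats > 0 ~ "ok",
    out$fights > 0 ~ "infinite",
    TRUE ~ "undefined"
  )
  out
}

#' Pathological-aggression profile
#'
#' Assembles, per animal, the quantitative criteria used to diagnose
#' escalated aggression: latency to first attack, total number of attacks,
#' mean duration of a single attack, the fight/threat ratio, and the modal
#' zone where aggression takes place. Short latency together with frequent,
#' long attacks concentrated at a resource point is the pathological
#' signature.
#'
#' Two attack definitions are in play and both are explicit parameters: the
#' latency filter includes chasing (`latency_set`), while attack counts and
#' durations are taken over the overt fight behaviors only (`count_set`).
#'
#' @param events Behavior events of one group.
#' @param schedule A [phase_schedule()].
#' @param plan A [sampling_plan()].
#' @param latency_set Behaviors for the latency filter.
#' @param count_set Behaviors counted as attacks for frequency/duration.
#' @param animals Animals to report.
#' @return A tibble with one row per animal: `latency_min`, `censored`,
#'   `total_attacks`, `mean_attack_duration_s`, `fights`, `threats`,
#'   `ratio`, `flag`, `hotspot` (modal aggression zone, `NA` when the
#'   animal never attacked).
#' @export
aggression_profile <- function(events, schedule, plan = sampling_plan(),
                               latency_set = c("struggle",
                                               "struggle_at_feeder",
                                               "chasing"),
                               count_set = c("struggle",
                                             "struggle_at_feeder"),
                               animals = NULL) {
  animals <- animals %||% sort(unique(events$actor))
  lat <- attack_latency(events, schedule, plan, latency_set, animals)
  ftr <- fight_threat_ratio(events, animals)
  atk <- events[events$behavior %in% count_set, ]
  per <- lapply(animals, function(a) {
    mine <- atk[atk$actor == a, ]
    hotspot <- if (nrow(mine) > 0) {
      names(sort(table(mine$location), decreasing = TRUE))[1]
    } else {
      NA_character_
    }
    tibble::tibble(
      animal = a,
      total_attacks = nrow(mine),
      mean_attack_duration_s = if (nrow(mine) > 0) {
        mean(mine$duration_s)
      } else {
        NA_real_
      },
      hotspot = hotspot
    )
  })
  per <- dplyr::bind_rows(per)
  out <- dplyr::left_join(lat, per, by = "animal")
  out <- dplyr::left_join(
    out, ftr[, c("animal", "fights", "threats", "ratio", "flag")],
    by = "animal"
  )
  out
}
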