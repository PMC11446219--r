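#' Bundle one group's recordings
#'
#' The unit the pipeline consumes: a group of co-housed animals with its
#' genotype label, behavior events, RFID stream and housing schedule.
#'
#' @param group_id Group label.
#' @param genotype Genotype label (e.g. "WT", "KO").
#' @param animals Character vector of animal ids (default group size 4).
#' @param events Behavior events tibble.
#' @param rfid RFID events tibble.
#' @param schedule A [phase_schedule()].
#' @param group_size Expected number of animals.
#' @return An object of class `vbs_group`.
#' @export
group_dataset <- function(group_id, genotype, animals, events, rfid,
                          schedule, group_size = 4) {
  if (length(animals) != group_size) {
    stop("expected ", group_size, " animals, got ", length(animals))
  }
  used <- unique(c(events$actor, events$target[!is.na(events$target)]))
  if (!all(used %in% animals)) {
    stop("events mention animals outside the group: ",
         paste(setdiff(used, animals), collapse = ", "))
  }
  structure(
    list(group_id = group_id, genotype = genotype, animals = animals,
         events = events, rfid = rfid, schedule = schedule),
    class = "vbs_group"
  )
}

#' @export
print.vbs_group <- function(x, ...) {
  cat(sprintf("VBS group %s (%s): %d animals, %d behavior events, %d RFID events\n",
              x$group_id, x$genotype, length(x$animals),
              nrow(x$events), nrow(x$rfid)))
  invisible(x)
}

#' Configuration of the synthetic VBS generator
#'
#' Defines the statistical structure the simulator plants into generated
#' groups: per-behavior event rates per scored 4-h window (dark vs light),
#' genotype effects as multiplicative rate changes for the knockout,
#' genotype-dependent first-attack latencies, a latent dominance hierarchy
#' (Bradley-Terry strengths steering who initiates and wins agonistic
#' interactions), circadian activity via a dark-phase step-rate multiplier,
#' and phase-dependent zone preferences for the RFID walk.
#'
#' Defaults mirror a serotonin-depletion-like phenotype: the knockout
#' multiplies struggling at feeder by 4 and chasing by 3, reduces
#' allogrooming to 0.4x and sniffing to 0.6x, eats 1.5x as often and
#' self-grooms 0.7x; first attacks come after ~16 min of scored
#' observation against ~150 min in the wildtype (exponential). The latent
#' strengths (8, 4, 2, 1) encode one steep, despotic-style hierarchy per
#' group with 2:1 win odds between adjacent ranks.
#'
#' @param group_size Animals per group (default 4).
#' @param base_rates Tibble `behavior`, `dark`, `light`: expected events
#'   per animal per scored 4-h window in each phase.
#' @param ko_multipliers Named numeric vector of knockout rate multipliers.
#' @param latency_mean_min Named vector, mean scored-minutes to first
#'   attack per genotype.
#' @param strengths Latent Bradley-Terry strengths, one per animal.
#' @param affiliative_skew Exponent applied to the strengths when choosing
#'   the initiator of non-agonistic social behaviors (default 0.5):
#'   affiliative and investigative initiation tracks rank more weakly than
#'   agonistic outcomes do.
#' @param animal_sd Log-normal standard deviation of per-animal rate
#'   multipliers for non-social behaviors (default 0.25), modeling stable
#'   individual variation in maintenance and locomotor activity.
#' @param dark_light_activity Dark-phase multiplier on the RFID step rate.
#' @param step_rate_light RFID walk steps per hour in the light phase.
#' @param zone_pref List with elements `dark` and `light`: named weights
#'   over the grid zones steering the walk.
#' @param dispersion Negative-binomial size for event counts; `Inf`
#'   (default) is the Poisson limit.
#' @param duration_mean_s Named vector of mean event durations; behaviors
#'   not listed use `default`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    group_size = 4,
    base_rates = default_base_rates(),
    ko_multipliers = c(
      struggle_at_feeder = 4, chasing = 3, allogrooming = 0.4,
      sniffing = 0.6, eating = 1.5, grooming = 0.7
    ),
    latency_mean_min = c(WT = 150, KO = 16),
    strengths = c(8, 4, 2, 1),
    affiliative_skew = 0.5,
    animal_sd = 0.25,
    dark_light_activity = 2.5,
    step_rate_light = 60,
    zone_pref = list(
      dark = c(feeder = 3, water = 1.5, center = 1, wall = 1.2,
               tunnel1 = 0.6, burrow1 = 0.7, tunnel2 = 0.5, burrow2 = 0.5),
      light = c(feeder = 0.3, water = 0.3, center = 0.15, wall = 0.3,
                tunnel1 = 1.5, burrow1 = 3.5, tunnel2 = 0.8, burrow2 = 1.8)
    ),
    dispersion = Inf,
    duration_mean_s = c(
      struggle = 6, struggle_at_feeder = 6, chasing = 5, huddle = 60,
      immobile = 30, eating = 15, default = 5
    )) {
  stopifnot(
    all(base_rates$dark >= 0), all(base_rates$light >= 0),
    all(ko_multipliers > 0), all(strengths > 0),
    length(strengths) == group_size,
    dark_light_activity > 0, step_rate_light > 0, dispersion > 0,
    affiliative_skew >= 0, animal_sd >= 0
  )
  structure(
    list(
      group_size = group_size, base_rates = base_rates,
      ko_multipliers = ko_multipliers, latency_mean_min = latency_mean_min,
      strengths = strengths, affiliative_skew = affiliative_skew,
      animal_sd = animal_sd, dark_light_activity = dark_light_activity,
      step_rate_light = step_rate_light, zone_pref = zone_pref,
      dispersion = dispersion, duration_mean_s = duration_mean_s
    ),
    class = "synthetic_config"
  )
}

#' Default per-window behavior rates
#'
#' Expected events per animal per scored 4-h window, chosen as plausible
#' wildtype home-cage magnitudes: frequent maintenance and locomotion,
#' moderate social investigation, sparse overt aggression, and near-absent
#' mounting and biting; almost everything is more frequent in the dark
#' phase except huddling and immobility, which dominate the resting phase.
#'
#' @return Tibble `behavior`, `dark`, `light`.
#' @export
default_base_rates <- function() {
  tibble::tribble(
    ~behavior,            ~dark, ~light,
    "allogrooming",        6,     1.5,
    "huddle",              1,     4,
    "flight",              2,     0.5,
    "chasing",             1.5,   0.2,
    "contact",             4,     0.8,
    "struggle",            1.5,   0.3,
    "struggle_at_feeder",  8,     1,
    "mounting",            0.05,  0.02,
    "biting",              0.05,  0.02,
    "approach_to_front",   5,     1,
    "approach_to_back",    4,     0.8,
    "following",           3,     0.5,
    "sniffing",            8,     1.5,
    "drinking",            3,     1,
    "eating",             10,     3,
    "grooming",            8,     3,
    "moving",             15,     4,
    "immobile",            5,    10
  )
}

agonistic_set <- function() {
  c("struggle", "struggle_at_feeder", "chasing", "biting", "mounting")
}

rcount <- function(n, mu, dispersion) {
  if (is.finite(dispersion)) {
    stats::rnbinom(n, mu = mu, size = dispersion)
  } else {
    stats::rpois(n, mu)
  }
}

# draw an ordered (winner, loser) pair: initiator chosen proportionally to
# latent strength, opponent likewise among the rest, outcome Bradley-Terry
draw_bout <- function(strengths) {
  k <- length(strengths)
  i <- sample.int(k, 1, prob = strengths)
  others <- (1:k)[-i]
  j <- others[sample.int(length(others), 1, prob = strengths[-i])]
  if (stats::runif(1) < strengths[i] / (strengths[i] + strengths[j])) {
    c(i, j)
  } else {
    c(j, i)
  }
}

location_weights <- function(behavior, phase, catalog, zone_pref) {
  zp <- zone_pref[[phase]]
  locs <- c(
    feeder = unname(zp["feeder"]), water = unname(zp["water"]),
    center = unname(zp["center"]), wall = unname(zp["wall"]),
    chamber = mean(zp[c("burrow1", "burrow2")]),
    tunnel = mean(zp[c("tunnel1", "tunnel2")])
  )
  row <- match(behavior, catalog$behavior)
  allowed <- split_zones(catalog$allowed_locations[row])
  forbidden <- split_zones(catalog$forbidden_locations[row])
  keep <- names(locs)
  if (length(allowed) > 0) keep <- intersect(keep, allowed)
  if (length(forbidden) > 0) keep <- setdiff(keep, forbidden)
  locs[keep]
}

scored_to_time <- function(mins, schedule, plan) {
  w <- plan$scored_window_h * 60
  phase_idx <- floor(mins / w) # 0-based phase counter (dark, light, dark, ...)
  within <- mins - phase_idx * w
  day <- phase_idx %/% 2
  is_light <- phase_idx %% 2 == 1
  offset <- day * 2 * schedule$phase_hours * 60 +
    is_light * schedule$phase_hours * 60 + within
  schedule$start + offset * 60
}

#' Simulate one VBS group
#'
#' Generates a full [group_dataset()]: behavior events drawn per scored
#' window at genotype-adjusted rates (social events routed through the
#' latent dominance hierarchy, locations respecting the catalog's zone
#' constraints, each animal's first attack placed at an
#' exponentially-distributed scored-observation latency) and an RFID
#' stream produced by a nearest-neighbor random walk over the reader grid
#' with phase-dependent step rate and zone preference. Output is fully
#' determined by `seed`.
#'
#' @param genotype `"WT"` or `"KO"` (must match a name in the config's
#'   `latency_mean_min`; multipliers apply to `"KO"`).
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param group_id Group label (also prefixes animal ids).
#' @param schedule A [phase_schedule()].
#' @param plan A [sampling_plan()] defining the scored windows.
#' @param grid A [reader_grid()] for the walk.
#' @param catalog Behavior catalog.
#' @return A `vbs_group`.
#' @export
simulate_group <- function(genotype, config = synthetic_config(), seed = 1,
                           group_id = "g1", schedule = phase_schedule(),
                           plan = sampling_plan(), grid = reader_grid(),
                           catalog = default_catalog()) {
  if (!genotype %in% names(config$latency_mean_min)) {
    stop("no latency mean configured for genotype ", genotype)
  }
  set.seed(seed)
  catalog <- behavior_catalog(catalog)
  k <- config$group_size
  animals <- paste0(group_id, "-m", seq_len(k))
  strengths <- config$strengths
  w_min <- plan$scored_window_h * 60

  dur_mean <- function(b) {
    if (b %in% names(config$duration_mean_s)) {
      config$duration_mean_s[[b]]
    } else {
      config$duration_mean_s[["default"]]
    }
  }

  soft <- strengths^config$affiliative_skew
  # stable per-animal multipliers for non-social rates (individual variation)
  animal_mult <- stats::rlnorm(k, -config$animal_sd^2 / 2, config$animal_sd)

  ev <- list()
  for (day in seq_len(schedule$n_days)) {
    for (phase in c("dark", "light")) {
      phase0 <- schedule$start + ((day - 1) * 24 +
                                    (phase == "light") * schedule$phase_hours) * 3600
      for (b in seq_len(nrow(catalog))) {
        beh <- catalog$behavior[b]
        rate <- config$base_rates[[phase]][
          match(beh, config$base_rates$behavior)]
        if (genotype == "KO" && beh %in% names(config$ko_multipliers)) {
          rate <- rate * config$ko_multipliers[[beh]]
        }
        if (catalog$social[b]) {
          n_ev <- rcount(1, rate * k, config$dispersion)
        } else {
          n_ev <- rcount(1, rate * sum(animal_mult), config$dispersion)
        }
        if (n_ev == 0) next
        lw <- location_weights(beh, phase, catalog, config$zone_pref)
        actor <- character(n_ev)
        target <- rep(NA_character_, n_ev)
        for (e in seq_len(n_ev)) {
          if (catalog$social[b]) {
            if (beh %in% agonistic_set()) {
              pair <- draw_bout(strengths)
            } else {
              i <- sample.int(k, 1, prob = soft)
              pair <- c(i, ((1:k)[-i])[sample.int(k - 1, 1)])
            }
            actor[e] <- animals[pair[1]]
            target[e] <- animals[pair[2]]
          } else {
            actor[e] <- animals[sample.int(k, 1, prob = animal_mult)]
          }
        }
        ev[[length(ev) + 1]] <- tibble::tibble(
          group_id = group_id, actor = actor, target = target,
          behavior = beh,
          start = phase0 + stats::runif(n_ev, 0, w_min * 60 - 1),
          duration_s = round(stats::rexp(n_ev, 1 / dur_mean(beh)), 1),
          location = sample(names(lw), n_ev, replace = TRUE, prob = lw)
        )
      }
    }
  }
  events <- dplyr::bind_rows(ev)

  # plant per-animal first-attack latencies on the scored-observation clock
  latency_set <- c("struggle", "struggle_at_feeder", "chasing")
  total_scored <- w_min * plan$phases_per_day * schedule$n_days
  sm <- scored_minutes(events$start, schedule, plan)
  keep <- rep(TRUE, nrow(events))
  extra <- list()
  for (i in seq_len(k)) {
    L <- stats::rexp(1, 1 / config$latency_mean_min[[genotype]])
    is_attack <- events$actor == animals[i] & events$behavior %in% latency_set
    keep <- keep & !(is_attack & !is.na(sm) & sm < L)
    if (L <= total_scored) {
      pair <- draw_bout(strengths)
      opp <- if (pair[1] == i) pair[2] else pair[1]
      extra[[length(extra) + 1]] <- tibble::tibble(
        group_id = group_id, actor = animals[i], target = animals[opp],
        behavior = "struggle_at_feeder",
        start = scored_to_time(L, schedule, plan),
        duration_s = round(stats::rexp(1, 1 / dur_mean("struggle_at_feeder")), 1),
        location = "feeder"
      )
    }
  }
  events <- dplyr::bind_rows(events[keep, ], extra)
  events <- dplyr::arrange(events, .data$start)

  rfid <- simulate_rfid_walk(animals, config, schedule, grid)

  group_dataset(group_id, genotype, animals, events, rfid, schedule,
                group_size = k)
}

# nearest-neighbor random walk over the reader grid; step rate follows the
# circadian phase, step direction follows the phase's zone preferences
simulate_rfid_walk <- function(animals, config, schedule, grid) {
  nr <- attr(grid, "nrow")
  nc <- attr(grid, "ncol")
  neighbors <- lapply(seq_len(nrow(grid)), function(rd) {
    r <- grid$row[rd]; c <- grid$col[rd]
    cand <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1), c(r, c))
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    (cand[ok, 1] - 1L) * nc + cand[ok, 2]
  })
  total_h <- housing_hours(schedule)
  out <- list()
  for (a in animals) {
    pos <- sample(grid$reader[grid$area == "burrow"], 1)
    times <- list(); readers <- list()
    for (h in seq_len(total_h) - 1L) {
      dark <- (h %% (2 * schedule$phase_hours)) < schedule$phase_hours
      rate <- config$step_rate_light *
        (if (dark) config$dark_light_activity else 1)
      nsteps <- stats::rpois(1, rate)
      if (nsteps == 0) next
      tt <- sort(stats::runif(nsteps, 0, 3600))
      rr <- integer(nsteps)
      pref <- config$zone_pref[[if (dark) "dark" else "light"]]
      for (s in seq_len(nsteps)) {
        nb <- neighbors[[pos]]
        pos <- nb[sample.int(length(nb), 1, prob = pref[grid$zone[nb]])]
        rr[s] <- pos
      }
      times[[length(times) + 1]] <- h * 3600 + tt
      readers[[length(readers) + 1]] <- rr
    }
    out[[a]] <- tibble::tibble(
      time = schedule$start + unlist(times),
      animal = a,
      reader = unlist(readers),
      duration_ms = round(stats::rexp(length(unlist(readers)), 1 / 2000))
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a two-genotype experiment
#'
#' Generates `n_per_genotype` groups per genotype with seeds derived from
#' one master seed.
#'
#' @param n_per_genotype Groups per genotype (default 5).
#' @param config A [synthetic_config()].
#' @param seed Master seed.
#' @param genotypes Genotype labels (default WT/KO).
#' @param ... Passed to [simulate_group()] (schedule, plan, grid, catalog).
#' @return A list of `vbs_group` objects.
#' @export
simulate_experiment <- function(n_per_genotype = 5,
                                config = synthetic_config(), seed = 1,
                                genotypes = c("WT", "KO"), ...) {
  set.seed(seed)
  sub_seeds <- sample.int(1e9, n_per_genotype * length(genotypes))
  out <- list()
  idx <- 0
  for (g in genotypes) {
    for (i in seq_len(n_per_genotype)) {
      idx <- idx + 1
      gid <- paste0(tolower(g), i)
      out[[gid]] <- simulate_group(g, config, seed = sub_seeds[idx],
                                   group_id = gid, ...)
    }
  }
  out
}

#' Simulate a winner/loser interaction sequence
#'
#' Fixture for the rating engine: `n` agonistic bouts among animals with
#' fixed latent strengths. The initiating pair is drawn proportionally to
#' strength and the winner follows the Bradley-Terry probability
#' `P(i beats j) = s_i / (s_i + s_j)`.
#'
#' @param strengths Positive latent strengths; names become animal ids
#'   (default `m1..mk`).
#' @param n Number of interactions.
#' @param seed Integer seed.
#' @return Tibble `index`, `winner`, `loser`.
#' @export
simulate_interactions <- function(strengths, n, seed = 1) {
  stopifnot(length(strengths) >= 2, all(strengths > 0), n >= 1)
  ids <- names(strengths) %||% paste0("m", seq_along(strengths))
  set.seed(seed)
  pairs <- t(vapply(seq_len(n), function(...) draw_bout(strengths),
                    numeric(2)))
  tibble::tibble(
    index = seq_len(n),
    winner = ids[pairs[, 1]],
    loser = ids[pairs[, 2]]
  )
}
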