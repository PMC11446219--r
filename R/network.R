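#' Build a dyadic interaction network
#'
#' Counts directed occurrences of one social behavior between every ordered
#' pair of animals, optionally restricted to one experimental day and
#' phase. Entry (i, j) of the adjacency matrix is the number of events
#' initiated by i toward j; the diagonal is structurally zero.
#'
#' @param events Validated behavior events.
#' @param behavior A social behavior label from the catalog.
#' @param animals Character vector of the group's animals (fixes matrix
#'   size and ordering even when some animals never interact).
#' @param schedule A [phase_schedule()]; required when filtering by day or
#'   phase.
#' @param day Optional experimental day filter.
#' @param phase Optional phase filter; networks are conventionally built
#'   from dark-phase events, when most interactions happen.
#' @param catalog Behavior catalog used to check that `behavior` is social.
#' @return An n x n integer matrix with `dimnames = list(actor, target)`,
#'   of class `dyad_network`, with attributes `behavior`, `day`, `phase`.
#' @export
build_network <- function(events, behavior, animals, schedule = NULL,
                          day = NULL, phase = "dark",
                          catalog = default_catalog()) {
  catalog <- behavior_catalog(catalog)
  row <- match(behavior, catalog$behavior)
  if (is.na(row)) stop("unknown behavior: ", behavior)
  if (!catalog$social[row]) {
    stop("'", behavior, "' is not a social behavior; no dyadic network exists")
  }
  sel <- events[events$behavior == behavior, ]
  if (nrow(sel) > 0 && (!is.null(day) || !is.null(phase))) {
    if (is.null(schedule)) stop("`schedule` is required to filter by day/phase")
    ph <- assign_phase(sel$start, schedule)
    keep <- rep(TRUE, nrow(sel))
    if (!is.null(day)) keep <- keep & ph$day == day
    if (!is.null(phase)) keep <- keep & ph$phase == phase
    sel <- sel[keep, ]
  }
  n <- length(animals)
  adj <- matrix(0L, n, n, dimnames = list(animals, animals))
  if (nrow(sel) > 0) {
    bad <- !(sel$actor %in% animals) | !(sel$target %in% animals)
    if (any(bad)) stop("event actor/target not among the group's animals")
    tab <- table(factor(sel$actor, levels = animals),
                 factor(sel$target, levels = animals))
    adj <- adj + unclass(tab)
  }
  diag(adj) <- 0L
  structure(adj, class = c("dyad_network", "matrix", "array"),
            behavior = behavior, day = day, phase = phase)
}

#' Node interaction strength
#'
#' Overall interaction strength of a node: its total number of interactions
#' within the directed network, incoming plus outgoing (row sum plus column
#' sum). Directed in- and out-strengths are available via `direction` for
#' completeness, although the overall strength is the standard summary.
#'
#' @param network A `dyad_network` matrix from [build_network()].
#' @param animal Animal id(s); default all nodes.
#' @param direction `"total"` (in + out, default), `"in"` or `"out"`.
#' @return Named numeric vector of strengths.
#' @export
interaction_strength <- function(network, animal = NULL,
                                 direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  animal <- animal %||% rownames(network)
  if (!all(animal %in% rownames(network))) {
    stop("unknown animal: ",
         paste(setdiff(animal, rownames(network)), collapse = ", "))
  }
  s <- switch(direction,
    total = rowSums(network) + colSums(network),
    `in` = colSums(network),
    out = rowSums(network)
  )
  s[animal]
}

#' Daily interaction-strength series with genotype comparisons
#'
#' Builds the per-day (dark-phase) network of one behavior for every group
#' and tabulates each animal's overall interaction strength, then compares
#' genotypes day by day with the exact rank-sum test. This is the
#' day-resolved view of how relationship strength develops over housing.
#'
#' @param datasets A list of [group_dataset()] objects.
#' @param behavior Social behavior to build networks from.
#' @param phase Phase filter for the networks (default dark).
#' @param catalog Behavior catalog.
#' @return A list of class `strength_series` with `series` (tibble:
#'   `group`, `genotype`, `animal`, `day`, `strength`) and `tests` (tibble
#'   of per-day [genotype_compare()] results; `NULL` when fewer than two
#'   genotypes are present).
#' @export
strength_series <- function(datasets, behavior, phase = "dark",
                            catalog = default_catalog()) {
  rows <- list()
  for (ds in datasets) {
    for (d in seq_len(ds$schedule$n_days)) {
      net <- build_network(ds$events, behavior, ds$animals, ds$schedule,
                           day = d, phase = phase, catalog = catalog)
      s <- interaction_strength(net)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = ds$group_id, genotype = ds$genotype,
        animal = names(s), day = d, strength = as.numeric(s)
      )
    }
  }
  series <- dplyr::bind_rows(rows)
  genos <- unique(series$genotype)
  tests <- NULL
  if (length(genos) == 2) {
    tests <- dplyr::bind_rows(lapply(sort(unique(series$day)), function(d) {
      a <- series$strength[series$day == d & series$genotype == genos[1]]
      b <- series$strength[series$day == d & series$genotype == genos[2]]
      cmp <- genotype_compare(a, b)
      cmp$day <- d
      cmp
    }))
    attr(tests, "groups") <- genos
  }
  structure(list(series = series, tests = tests, behavior = behavior),
            class = "strength_series")
}

#' Export a network as an edge list
#'
#' @param network A `dyad_network`.
#' @return Tibble `source`, `target`, `weight` for nonzero edges, carrying
#'   the network's behavior/day/phase as columns.
#' @export
network_edges <- function(network) {
  idx <- which(network > 0, arr.ind = TRUE)
  tibble::tibble(
    behavior = attr(network, "behavior") %||% NA_character_,
    day = (attr(network, "day") %||% NA_integer_),
    phase = attr(network, "phase") %||% NA_character_,
    source = rownames(network)[idx[, 1]],
    target = colnames(network)[idx[, 2]],
    weight = network[idx]
  )
}
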