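#' Glicko rating parameters
#'
#' The Glicko system extends Elo with a per-animal rating deviation (RD)
#' that quantifies how uncertain the current rating is: it shrinks with
#' every observed interaction and inflates with inactivity. Ratings start
#' at 0 (rather than the conventional 1500) so that dominants and
#' subordinates stratify above and below zero; "no prior certainty" is
#' expressed as the conventional maximum deviation of 350, which also caps
#' inflation. The update constant `c` governs how fast deviation grows per
#' rating period of inactivity; `c = 1` is an accepted value for mouse
#' agonistic interactions and has little influence on final ratings.
#'
#' @param initial_rating Starting rating for every animal (default 0).
#' @param initial_deviation Starting rating deviation (default 350).
#' @param c Deviation-inflation constant per rating period (default 1).
#' @param deviation_cap Upper bound on the deviation (defaults to
#'   `initial_deviation`).
#' @return An object of class `glicko_params`; `q = ln(10)/400` is the
#'   fixed scale constant of the system.
#' @export
glicko_params <- function(initial_rating = 0, initial_deviation = 350,
                          c = 1, deviation_cap = initial_deviation) {
  stopifnot(initial_deviation > 0, c >= 0, deviation_cap > 0)
  structure(
    list(
      initial_rating = initial_rating,
      initial_deviation = initial_deviation,
      c = c, deviation_cap = deviation_cap,
      q = log(10) / 400
    ),
    class = "glicko_params"
  )
}

#' Fresh Glicko state for a set of animals
#'
#' @param animals Character vector of animal ids.
#' @param params A [glicko_params()].
#' @return A tibble with columns `animal`, `rating`, `deviation`, `idle`
#'   (rating periods since the animal was last observed; feeds deviation
#'   inflation at its next update).
#' @export
glicko_state <- function(animals, params = glicko_params()) {
  stopifnot(length(animals) >= 2, !anyDuplicated(animals))
  tibble::tibble(
    animal = animals,
    rating = params$initial_rating,
    deviation = params$initial_deviation,
    idle = 1
  )
}

g_rd <- function(rd, q) 1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)

#' Single Glicko update for one agonistic interaction
#'
#' Applies one interaction (the initiator of a directed attack wins, the
#' recipient loses; there are no draws) to the current state. Each
#' participant's deviation is first inflated for the rating periods it sat
#' idle, `RD <- min(sqrt(RD^2 + c^2 t), cap)`, then both rating and
#' deviation are updated from the expected score
#' `E = 1 / (1 + 10^(-g(RD_opp) (r - r_opp) / 400))`:
#' `r' = r + q / (1/RD^2 + 1/d^2) g(RD_opp) (s - E)` with `s = 1` for the
#' winner and `0` for the loser, and `RD' = sqrt(1 / (1/RD^2 + 1/d^2))`
#' where `d^2 = 1 / (q^2 g(RD_opp)^2 E (1 - E))`. Only the two
#' participants' ratings change; everyone else's idle counter advances.
#'
#' @param state A [glicko_state()] tibble.
#' @param winner,loser Animal ids of the initiator and recipient.
#' @param params A [glicko_params()].
#' @return The updated state tibble.
#' @export
#' @examples
#' st <- glicko_state(c("m1", "m2"))
#' glicko_update(st, "m1", "m2") # m1 to about +162.2, RD about 290.2
glicko_update <- function(state, winner, loser, params = glicko_params()) {
  if (winner == loser) stop("an animal cannot interact with itself")
  wi <- match(winner, state$animal)
  li <- match(loser, state$animal)
  if (is.na(wi) || is.na(li)) stop("unknown animal in interaction")
  q <- params$q

  # pre-period inflation for the two participants
  for (k in c(wi, li)) {
    state$deviation[k] <- min(
      sqrt(state$deviation[k]^2 + params$c^2 * state$idle[k]),
      params$deviation_cap
    )
  }

  one <- function(i, j, s) {
    gj <- g_rd(state$deviation[j], q)
    E <- 1 / (1 + 10^(-gj * (state$rating[i] - state$rating[j]) / 400))
    d2 <- 1 / (q^2 * gj^2 * E * (1 - E))
    denom <- 1 / state$deviation[i]^2 + 1 / d2
    c(rating = state$rating[i] + q / denom * gj * (s - E),
      deviation = sqrt(1 / denom))
  }
  w_new <- one(wi, li, 1)
  l_new <- one(li, wi, 0)
  state$rating[wi] <- w_new[["rating"]]
  state$deviation[wi] <- w_new[["deviation"]]
  state$rating[li] <- l_new[["rating"]]
  state$deviation[li] <- l_new[["deviation"]]
  state$idle <- state$idle + 1
  state$idle[c(wi, li)] <- 1
  state
}

#' Rating history over a sequence of agonistic interactions
#'
#' Replays an ordered sequence of directed attacks (initiator = winner)
#' through [glicko_update()], recalculating ratings after every
#' interaction. Each interaction is its own rating period for its
#' participants; animals not involved keep their ratings but accrue
#' inactivity that inflates their deviation at their next appearance.
#'
#' @param interactions A data frame with columns `winner` and `loser`, in
#'   scoring-time order.
#' @param animals Character vector of all animals in the group.
#' @param params A [glicko_params()].
#' @return An object of class `glicko_history`: list with `ratings` and
#'   `deviations` (matrices, one row per interaction, one column per
#'   animal; row k holds the post-update state after interaction k),
#'   `winner`, `loser`, `animals`, `final` (tibble `animal`, `rating`,
#'   `deviation`, `rank`), `params`. Final ranks break rating ties by
#'   lower deviation, then animal id; exact ties are reported in the
#'   `tied` attribute of `final`.
#' @export
rate_history <- function(interactions, animals, params = glicko_params()) {
  interactions <- tibble::as_tibble(interactions)
  stopifnot(all(c("winner", "loser") %in% names(interactions)))
  if (!all(c(interactions$winner, interactions$loser) %in% animals)) {
    stop("interaction involves an animal not in `animals`")
  }
  n <- nrow(interactions)
  state <- glicko_state(animals, params)
  ratings <- matrix(NA_real_, n, length(animals),
                    dimnames = list(NULL, animals))
  deviations <- ratings
  for (k in seq_len(n)) {
    state <- glicko_update(state, interactions$winner[k],
                           interactions$loser[k], params)
    ratings[k, ] <- state$rating
    deviations[k, ] <- state$deviation
  }
  ord <- order(-state$rating, state$deviation, state$animal)
  final <- state[ord, c("animal", "rating", "deviation")]
  final$rank <- seq_len(nrow(final))
  tied <- final$animal[duplicated(final$rating) |
                         duplicated(final$rating, fromLast = TRUE)]
  attr(final, "tied") <- tied
  structure(
    list(ratings = ratings, deviations = deviations,
         winner = interactions$winner, loser = interactions$loser,
         animals = animals, final = final, params = params),
    class = "glicko_history"
  )
}

#' @export
print.glicko_history <- function(x, ...) {
  cat(sprintf("Glicko history: %d interactions, %d animals\n",
              nrow(x$ratings), length(x$animals)))
  print(x$final, ...)
  invisible(x)
}

#' Normalize a rating history to the group's maximum absolute rating
#'
#' Divides every rating in the history by the maximum absolute rating
#' attained anywhere in the group's history, mapping trajectories into
#' [-1, 1] for cross-group display. A history that never leaves zero is
#' returned unchanged with an `all_zero` flag.
#'
#' @param history A `glicko_history`.
#' @return The history with `ratings` rescaled; attribute `scale` holds
#'   the divisor and attribute `all_zero` the degenerate-input flag.
#' @export
normalize_history <- function(history) {
  stopifnot(inherits(history, "glicko_history"))
  if (nrow(history$ratings) == 0) stop("empty history")
  m <- max(abs(history$ratings))
  if (m == 0) {
    attr(history, "all_zero") <- TRUE
    attr(history, "scale") <- 1
    return(history)
  }
  history$ratings <- history$ratings / m
  history$final$rating <- history$final$rating / m
  attr(history, "all_zero") <- FALSE
  attr(history, "scale") <- m
  history
}

#' Plot rating trajectories
#'
#' @param history A `glicko_history` (optionally normalized).
#' @return A ggplot object; the final dominant's trajectory is drawn on top.
#' @export
plot_rating_history <- function(history) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(interaction = seq_len(nrow(history$ratings)),
                            history$ratings)),
    -"interaction", names_to = "animal", values_to = "rating"
  )
  dom <- history$final$animal[1]
  ggplot2::ggplot(df, ggplot2::aes(.data$interaction, .data$rating,
                                   color = .data$animal)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_line(
      data = df[df$animal == dom, ], color = "black", linewidth = 0.7
    ) +
    ggplot2::labs(x = "agonistic interaction", y = "Glicko rating") +
    ggplot2::theme_minimal()
}
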