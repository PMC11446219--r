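#' Emergence of dominance
#'
#' The number of agonistic interactions after which the finally dominant
#' animal reached the top Glicko rating and kept it until the end of the
#' observation period. Concretely: find the earliest step from which the
#' dominant holds the strictly highest rating at every subsequent step,
#' then count interactions up to and including that step. With
#' `basis = "engaged"` (default) only interactions the dominant itself took
#' part in are counted; `basis = "all"` counts every scored interaction.
#'
#' @param history A `glicko_history`.
#' @param basis `"engaged"` or `"all"`.
#' @return Integer emergence count.
#' @export
emergence_count <- function(history, basis = c("engaged", "all")) {
  basis <- match.arg(basis)
  n <- nrow(history$ratings)
  if (n == 0) stop("empty history")
  dom <- history$final$animal[1]
  engaged <- history$winner == dom | history$loser == dom
  if (!any(engaged)) stop("the dominant animal engaged in no interactions")
  dom_col <- match(dom, colnames(history$ratings))
  others <- history$ratings[, -dom_col, drop = FALSE]
  on_top <- history$ratings[, dom_col] > apply(others, 1, max)
  # earliest step from which the dominant stays strictly on top to the end
  stays <- rev(cumprod(rev(on_top))) > 0
  if (!stays[n]) stop("the final top rating is tied; emergence undefined")
  first <- which(stays)[1]
  if (basis == "engaged") sum(engaged[seq_len(first)]) else first
}

#' Summarize emergence counts across groups
#'
#' Median, arithmetic mean and population standard deviation (divisor n) of
#' per-group emergence counts.
#'
#' @param counts Numeric vector, one emergence count per group.
#' @return A tibble with `n`, `median`, `mean`, `sd` (population).
#' @export
#' @examples
#' emergence_summary(c(16, 60, 61, 171, 121)) # median 61, mean 85.8, sd 54.13
emergence_summary <- function(counts) {
  if (length(counts) == 0) stop("no emergence counts supplied")
  n <- length(counts)
  tibble::tibble(
    n = n,
    median = stats::median(counts),
    mean = mean(counts),
    sd = sqrt(sum((counts - mean(counts))^2) / n)
  )
}

#' Emergence normalized by the group's interaction total
#'
#' Groups differ widely in how many agonistic interactions they produce; to
#' compare emergence across groups, the count at emergence is divided by
#' the group's overall interaction count.
#'
#' @param count Emergence count.
#' @param total_interactions Total agonistic interactions in the group.
#' @return Fraction in (0, 1].
#' @export
normalized_emergence <- function(count, total_interactions) {
  if (any(total_interactions <= 0)) stop("total_interactions must be positive")
  count / total_interactions
}

#' Despotism power ratio
#'
#' How unequally power is distributed within a group: the rating gap the
#' dominant imposes on the second-ranked animal, relative to the gap down
#' to the lowest-ranked animal,
#' `(r_dominant - r_second) / (r_dominant - r_lowest)`. A dominant whose
#' margin over its first subordinate exceeds one third of its total margin
#' (ratio > 0.33) is labeled despotic: it projects similar amounts of
#' power toward every other animal.
#'
#' @param final_ratings Numeric vector of final ratings (>= 3 animals).
#' @param threshold Despotism threshold (default 0.33).
#' @return A list with `ratio`, `despotic` and `flag` (`"ok"`, or
#'   `"undefined"` when all ratings are equal).
#' @export
#' @examples
#' despotism_ratio(c(100, 0, -50, -100)) # 0.5, despotic
despotism_ratio <- function(final_ratings, threshold = 0.33) {
  if (length(final_ratings) < 3) stop("need at least 3 animals")
  s <- sort(final_ratings, decreasing = TRUE)
  if (s[1] == s[length(s)]) {
    return(list(ratio = NA_real_, despotic = NA, flag = "undefined"))
  }
  ratio <- (s[1] - s[2]) / (s[1] - s[length(s)])
  list(ratio = ratio, despotic = ratio > threshold, flag = "ok")
}

#' Dominance summary for one group
#'
#' Bundles the dominance statistics derived from a rating history: final
#' ranking, the dominant's identity, emergence (both counting bases and
#' the normalized fraction) and the despotism ratio.
#'
#' @param history A `glicko_history`.
#' @param threshold Despotism threshold passed to [despotism_ratio()].
#' @return A list of class `dominance_summary`.
#' @export
dominance_summary <- function(history, threshold = 0.33) {
  total <- nrow(history$ratings)
  emer <- emergence_count(history, "engaged")
  desp <- despotism_ratio(history$final$rating, threshold)
  structure(
    list(
      final = history$final,
      dominant = history$final$animal[1],
      total_interactions = total,
      emergence_engaged = emer,
      emergence_all = emergence_count(history, "all"),
      normalized_emergence = normalized_emergence(
        emergence_count(history, "all"), total
      ),
      despotism = desp
    ),
    class = "dominance_summary"
  )
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf(
    "Dominant: %s after %d engaged interactions (%d scored; normalized %.3f)\n",
    x$dominant, x$emergence_engaged, x$emergence_all, x$normalized_emergence
  ))
  cat(sprintf("Despotism ratio: %.3f (%s)\n", x$despotism$ratio,
              if (isTRUE(x$despotism$despotic)) "despotic" else "not despotic"))
  print(x$final, ...)
  invisible(x)
}
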