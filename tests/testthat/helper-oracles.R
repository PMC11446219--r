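# Independent oracles used across tests. Deliberately written in a
# different style from the package code paths they check.

# Sequential Glicko replay on plain named vectors: inactivity time for an
# animal at interaction m is m minus the index of its last update.
glicko_oracle <- function(winners, losers, animals,
                          r0 = 0, rd0 = 350, cval = 1, cap = 350) {
  q <- log(10) / 400
  gf <- function(x) 1 / sqrt(1 + 3 * (q * x / pi)^2)
  r <- stats::setNames(rep(r0, length(animals)), animals)
  rd <- stats::setNames(rep(rd0, length(animals)), animals)
  last <- stats::setNames(rep(0, length(animals)), animals)
  R <- matrix(NA_real_, length(winners), length(animals),
              dimnames = list(NULL, animals))
  D <- R
  for (m in seq_along(winners)) {
    w <- winners[m]
    l <- losers[m]
    rd[w] <- min(sqrt(rd[w]^2 + cval^2 * (m - last[w])), cap)
    rd[l] <- min(sqrt(rd[l]^2 + cval^2 * (m - last[l])), cap)
    ew <- 1 / (1 + 10^(-(r[w] - r[l]) * gf(rd[l]) / 400))
    el <- 1 / (1 + 10^(-(r[l] - r[w]) * gf(rd[w]) / 400))
    d2w <- 1 / (q^2 * gf(rd[l])^2 * ew * (1 - ew))
    d2l <- 1 / (q^2 * gf(rd[w])^2 * el * (1 - el))
    rw <- r[w] + q / (1 / rd[w]^2 + 1 / d2w) * gf(rd[l]) * (1 - ew)
    rl <- r[l] + q / (1 / rd[l]^2 + 1 / d2l) * gf(rd[w]) * (0 - el)
    rd[w] <- sqrt(1 / (1 / rd[w]^2 + 1 / d2w))
    rd[l] <- sqrt(1 / (1 / rd[l]^2 + 1 / d2l))
    r[w] <- rw
    r[l] <- rl
    last[w] <- m
    last[l] <- m
    R[m, ] <- r
    D[m, ] <- rd
  }
  list(ratings = R, deviations = D, r = r, rd = rd)
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled observations to the first group.
ranksum_enum <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  mu <- n1 * length(y) / 2
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Minimal event-row factory for hand-built fixtures.
make_events <- function(..., schedule = phase_schedule()) {
  rows <- list(...)
  tibble::tibble(
    group_id = "g1",
    actor = vapply(rows, `[[`, "", 1),
    target = vapply(rows, function(r) {
      if (length(r) >= 5 && nzchar(r[[5]])) r[[5]] else NA_character_
    }, ""),
    behavior = vapply(rows, `[[`, "", 2),
    start = schedule$start + as.numeric(vapply(rows, `[[`, "", 3)) * 60,
    duration_s = 5,
    location = vapply(rows, `[[`, "", 4)
  )
}

default_sched <- phase_schedule()
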