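test_that("a single symmetric update matches the closed-form evaluation", {
  st <- glicko_state(c("m1", "m2", "m3", "m4"))
  up <- glicko_update(st, "m1", "m2")
  # frozen from an independent evaluation of the update formulas at
  # r = 0, RD = 350 for both participants
  expect_equal(up$rating[up$animal == "m1"], 162.212, tolerance = 1e-4)
  expect_equal(up$rating[up$animal == "m2"], -162.212, tolerance = 1e-4)
  expect_equal(up$deviation[up$animal == "m1"], 290.2305, tolerance = 1e-4)
  # bystanders untouched
  expect_equal(up$rating[up$animal %in% c("m3", "m4")], c(0, 0))
  expect_equal(up$deviation[up$animal %in% c("m3", "m4")], c(350, 350))
  expect_error(glicko_update(st, "m1", "m1"), "itself")
  expect_error(glicko_update(st, "m1", "m9"), "unknown")
})

test_that("equal-state updates are exactly antisymmetric", {
  st <- glicko_state(c("a", "b"))
  up <- glicko_update(st, "a", "b")
  expect_equal(up$rating[1], -up$rating[2])
  expect_equal(up$deviation[1], up$deviation[2])
})

test_that("a foregone win moves the leader's rating almost nowhere", {
  st <- glicko_state(c("a", "b"))
  st$rating <- c(2000, -2000)
  st$deviation <- c(50, 50)
  up <- glicko_update(st, "a", "b")
  delta <- up$rating[1] - 2000
  expect_gt(delta, 0)
  expect_lt(delta, 0.5)
})

test_that("wins never lower and losses never raise a rating; RDs shrink", {
  set.seed(14)
  for (i in 1:25) {
    st <- glicko_state(c("a", "b", "c"))
    st$rating <- rnorm(3, 0, 300)
    st$deviation <- runif(3, 30, 350)
    st$idle <- sample(1:20, 3, replace = TRUE)
    pre <- st
    up <- glicko_update(st, "a", "b")
    expect_gt(up$rating[1], pre$rating[1])
    expect_lt(up$rating[2], pre$rating[2])
    # deviation shrinks relative to its inflated (pre-observation) value
    # and never exceeds the cap
    expect_true(all(up$deviation <= 350))
    infl <- pmin(sqrt(pre$deviation^2 + pre$idle), 350)
    expect_lt(up$deviation[1], infl[1] + 1e-12)
    expect_lt(up$deviation[2], infl[2] + 1e-12)
    # the lower-RD participant moves less
    d <- abs(up$rating - pre$rating)
    if (pre$deviation[1] < pre$deviation[2]) {
      expect_lt(d[1], d[2])
    } else if (pre$deviation[2] < pre$deviation[1]) {
      expect_lt(d[2], d[1])
    }
  }
})

test_that("histories replay an independent sequential oracle to 1e-9", {
  animals <- paste0("m", 1:4)
  ints <- simulate_interactions(c(8, 4, 2, 1), 1000, seed = 5)
  h <- rate_history(ints, animals)
  o <- glicko_oracle(ints$winner, ints$loser, animals)
  rel <- abs(h$ratings - o$ratings) / pmax(abs(o$ratings), 1)
  expect_lt(max(rel), 1e-9)
  expect_lt(max(abs(h$deviations - o$deviations)), 1e-9)
})

test_that("an unbeaten animal holds the top rating from its first win", {
  ints <- tibble::tibble(
    winner = rep("m1", 10),
    loser = rep(c("m2", "m3", "m4"), length.out = 10)
  )
  h <- rate_history(ints, paste0("m", 1:4))
  top <- apply(h$ratings, 1, function(r) names(which.max(r)))
  expect_true(all(top == "m1"))
  expect_equal(emergence_count(h), 1L)
  expect_equal(h$final$animal[1], "m1")
})

test_that("an empty interaction list leaves ratings flat at the start value", {
  h <- rate_history(tibble::tibble(winner = character(0), loser = character(0)),
                    c("a", "b"))
  expect_equal(nrow(h$ratings), 0)
  expect_true(all(h$final$rating == 0))
  expect_error(rate_history(tibble::tibble(winner = "x", loser = "a"),
                            c("a", "b")), "not in")
})

test_that("history normalization maps into [-1, 1] with an attained bound", {
  ints <- simulate_interactions(c(5, 3, 2, 1), 120, seed = 9)
  h <- normalize_history(rate_history(ints, paste0("m", 1:4)))
  expect_lte(max(abs(h$ratings)), 1)
  expect_equal(max(abs(h$ratings)), 1)
  expect_false(attr(h, "all_zero"))
  # oracle: the scale is the max |rating| of the raw history
  raw <- rate_history(ints, paste0("m", 1:4))
  expect_equal(attr(h, "scale"), max(abs(raw$ratings)))
  expect_equal(h$ratings * attr(h, "scale"), raw$ratings)

  empty <- rate_history(tibble::tibble(winner = character(0),
                                       loser = character(0)), c("a", "b"))
  expect_error(normalize_history(empty), "empty")
})

test_that("emergence counts interactions until the lead becomes permanent", {
  # scripted lead change: m2 wins the first 3 bouts, then m1 wins 7 straight
  ints <- tibble::tibble(
    winner = c("m2", "m2", "m2", rep("m1", 7)),
    loser = c("m1", "m3", "m4", c("m2", "m2", "m3", "m4", "m2", "m3", "m2"))
  )
  h <- rate_history(ints, paste0("m", 1:4))
  expect_equal(h$final$animal[1], "m1")
  # brute-force scan oracle over the recorded trajectory
  dom_top <- h$ratings[, "m1"] > apply(h$ratings[, -1], 1, max)
  first_stable <- min(which(rev(cumsum(rev(!dom_top))) == 0))
  engaged <- h$winner == "m1" | h$loser == "m1"
  expect_equal(emergence_count(h, "engaged"), sum(engaged[1:first_stable]))
  expect_equal(emergence_count(h, "all"), first_stable)

  # a dominant that only seizes the lead on its last bout: alternating wins
  # make every earlier lead transient, so emergence equals the full count
  late <- tibble::tibble(
    winner = c("m2", "m1", "m2", "m1", "m2", "m1"),
    loser = c("m1", "m2", "m1", "m2", "m1", "m2")
  )
  hl <- rate_history(late, c("m1", "m2", "m3"))
  expect_equal(hl$final$animal[1], "m1")
  lead <- hl$ratings[, "m1"] > apply(hl$ratings[, -1, drop = FALSE], 1, max)
  expect_false(all(lead[-nrow(hl$ratings)])) # earlier leads were transient
  n_engaged <- sum(late$winner == "m1" | late$loser == "m1")
  expect_equal(emergence_count(hl, "engaged"), n_engaged)
})

test_that("emergence summaries reproduce the population-SD convention", {
  wt <- emergence_summary(c(16, 60, 61, 171, 121))
  expect_equal(wt$median, 61)
  expect_equal(wt$mean, 85.8)
  expect_equal(wt$sd, 54.13, tolerance = 5e-4)
  ko <- emergence_summary(c(125, 243, 158, 382, 438))
  expect_equal(ko$median, 243)
  expect_equal(ko$mean, 269.2)
  expect_equal(ko$sd, 122.53, tolerance = 5e-4)
  flat <- emergence_summary(c(5, 5, 5))
  expect_equal(flat$median, 5)
  expect_equal(flat$sd, 0)
  expect_error(emergence_summary(numeric(0)), "no emergence")
})

test_that("normalized emergence divides by the group's interaction total", {
  expect_equal(normalized_emergence(61, 244), 0.25)
  expect_equal(normalized_emergence(57, 57), 1)
  expect_error(normalized_emergence(5, 0), "positive")
})

test_that("despotism ratio flags power concentration above one third", {
  tied_second <- despotism_ratio(c(100, 100, 50, 0))
  expect_equal(tied_second$ratio, 0)
  expect_false(tied_second$despotic)

  mid <- despotism_ratio(c(100, 0, -50, -100))
  expect_equal(mid$ratio, 0.5)
  expect_true(mid$despotic)

  lone <- despotism_ratio(c(100, 0, 0, 0))
  expect_equal(lone$ratio, 1)
  expect_true(lone$despotic)

  expect_error(despotism_ratio(c(1, 2)), "at least 3")
  alleq <- despotism_ratio(c(7, 7, 7, 7))
  expect_equal(alleq$flag, "undefined")
  expect_true(is.na(alleq$ratio))
})
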