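test_that("behavior tallies are exhaustive and zero-filled", {
  empty <- behavior_totals(make_events()[0, ], default_sched,
                           animals = c("m1", "m2"))
  expect_equal(nrow(empty), 2 * 2 * 18)
  expect_true(all(empty$n == 0))

  ev <- make_events(
    c("m1", "struggle_at_feeder", "5", "feeder", "m2"),
    c("m1", "struggle_at_feeder", "15", "feeder", "m3"),
    c("m1", "struggle_at_feeder", "25", "feeder", "m2")
  )
  tt <- behavior_totals(ev, default_sched, animals = paste0("m", 1:4))
  expect_equal(
    tt$n[tt$animal == "m1" & tt$phase == "dark" &
           tt$behavior == "struggle_at_feeder"], 3L
  )
  expect_equal(sum(tt$n), 3L)
})

test_that("tallies agree with an independent group-and-count oracle", {
  set.seed(21)
  g <- simulate_group("WT", seed = 21, group_id = "t")
  tt <- behavior_totals(g$events, g$schedule, animals = g$animals)
  ph <- assign_phase(g$events$start, g$schedule)
  oracle <- table(g$events$actor, ph$phase, g$events$behavior)
  for (i in sample(nrow(tt), 50)) {
    o <- tryCatch(
      oracle[tt$animal[i], tt$phase[i], tt$behavior[i]],
      error = function(e) 0L
    )
    expect_equal(tt$n[i], as.integer(o))
  }
  # conservation: per-day tallies sum to the pooled tallies
  td <- behavior_totals(g$events, g$schedule, per_day = TRUE,
                        animals = g$animals)
  pooled <- dplyr::count(td, animal, phase, behavior, wt = n, name = "n")
  merged <- dplyr::left_join(tt, pooled, by = c("animal", "phase", "behavior"),
                             suffix = c("", ".day"))
  expect_equal(merged$n, merged$n.day)
})

test_that("attack latency is the first qualifying event on the scored clock", {
  ev <- make_events(
    c("m1", "sniffing", "2", "center", "m2"),
    c("m1", "chasing", "12", "center", "m2"),
    c("m1", "struggle", "30", "wall", "m3"),
    c("m2", "grooming", "40", "wall")
  )
  lat <- attack_latency(ev, default_sched, animals = c("m1", "m2"))
  expect_equal(lat$latency_min[lat$animal == "m1"], 12)
  expect_false(lat$censored[lat$animal == "m1"])
  # m2 never attacks: censored at the total scored observation time
  expect_true(lat$censored[lat$animal == "m2"])
  expect_equal(lat$latency_min[lat$animal == "m2"], 2400)
  expect_equal(attr(lat, "group_min"), 12)

  # order invariance: shuffling rows cannot change a min-over-set
  set.seed(3)
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(attack_latency(shuf, default_sched, animals = c("m1", "m2")),
               lat, ignore_attr = TRUE)
})

test_that("adding an earlier attack can only shorten the latency", {
  base <- make_events(c("m1", "chasing", "50", "center", "m2"))
  lat0 <- attack_latency(base, default_sched)$latency_min
  earlier <- rbind(base, make_events(c("m1", "struggle", "20", "wall", "m3")))
  expect_lte(attack_latency(earlier, default_sched)$latency_min, lat0)
})

test_that("fight/threat ratio handles degenerate denominators with flags", {
  rows <- c(
    # m1: 10 fights, 5 threats
    lapply(1:6, function(i) c("m1", "struggle", as.character(i), "wall", "m2")),
    lapply(1:4, function(i) c("m1", "struggle_at_feeder", as.character(10 + i), "feeder", "m2")),
    lapply(1:5, function(i) c("m1", "chasing", as.character(20 + i), "center", "m2")),
    # m2: 0 fights, 7 threats
    lapply(1:7, function(i) c("m2", "following", as.character(30 + i), "center", "m1")),
    # m3: 3 fights, 0 threats
    lapply(1:3, function(i) c("m3", "struggle", as.character(40 + i), "wall", "m1"))
  )
  ev <- do.call(make_events, rows)
  ftr <- fight_threat_ratio(ev, animals = c("m1", "m2", "m3", "m4"))
  expect_equal(ftr$ratio[ftr$animal == "m1"], 2)
  expect_equal(ftr$flag[ftr$animal == "m1"], "ok")
  expect_equal(ftr$ratio[ftr$animal == "m2"], 0)
  expect_true(is.na(ftr$ratio[ftr$animal == "m3"]))
  expect_equal(ftr$flag[ftr$animal == "m3"], "infinite")
  expect_equal(ftr$flag[ftr$animal == "m4"], "undefined")
})

test_that("aggression profiles assemble latency, counts, duration, hotspot", {
  ev <- make_events(
    c("m1", "struggle_at_feeder", "5", "feeder", "m2"),
    c("m1", "struggle_at_feeder", "15", "feeder", "m3"),
    c("m1", "struggle", "25", "feeder", "m2"),
    c("m2", "struggle", "35", "wall", "m1")
  )
  ev$duration_s <- c(3, 5, 10, 4.2)
  prof <- aggression_profile(ev, default_sched, animals = paste0("m", 1:4))
  m1 <- prof[prof$animal == "m1", ]
  expect_equal(m1$total_attacks, 3L)
  expect_equal(m1$mean_attack_duration_s, 6)
  expect_equal(m1$hotspot, "feeder")
  expect_equal(m1$latency_min, 5)
  m2 <- prof[prof$animal == "m2", ]
  expect_equal(m2$mean_attack_duration_s, 4.2)
  expect_true(prof$censored[prof$animal == "m4"])
})

test_that("exact rank-sum p-values match full enumeration", {
  same <- genotype_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1)

  sep <- genotype_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p, 0.1)
  expect_equal(sep$p, ranksum_enum(c(1, 2, 3), c(10, 11, 12)))

  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- round(rnorm(n1, sd = 2), if (i %% 2) 3 else 0) # ties on even i
    y <- round(rnorm(n2, sd = 2), if (i %% 2) 3 else 0)
    expect_equal(genotype_compare(x, y)$p, ranksum_enum(x, y),
                 tolerance = 1e-12,
                 info = paste("case", i))
  }

  const <- genotype_compare(c(2, 2), c(2, 2, 2))
  expect_equal(const$flag, "degenerate")
})

test_that("behavior correlations are symmetric with unit diagonal", {
  set.seed(8)
  m <- matrix(rpois(8 * 6, 20), 8, 6,
              dimnames = list(NULL, paste0("b", 1:6)))
  m[, 2] <- m[, 1] + rpois(8, 2) # correlated pair
  m[, 6] <- 7                    # constant column
  bc <- behavior_correlations(as.data.frame(m))
  expect_equal(diag(bc$rho), rep(1, 6), ignore_attr = TRUE)
  expect_equal(bc$rho, t(bc$rho))
  expect_equal(bc$q, t(bc$q))
  expect_true(all(bc$q >= bc$p - 1e-12, na.rm = TRUE))
  expect_equal(bc$flag, "b6")
  expect_true(all(is.na(bc$rho["b6", -6])))
  expect_gt(bc$rho["b1", "b2"], 0.5)
})
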