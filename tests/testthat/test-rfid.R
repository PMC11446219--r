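rfid_stream <- function(readers, minutes, animal = "m1",
                        schedule = default_sched) {
  tibble::tibble(
    time = schedule$start + minutes * 60,
    animal = animal, reader = as.integer(readers), duration_ms = 1000
  )
}

test_that("repeated detections on one reader travel zero distance", {
  g <- reader_grid()
  rf <- rfid_stream(rep(7L, 50), seq(0, 49))
  d <- distance_per_hour(rf, g, default_sched)
  expect_true(all(d$distance_m == 0))
})

test_that("alternations between adjacent readers sum pitch per crossing", {
  g <- reader_grid(pitch = 0.08)
  # readers 1 and 2 are horizontally adjacent; 10 transitions in hour 1
  rf <- rfid_stream(rep(c(1L, 2L), 6), seq(0, 55, by = 5))
  d <- distance_per_hour(rf, g, default_sched)
  h1 <- d[d$day == 1 & d$phase == "dark" & d$phase_hour == 1, ]
  expect_equal(h1$distance_m[h1$animal == "m1"], 11 * 0.08)
})

test_that("hourly distances match a brute-force pairwise oracle", {
  g <- reader_grid()
  set.seed(42)
  rf <- rfid_stream(sample(1:24, 500, replace = TRUE),
                    sort(runif(500, 0, 600)))
  d <- distance_per_hour(rf, g, default_sched)
  # oracle: re-sum pairwise distances over the sorted stream
  xy <- cbind(g$x, g$y)[rf$reader, ]
  steps <- sqrt(rowSums((xy[-1, ] - xy[-500, ])^2))
  expect_equal(sum(d$distance_m), sum(steps), tolerance = 1e-12)
  # transitions credit the hour of the later event
  hr <- floor(as.numeric(difftime(rf$time[-1], default_sched$start,
                                  units = "hours")))
  oracle_h1 <- sum(steps[hr == 0])
  expect_equal(d$distance_m[d$day == 1 & d$phase == "dark" &
                              d$phase_hour == 1], oracle_h1,
               tolerance = 1e-12)
})

test_that("silent hours are zero-distance but flagged no-detection", {
  g <- reader_grid()
  rf <- rfid_stream(c(1L, 2L), c(0, 30))
  d <- distance_per_hour(rf, g, default_sched)
  expect_equal(nrow(d), 120) # full scaffold for one animal
  quiet <- d[!(d$day == 1 & d$phase == "dark" & d$phase_hour == 1), ]
  expect_true(all(quiet$no_detection))
  expect_true(all(quiet$distance_m == 0))
  expect_false(d$no_detection[d$day == 1 & d$phase == "dark" &
                                d$phase_hour == 1])
  expect_error(distance_per_hour(rfid_stream(99L, 0), g, default_sched),
               "unknown reader")
})

test_that("place preference normalizes activations to 100 percent", {
  g <- reader_grid()
  one <- place_preference(rfid_stream(rep(7L, 10), 1:10), g)
  expect_equal(one$percent[one$reader == 7], 100)
  expect_equal(sum(one$percent), 100)

  unif <- place_preference(rfid_stream(rep(1:24, 5), seq_len(120)), g)
  expect_equal(unif$percent, rep(100 / 24, 24))

  biased <- place_preference(
    rfid_stream(rep(c(3L, 3L, 3L, 9L), 25), seq_len(100)), g
  )
  expect_equal(biased$percent[biased$reader == 3], 75)
  expect_equal(biased$percent[biased$reader == 9], 25)
})

test_that("empty selections raise an error instead of a NaN map", {
  g <- reader_grid()
  rf <- rfid_stream(1L, 1) # a single dark-phase event
  expect_error(place_preference(rf, g, default_sched, phase = "light"),
               "no RFID events")
})

test_that("duration weighting changes the map only when durations differ", {
  g <- reader_grid()
  rf <- rfid_stream(c(1L, 2L), c(0, 10))
  rf$duration_ms <- c(3000, 1000)
  counts <- place_preference(rf, g)
  dur <- place_preference(rf, g, weight = "duration")
  expect_equal(counts$percent[1:2], c(50, 50))
  expect_equal(dur$percent[1:2], c(75, 25))
})

test_that("preference maps sum to 100 under random streams", {
  g <- reader_grid()
  set.seed(99)
  for (i in 1:10) {
    rf <- rfid_stream(sample(1:24, 200, replace = TRUE),
                      sort(runif(200, 0, 7000)))
    expect_equal(sum(place_preference(rf, g)$percent), 100, tolerance = 1e-9)
  }
})

test_that("zone contrasts difference maps and re-aggregate by area", {
  g <- reader_grid()
  set.seed(7)
  map_a <- place_preference(
    rfid_stream(sample(1:24, 300, replace = TRUE, prob = c(rep(2, 12), rep(1, 12))),
                sort(runif(300, 0, 700))), g
  )
  map_b <- place_preference(
    rfid_stream(sample(1:24, 300, replace = TRUE), sort(runif(300, 0, 700))), g
  )
  self <- zone_contrast(map_a, map_a)
  expect_true(all(self$delta$delta_percent == 0))

  zc <- zone_contrast(map_a, map_b)
  expect_equal(zc$delta$delta_percent, map_a$percent - map_b$percent)
  # re-aggregation oracle: sum member readers by hand
  for (ar in c("open", "burrow")) {
    expect_equal(
      zc$area_summary$delta[zc$area_summary$area == ar],
      sum(map_a$percent[g$area == ar]) - sum(map_b$percent[g$area == ar])
    )
  }

  disj_a <- place_preference(rfid_stream(rep(1L, 5), 1:5), g)
  disj_b <- place_preference(rfid_stream(rep(24L, 5), 1:5), g)
  dd <- zone_contrast(disj_a, disj_b)$delta
  expect_equal(dd$delta_percent[dd$reader == 1], 100)
  expect_equal(dd$delta_percent[dd$reader == 24], -100)

  g5 <- reader_grid(pitch = 0.05)
  small <- place_preference(rfid_stream(1L, 1), g5)
  expect_error(zone_contrast(map_a, small), NA) # same zones, compatible
})
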