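# Rule-based anomaly classification: activity features, the 5x5 agreement
# matrix, stay state and the rule cascade.

test_that("weighted global activity interpolates the neighbouring cells", {
  fx <- profile_a_model()
  m <- fx$model
  # forced arithmetic through a crafted AG pair: minutes = 30, dt = 60,
  # AG_cur = 2, AG_prev = 4 -> 3.0
  m2 <- m
  # Monday (10-11] and (9-10]
  m2$AG[2, 11] <- 2; m2$AG[2, 10] <- 4
  t30 <- utc("2024-02-05 10:30:00")
  expect_equal(weighted_global_activity(m2, t30), 3.0)
  # at the very start of an interval the previous cell dominates
  t0 <- utc("2024-02-05 10:00:30")
  expect_equal(weighted_global_activity(m2, t0), 4 * (1 - 0.5 / 60) +
                 2 * 0.5 / 60)
  # near the end the current cell dominates
  t59 <- utc("2024-02-05 10:59:30")
  expect_equal(weighted_global_activity(m2, t59), 2 * (59.5 / 60) +
                 4 * (0.5 / 60))
})

test_that("sampled global activity equals a brute-force trailing count", {
  set.seed(21)
  times <- sort(utc("2024-03-04 00:00:00") + round(runif(300, 0, 6 * 3600)))
  obs <- obs_df(times, sample(c("Kitchen", "Bedroom"), 300, TRUE))
  for (probe in utc("2024-03-04 01:30:00") + c(0, 3600, 7200, 10000)) {
    probe <- as.POSIXct(probe, tz = "UTC")
    manual <- sum(obs$time > probe - 3600 & obs$time <= probe) / 60
    expect_equal(sampled_global_activity(obs, probe), manual)
  }
  # no recent observations: zero
  expect_equal(sampled_global_activity(obs, utc("2024-03-10 00:00:00")), 0)
})

test_that("activity rates quantise into five equal bands of the model maximum", {
  expect_equal(as.character(activity_level(1, 1)), "VeryHigh")
  expect_equal(as.character(activity_level(0, 1)), "VeryLow")
  expect_equal(as.character(activity_level(0.5, 1)), "Medium")
  expect_equal(as.character(activity_level(0.25, 1)), "Low")
  expect_equal(as.character(activity_level(0.65, 1)), "High")
  # degenerate model: everything is VeryLow
  expect_equal(as.character(activity_level(3, 0)), "VeryLow")
})

test_that("level agreement reproduces the published 5x5 matching matrix", {
  lv <- c("VeryHigh", "High", "Medium", "Low", "VeryLow")
  # printed matrix, rows = sampled level, columns = weighted level
  printed <- matrix(c(
    "N", "N", "A", "A", "A",
    "N", "N", "N", "A", "A",
    "A", "N", "N", "N", "A",
    "A", "A", "N", "N", "N",
    "A", "A", "A", "N", "N"), 5, 5, byrow = TRUE,
    dimnames = list(lv, lv))
  for (s in lv) for (w in lv) {
    got <- activity_match(w, s)
    expect_equal(substr(got, 1, 1), printed[s, w],
                 label = paste("pair", s, w, "->", got))
  }
})

test_that("stay state flags a continuous stay reaching the learned longest", {
  fx <- profile_a_model()
  m <- fx$model
  long_bed <- max(m$cs_longest[, "Bedroom"])
  expect_equal(stay_state(0, m, "Bedroom"), "Normal")
  expect_equal(stay_state(long_bed - 1, m, "Bedroom"), "Normal")
  # equality already counts as High ("less than expected" fails)
  expect_equal(stay_state(long_bed, m, "Bedroom"), "High")
  # per-weekday comparison uses that day's own profile
  expect_equal(stay_state(longest_stay(m, "Monday", "Bedroom"), m,
                          "Bedroom", "Monday"), "High")
})

test_that("no anomaly label is ever emitted while the automaton is Normal", {
  fx <- profile_a_model()
  ev <- fx$events
  start <- attr(ev, "start")
  ch <- detect(fx$model, ev, from = start + 4 * 7 * 86400,
               to = start + 5 * 7 * 86400)
  expect_true(all(ch$label[ch$state == "Normal"] == "Normal"))
})

test_that("the rule cascade identifies the four anomaly classes", {
  fx <- profile_a_model()
  m <- fx$model
  day <- utc("2024-02-07 00:00:00")   # a Wednesday after the window

  # extended bedroom stay reaching into expected away-hours: OverSleeping
  obs <- obs_df(day + c(0, seq(1800, 12 * 3600, by = 1800)),
                rep("Bedroom", 25))
  ch <- detect(m, obs, from = day + 8 * 3600, to = day + 11 * 3600)
  lab <- ch$label[ch$state == "Abnormal"]
  # unclassified until the stay exceeds the learned longest, then committed
  expect_true(any(lab == "OverSleeping"))
  expect_true(all(lab %in% c("Normal", "OverSleeping")))
  expect_true(all(lab[ch$cs[ch$state == "Abnormal"] >=
                        max(m$cs_longest[, "Bedroom"])] == "OverSleeping"))

  # detected in the kitchen while the model expects sleep: LessSleeping,
  # firing already in the PotentialAbnormal state
  obs <- obs_df(day + c(0, seq(3600, 4 * 3600, by = 300)),
                c("Bedroom", rep("Kitchen", 37)))
  ch <- detect(m, obs, from = day + 3600, to = day + 3 * 3600)
  expect_true(any(ch$label[ch$state == "PotentialAbnormal"] ==
                    "LessSleeping"))
  expect_true(all(ch$label[ch$state != "Normal"] == "LessSleeping"))

  # long silent stay in the store with no sampled activity: Dead, only
  # after full confirmation
  obs <- obs_df(day + c(16 * 3600, 16 * 3600 + 30),
                c("Store", "Store"))
  ch <- detect(m, obs, from = day + 17 * 3600, to = day + 20 * 3600)
  expect_true(any(ch$label == "Dead"))
  expect_true(all(ch$label[ch$state != "Abnormal"] == "Normal"))

  # never coming back from an outing: NotBackHome once the outside stay
  # exceeds the longest learned one
  obs <- obs_df(day + c(8 * 3600), "Outside")
  ch <- detect(m, obs, from = day + 16 * 3600, to = day + 20 * 3600)
  expect_true(any(ch$label == "NotBackHome"))
  expect_true(all(ch$label %in% c("Normal", "NotBackHome")))
})

test_that("the classifier only filters automaton alerts on clean data", {
  fp <- fp_experiment("A", seed = 2, weeks = 8, monitor_weeks = 4)
  expect_lte(fp$fp_weekly[fp$level == "classifier"],
             fp$fp_weekly[fp$level == "automaton"])
})
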