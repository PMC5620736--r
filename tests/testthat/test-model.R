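# Learning: per-cell accumulation, probabilities, activity rates, continuous
# stays, and the sliding-window update.

lay <- default_home_layout()
sunday <- utc("2024-01-07 00:00:00")       # window start used throughout

test_that("stay minutes accumulate per cell and average over window days", {
  # four Mondays with bedroom stays of 60, 60, 30, 30 min in cell (4-5]
  dur <- c(60, 60, 30, 30)
  times <- rooms <- NULL
  for (w in 0:3) {
    d0 <- sunday + (w * 7 + 1) * 86400     # the Monday of week w+1
    times <- c(times, d0 + 4 * 3600, d0 + 4 * 3600 + dur[w + 1] * 60)
    rooms <- c(rooms, "Bedroom", "Bathroom")
  }
  m <- behaviour_model(obs_df(utc(times), rooms), lay,
                       window_start = sunday, window_weeks = 4)
  expect_equal(total_stay_time(m, "Monday", 5, "Bedroom"), 45)
})

test_that("self-transition probability is the dwell share of the interval", {
  # 36 min in the kitchen then 24 min in the living room within one hour
  obs <- obs_df(c("2024-01-08 10:00:00", "2024-01-08 10:36:00",
                  "2024-01-08 11:00:00"),
                c("Kitchen", "Livingroom", "Bedroom"))
  m <- behaviour_model(obs, lay, window_start = sunday, window_weeks = 1)
  expect_equal(self_transition_prob(m, "Monday", 11, "Kitchen"), 0.6)
  expect_equal(self_transition_prob(m, "Monday", 11, "Livingroom"), 0.4)
})

test_that("off-diagonal mass splits proportionally to transition counts", {
  # within one cell: kitchen dwell 24/60, then transitions K->L x3, K->B x1
  # interleaved with instant returns so the counts are 3:1
  base <- utc("2024-01-08 10:00:00")
  times <- base + c(0, 24 * 60,
                    25 * 60, 25 * 60 + 1, 26 * 60, 26 * 60 + 1,
                    27 * 60, 27 * 60 + 1, 28 * 60)
  rooms <- c("Kitchen", "Livingroom",
             "Kitchen", "Livingroom", "Kitchen", "Livingroom",
             "Kitchen", "Bedroom", "Kitchen")
  m <- behaviour_model(obs_df(times, rooms), lay, window_start = sunday,
                       window_weeks = 1)
  pii <- self_transition_prob(m, "Monday", 11, "Kitchen")
  pkl <- transition_prob(m, "Monday", 11, "Kitchen", "Livingroom")
  pkb <- transition_prob(m, "Monday", 11, "Kitchen", "Bedroom")
  expect_equal(pkl, (1 - pii) * 3 / 4)
  expect_equal(pkb, (1 - pii) * 1 / 4)
  # full row sums to one
  expect_equal(pii + pkl + pkb, 1)
})

test_that("activity rates match direct tallies and their identities hold", {
  # A,B,A,B within one cell: 4 observations, 3 inter-room transitions
  obs <- obs_df(utc("2024-01-08 10:05:00") + (0:3) * 600,
                rep(c("Kitchen", "Livingroom"), 2))
  m <- behaviour_model(obs, lay, window_start = sunday, window_weeks = 1)
  expect_equal(global_activity(m, "Monday", 11), 4 / 60)
  expect_equal(inter_room_activity(m, "Monday", 11), 3 / 60)
  expect_equal(intra_room_activity(m, "Monday", 11, "Kitchen"), 2 / 60)
  expect_equal(intra_room_activity(m, "Monday", 11, "Livingroom"), 2 / 60)
})

test_that("model probabilities match a per-second occupancy oracle on random data", {
  set.seed(11)
  n <- 400
  times <- sort(sunday + round(runif(n, 0, 7 * 86400 - 1)))
  rooms <- sample(lay$rooms, n, replace = TRUE)
  obs <- obs_df(times, rooms)
  m <- behaviour_model(obs, lay, window_start = sunday, window_weeks = 1)
  oracle <- occupancy_oracle(obs, lay$rooms, 60)
  checked <- 0
  for (key in names(oracle)) {
    parts <- strsplit(key, " ")[[1]]
    d <- as.integer(parts[1]); k <- as.integer(parts[2]); rm <- parts[3]
    # only fully covered cells follow the pure occupancy fraction
    if (abs(sum(m$TS[d, k, ]) - 60) > 1e-6) next
    expect_equal(self_transition_prob(m, d, k, rm), oracle[[key]],
                 tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("model invariants hold on a simulated stream", {
  m <- profile_a_model()$model
  # every observed row of the transition matrix is stochastic
  for (d in 1:7) for (k in seq_len(m$n_intervals)) {
    P <- coef(m, d, k)
    obsv <- m$observed[d, k, ]
    if (any(obsv))
      expect_true(all(abs(rowSums(P)[obsv] - 1) < 1e-9))
    # unobserved rows are all zero
    if (any(!obsv))
      expect_true(all(P[!obsv, ] == 0))
  }
  # self-transition probabilities sum to one over rooms in covered cells
  dsum <- apply(m$pstay, c(1, 2), sum)
  covered <- apply(m$TS, c(1, 2), sum) > 0
  expect_true(all(abs(dsum[covered] - 1) < 1e-9))
  # per-room activity sums to the global rate; inter-room never exceeds it
  expect_true(all(abs(apply(m$AA, c(1, 2), sum) - m$AG) < 1e-12))
  expect_true(all(m$AE <= m$AG + 1e-12))
  expect_true(all(m$pstay >= 0 & m$pstay <= 1))
  expect_true(all(m$P >= 0 & m$P <= 1))
})

test_that("continuous stays merge consecutive same-room dwells", {
  # stays: bed 30, bed 40, kitchen 10, bed 20 -> bedroom runs 70 and 20
  base <- utc("2024-01-08 02:00:00")
  mins <- cumsum(c(0, 30, 40, 10, 20))
  obs <- obs_df(base + mins * 60,
                c("Bedroom", "Bedroom", "Kitchen", "Bedroom", "Bathroom"))
  m <- behaviour_model(obs, lay, window_start = sunday, window_weeks = 1)
  expect_equal(sort(m$cs_list[[2]]$Bedroom, decreasing = TRUE), c(70, 20))
  expect_equal(longest_stay(m, "Monday", "Bedroom"), 70)
  # a zero-duration stay in another room still breaks the run
  obs2 <- obs_df(base + c(0, 30, 30, 60) * 60,
                 c("Bedroom", "Kitchen", "Bedroom", "Bedroom"))
  m2 <- behaviour_model(obs2, lay, window_start = sunday, window_weeks = 1)
  expect_equal(sort(m2$cs_list[[2]]$Bedroom, decreasing = TRUE), c(30, 30))
})

test_that("sliding-window update equals a from-scratch batch rebuild", {
  ev <- simulate_profile(profile_spec("A", weeks = 6), seed = 5)
  lay6 <- attr(ev, "layout")
  start <- attr(ev, "start")
  m <- behaviour_model(ev, lay6, window_start = start, window_weeks = 4)
  for (w in 1:2) {
    m <- update(m, ev)
    batch <- behaviour_model(ev, lay6,
                             window_start = start + w * 7 * 86400,
                             window_weeks = 4)
    expect_identical(m$pstay, batch$pstay)
    expect_identical(m$P, batch$P)
    expect_identical(m$AG, batch$AG)
    expect_identical(m$cs_longest, batch$cs_longest)
  }
})

test_that("models survive a JSON round-trip", {
  m <- profile_a_model()$model
  f <- tempfile(fileext = ".json")
  model_write(m, f)
  m2 <- model_read(f)
  expect_equal(m2$pstay, m$pstay)
  expect_equal(m2$P, m$P)
  expect_equal(m2$AG, m$AG)
  expect_equal(m2$cs_longest, m$cs_longest)
  expect_equal(m2$max_AG, m$max_AG)
  expect_error(update(m2, m$buffer), "buffer")
})

test_that("expected room is the cell argmax with layout-order tie-break", {
  m <- profile_a_model()$model
  expect_equal(expected_room(m, utc("2024-02-05 04:25:00")), "Bedroom")
  expect_equal(expected_room(m, utc("2024-02-05 12:00:00")), "Outside")
})
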