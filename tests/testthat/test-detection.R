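# Estimator (likelihood, normalisation, smoothing, threshold) and the
# three-state confirmation automaton.

# internal shorthand used by the automaton tests
.automaton_chain <- function(h, dt = 1, n1 = 5, n2 = 10)
  bmsense:::.automaton_run(h, dt, n1, n2)$state


test_that("location likelihood reads the detected room's stay probability", {
  fx <- profile_a_model()
  m <- fx$model
  # Monday 04:25, latest observation in the bedroom: the learned stay
  # probability is near 1 and the likelihood equals it
  nd <- data.frame(time = utc("2024-02-05 04:25:00"), room = "Bedroom")
  l <- predict(m, nd)
  expect_equal(l, self_transition_prob(m, "Monday", 5, "Bedroom"))
  expect_gt(l, 0.9)
  # a room with no dwell in the cell has zero likelihood
  expect_equal(predict(m, data.frame(time = nd$time, room = "Store")), 0)
  # unknown room: zero
  expect_equal(predict(m, data.frame(time = nd$time, room = "Attic")), 0)
})

test_that("normalisation divides by the cell maximum and never decreases", {
  expect_equal(normalise_likelihood(0.3, c(0.6, 0.3, 0.1)), 0.5)
  expect_equal(normalise_likelihood(0.6, c(0.6, 0.3, 0.1)), 1)
  expect_equal(normalise_likelihood(0.2, c(0, 0, 0)), 0)   # unmodelled cell
  set.seed(3)
  for (i in 1:50) {
    p <- runif(6); p <- p / sum(p)
    l <- sample(p, 1)
    expect_gte(normalise_likelihood(l, p), l)   # max <= 1 so it never shrinks
  }
})

test_that("the moving-average filter behaves as an FIR smoother", {
  fx <- profile_a_model()
  m <- fx$model
  # constant input passes through unchanged: a quiet night in the bedroom
  night <- detect(m, fx$events, from = utc("2024-02-05 01:00:00"),
                  to = utc("2024-02-05 03:00:00"), classify = FALSE)
  expect_true(all(abs(night$g[!night$warmup] -
                        night$g[which(!night$warmup)[1]]) < 0.2))
  # direct filter arithmetic on a crafted sample chain: a single zero in a
  # run of ones dips the 10-sample mean to exactly 0.9
  x <- rep(1, 30); x[15] <- 0
  g <- as.numeric(stats::filter(x, rep(0.1, 10), sides = 1))
  expect_equal(min(g, na.rm = TRUE), 0.9)
  # step from 1 to 0 settles only after a full window
  s <- c(rep(1, 15), rep(0, 15))
  gs <- as.numeric(stats::filter(s, rep(0.1, 10), sides = 1))
  expect_equal(gs[16:24], seq(0.9, 0.1, by = -0.1))
  expect_equal(gs[25], 0)
})

test_that("threshold comparison is a strict drop below", {
  fx <- profile_a_model()
  ch <- detect(fx$model, fx$events, from = utc("2024-02-05 01:00:00"),
               to = utc("2024-02-05 02:00:00"), threshold = 1,
               classify = FALSE)
  # g == 1 at threshold 1 is NOT abnormal (strict <)
  expect_true(all(ch$h[ch$g >= 1] == 0))
  # g = 0 is abnormal for any positive threshold
  expect_true(all(ch$h[ch$g == 0 & !ch$warmup] == 1))
})

test_that("abnormal sample count is monotone in the threshold", {
  fx <- profile_a_model()
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.9, 1), function(th)
    sum(detect(fx$model, fx$events, from = utc("2024-02-05 00:00:00"),
               to = utc("2024-02-06 00:00:00"), threshold = th,
               classify = FALSE)$h), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)              # g >= 0 can never drop below 0
})

test_that("detection emits exactly one record per sampling period", {
  fx <- profile_a_model()
  ch <- detect(fx$model, fx$events, from = utc("2024-02-05 06:00:00"),
               to = utc("2024-02-05 09:00:00"), classify = FALSE)
  expect_equal(nrow(ch), 180)
  expect_equal(unique(diff(as.numeric(ch$time))), 60)
})

test_that("the automaton confirms sustained abnormality through its timeouts", {
  # h = 0 forever: stays Normal
  st <- .automaton_chain(rep(0, 20))
  expect_true(all(st == "Normal"))
  # 6 consecutive abnormal minutes (N1 = 5) reach PotentialAbnormal
  st <- .automaton_chain(c(rep(1, 6), rep(0, 10)))
  expect_equal(as.character(st[6]), "PotentialAbnormal")
  # 10 abnormal minutes (N2 = 10) confirm Abnormal
  st <- .automaton_chain(rep(1, 12))
  expect_equal(as.character(st[10]), "Abnormal")
  expect_true(all(st[1:5] == "Normal"))
})

test_that("short abnormal glitches never leave the Normal state", {
  set.seed(9)
  for (i in 1:25) {
    len <- sample(1:5, 1)                  # strictly shorter than N1 + 1
    h <- c(rep(0, 8), rep(1, len), rep(0, 8))
    expect_true(all(.automaton_chain(h) == "Normal"))
  }
})

test_that("Abnormal is reachable only through PotentialAbnormal", {
  set.seed(4)
  for (i in 1:30) {
    h <- rbinom(200, 1, 0.5)
    st <- as.character(.automaton_chain(h))
    prev <- c("Normal", st[-length(st)])
    entered <- which(st == "Abnormal" & prev != "Abnormal")
    if (length(entered))
      expect_true(all(prev[entered] == "PotentialAbnormal"))
  }
})

test_that("automaton_step matches the chain runner and releases after a normal streak", {
  h <- c(rep(1, 20), rep(0, 20))
  chain <- as.character(.automaton_chain(h))
  s <- "Normal"; timer <- 0; streak <- 0
  stepped <- character(length(h))
  for (k in seq_along(h)) {
    r <- automaton_step(s, timer, h[k], dt = 1, n1 = 5, n2 = 10,
                        streak = streak)
    s <- r$state; timer <- r$timer; streak <- r$streak
    stepped[k] <- s
  }
  expect_equal(stepped, chain)
  # release: after confirmation, 5 normal minutes return to Normal
  expect_equal(chain[20], "Abnormal")
  expect_equal(chain[25], "Normal")
})
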