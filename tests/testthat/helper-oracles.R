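# Independent brute-force oracles and shared fixtures used across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")

obs_df <- function(times, rooms)
  data.frame(time = utc(times), room = rooms, stringsAsFactors = FALSE)

# Brute-force stay splitter: assigns every whole second of the stay to the
# grid cell containing it and tallies minutes per (weekday, interval, room).
# Independent of split_stays(): works second by second.
split_oracle <- function(stays, delta_t = 60) {
  acc <- list()
  for (i in seq_len(nrow(stays))) {
    s0 <- as.numeric(stays$start[i])
    s1 <- as.numeric(stays$end[i])
    if (s1 <= s0) next
    secs <- seq(s0, s1 - 1)
    cell <- secs %/% (delta_t * 60)
    for (g in unique(cell)) {
      day <- ((g * delta_t) %/% 1440 + 4) %% 7 + 1
      iv <- ((g * delta_t) %% 1440) %/% delta_t + 1
      key <- paste(stays$room[i], day, iv)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        sum(cell == g) / 60
    }
  }
  acc
}

# minute-level occupancy tally: fraction of each cell's covered time spent
# in each room, from "person stays where last observed" first principles
occupancy_oracle <- function(obs, rooms, delta_t = 60) {
  t0 <- as.numeric(min(obs$time))
  t1 <- as.numeric(max(obs$time))
  secs <- seq(t0, t1 - 1)
  occupant <- obs$room[findInterval(secs, as.numeric(obs$time))]
  cell <- secs %/% (delta_t * 60)
  out <- list()
  for (g in unique(cell)) {
    sel <- cell == g
    tot <- sum(sel)
    day <- ((g * delta_t) %/% 1440 + 4) %% 7 + 1
    iv <- ((g * delta_t) %% 1440) %/% delta_t + 1
    for (rm in unique(occupant[sel]))
      out[[paste(day, iv, rm)]] <- sum(occupant[sel] == rm) / tot
  }
  out
}

# shared fitted model on 4 weeks of Profile A (built once per test run)
.fixture_env <- new.env()
profile_a_model <- function() {
  if (is.null(.fixture_env$m)) {
    ev <- simulate_profile("A", seed = 42)
    .fixture_env$ev <- ev
    .fixture_env$m <- behaviour_model(ev, attr(ev, "layout"),
                                      window_weeks = 4)
  }
  list(model = .fixture_env$m, events = .fixture_env$ev)
}
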