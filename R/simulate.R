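#' Synthetic single-resident mobility profiles
#'
#' Two contrasting daily routines over the six-room home of
#' \code{\link{default_home_layout}}:
#' \describe{
#'   \item{A, the "morning person"}{sleeps in the bedroom from midnight to
#'     08:00, is out of the home 08:00--16:00, and does domestic activities
#'     in the living room through the evening until midnight.}
#'   \item{B, the "nightly person"}{is out of the home from 23:00 through the
#'     night until 08:00, sleeps 08:00--16:00, and is active in the living
#'     room 16:00--23:00.}
#' }
#' Schedule boundaries are jittered day to day (\code{jitter_sd}); while at
#' home the person emits PIR observations with exponentially distributed
#' gaps (mean \code{active_gap} when active, \code{asleep_gap} when asleep)
#' and takes short excursions (night bathroom visits; evening kitchen and
#' store visits) that follow the room adjacency graph, one observation per
#' traversed room. Periods outside emit a single exit observation and then
#' silence until return.
#'
#' @param profile \code{"A"} or \code{"B"}.
#' @param weeks Number of weeks to simulate (default 12).
#' @param active_gap,asleep_gap Mean inter-observation gap (minutes) while
#'   active / asleep.
#' @param jitter_sd Standard deviation (minutes) of the day-to-day jitter on
#'   segment boundaries.
#' @param night_bathroom_rate Mean bathroom visits per sleeping segment.
#' @param kitchen_rate,store_rate Mean kitchen / store visits per active
#'   evening segment.
#' @return A profile specification list used by
#'   \code{\link{simulate_profile}}.
#' @export
profile_spec <- function(profile = c("A", "B"), weeks = 12,
                         active_gap = 5, asleep_gap = 30, jitter_sd = 10,
                         night_bathroom_rate = 0.5, kitchen_rate = 2,
                         store_rate = 0.2) {
  profile <- match.arg(profile)
  segments <- if (profile == "A") list(
    list(start = 0, end = 8, room = "Bedroom", state = "asleep"),
    list(start = 8, end = 16, room = "Outside", state = "away"),
    list(start = 16, end = 24, room = "Livingroom", state = "active")
  ) else list(
    list(start = 0, end = 8, room = "Outside", state = "away"),
    list(start = 8, end = 16, room = "Bedroom", state = "asleep"),
    list(start = 16, end = 23, room = "Livingroom", state = "active"),
    list(start = 23, end = 24, room = "Outside", state = "away")
  )
  excursions <- list(
    asleep = list(list(room = "Bathroom", rate = night_bathroom_rate,
                       dur = 3)),
    active = list(list(room = "Kitchen", rate = kitchen_rate, dur = 5),
                  list(room = "Store", rate = store_rate, dur = 2)))
  list(name = profile, weeks = weeks, segments = segments,
       excursions = excursions, active_gap = active_gap,
       asleep_gap = asleep_gap, jitter_sd = jitter_sd)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic PIR observation stream
#'
#' Simulates \code{spec$weeks} weeks of the given profile starting at
#' midnight of \code{start} (use a Sunday so learning windows align with
#' whole weeks). Identical \code{(spec, seed, start)} give byte-identical
#' streams.
#'
#' @param spec A \code{\link{profile_spec}} (or simply \code{"A"} /
#'   \code{"B"}).
#' @param start Start date (coerced to UTC midnight); default the Sunday
#'   2024-01-07.
#' @param seed Integer RNG seed.
#' @param layout Home layout (default \code{\link{default_home_layout}});
#'   every segment room must exist in it.
#' @return Observation stream (columns \code{time}, \code{sensor},
#'   \code{room}) with the spec, layout and start attached as attributes.
#' @export
simulate_profile <- function(spec = "A", start = "2024-01-07", seed = 1,
                             layout = default_home_layout()) {
  if (is.character(spec)) spec <- profile_spec(spec)
  segrooms <- vapply(spec$segments, `[[`, "", "room")
  if (!all(segrooms %in% layout$rooms))
    stop("segment room not in layout: ",
         paste(setdiff(segrooms, layout$rooms), collapse = ", "))
  start <- .as_utc(paste(as.character(as.Date(start)), "00:00:00"))
  t0 <- as.numeric(start)
  horizon <- spec$weeks * 7 * 86400

  .with_seed(seed, {
    pieces <- .occupancy_path(spec, layout, t0, horizon)
    pieces <- .insert_excursions(pieces, spec, layout)
    ev <- .emit_events(pieces, spec, layout)
    ev <- ev[ev$time < t0 + horizon, , drop = FALSE]
    out <- data.frame(
      time = .as_utc(ev$time),
      sensor = names(layout$sensor_map)[match(ev$room, layout$sensor_map)],
      room = ev$room, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    attr(out, "layout") <- layout
    attr(out, "start") <- start
    out
  })
}

# (room, state, t0, t1) pieces over the horizon with jittered boundaries and
# adjacency-path traversal between non-adjacent consecutive rooms
.occupancy_path <- function(spec, layout, t0, horizon) {
  ndays <- ceiling(horizon / 86400)
  segs <- spec$segments
  room <- character(0); state <- character(0); nominal <- numeric(0)
  for (d in seq_len(ndays) - 1) for (s in segs) {
    room <- c(room, s$room); state <- c(state, s$state)
    nominal <- c(nominal, t0 + d * 86400 + s$start * 3600)
  }
  # merge consecutive same-room segments (e.g. outside across midnight)
  keep <- c(TRUE, room[-1] != room[-length(room)])
  room <- room[keep]; state <- state[keep]; nominal <- nominal[keep]
  bt <- nominal + c(0, stats::rnorm(length(nominal) - 1, 0,
                                    spec$jitter_sd * 60))
  ramp <- 120 * seq_along(bt)                  # enforce gaps of >= 2 min
  bt <- round(cummax(bt - ramp) + ramp)
  out <- list()
  for (k in seq_along(room)) {
    t1 <- if (k < length(room)) bt[k + 1] else t0 + horizon
    if (k > 1) {
      path <- room_path(layout, room[k - 1], room[k])
      mid <- path[-c(1, length(path))]
      arrive <- bt[k]
      for (j in seq_along(mid))
        out[[length(out) + 1]] <- list(
          room = mid[j], state = "transit",
          t0 = arrive - 30 * (length(mid) - j + 1),
          t1 = arrive - 30 * (length(mid) - j))
    }
    out[[length(out) + 1]] <- list(room = room[k], state = state[k],
                                   t0 = bt[k], t1 = t1)
  }
  out
}

# random short visits out of asleep/active pieces, with path traversal
.insert_excursions <- function(pieces, spec, layout) {
  out <- list()
  for (p in pieces) {
    exc <- spec$excursions[[p$state]]
    if (is.null(exc) || (p$t1 - p$t0) < 1800) {
      out[[length(out) + 1]] <- p
      next
    }
    dur_h <- (p$t1 - p$t0) / 3600
    visits <- list()
    for (e in exc) {
      n <- stats::rpois(1, e$rate * dur_h / 8)
      if (n == 0) next
      lo <- p$t0 + 600; hi <- p$t1 - 600 - e$dur * 60
      if (hi <= lo) next
      at <- sort(stats::runif(n, lo, hi))
      for (a in at) visits[[length(visits) + 1]] <-
          list(room = e$room, at = a, dur = e$dur * 60)
    }
    if (!length(visits)) {
      out[[length(out) + 1]] <- p
      next
    }
    visits <- visits[order(vapply(visits, `[[`, 0, "at"))]
    cursor <- p$t0
    last_end <- -Inf
    for (v in visits) {
      if (v$at < last_end + 120) next     # drop overlapping visits
      path <- room_path(layout, p$room, v$room)
      mid <- path[-c(1, length(path))]
      leave <- v$at - 30 * length(mid)
      if (leave <= cursor) next
      out[[length(out) + 1]] <- list(room = p$room, state = p$state,
                                     t0 = cursor, t1 = leave)
      tt <- leave
      for (m in mid) {
        out[[length(out) + 1]] <- list(room = m, state = "transit",
                                       t0 = tt, t1 = tt + 30)
        tt <- tt + 30
      }
      out[[length(out) + 1]] <- list(room = v$room, state = "excursion",
                                     t0 = tt, t1 = tt + v$dur)
      tt <- tt + v$dur
      for (m in rev(mid)) {
        out[[length(out) + 1]] <- list(room = m, state = "transit",
                                       t0 = tt, t1 = tt + 30)
        tt <- tt + 30
      }
      cursor <- tt
      last_end <- tt
    }
    out[[length(out) + 1]] <- list(room = p$room, state = p$state,
                                   t0 = cursor, t1 = p$t1)
  }
  out
}

# one observation at each piece arrival; within in-home pieces further
# observations at exponential gaps; outside pieces stay silent after exit
.emit_events <- function(pieces, spec, layout) {
  tl <- vector("list", length(pieces))
  rl <- character(length(pieces))
  for (k in seq_along(pieces)) {
    p <- pieces[[k]]
    rl[k] <- p$room
    if (p$t1 <= p$t0) next
    tt <- p$t0
    gap <- switch(p$state, active = spec$active_gap,
                  excursion = spec$active_gap / 2,
                  asleep = spec$asleep_gap, NA)
    if (!is.na(gap)) {
      repeat {
        nxt <- tt[length(tt)] +
          max(1, round(stats::rexp(1, 1 / (gap * 60))))
        if (nxt >= p$t1) break
        tt <- c(tt, nxt)
      }
    }
    tl[[k]] <- tt
  }
  times <- unlist(tl)
  rooms <- rep(rl, lengths(tl))
  o <- order(times)
  data.frame(time = times[o], room = rooms[o], stringsAsFactors = FALSE)
}

.ANOMALY_TABLE <- list(
  A = list(OverSleeping = list(hours = c(8, 19), room = "Bedroom",
                               mode = "asleep"),
           LessSleeping = list(hours = c(0, 8), room = "Outside",
                               mode = "away"),
           NotBackHome = list(hours = c(16, 23), room = "Outside",
                              mode = "extend_away"),
           Dead = list(hours = c(8, 23), room = "Store", mode = "dead")),
  B = list(OverSleeping = list(hours = c(16, 23), room = "Bedroom",
                               mode = "asleep"),
           LessSleeping = list(hours = c(8, 16), room = "Kitchen",
                               mode = "active"),
           NotBackHome = list(hours = c(8, 23), room = "Outside",
                              mode = "extend_away"),
           Dead = list(hours = c(8, 23), room = "Store", mode = "dead")))

#' Inject an abnormal behaviour into a synthetic stream
#'
#' Baseline observations inside the anomaly window are \emph{replaced} (not
#' overlaid) so the ground truth is unambiguous:
#' \describe{
#'   \item{OverSleeping}{sleep-rate bedroom events extended through the
#'     window;}
#'   \item{LessSleeping}{activity in the override room during expected
#'     sleeping hours (for an Outside override, an exit event then
#'     silence);}
#'   \item{NotBackHome}{the ongoing outside period is simply never ended:
#'     all events from the last exit observation through the window are
#'     removed, so the scheduled return never happens;}
#'   \item{Dead}{a few events reaching the override room at the window
#'     start, then total silence.}
#' }
#' The per-profile windows and override rooms are fixed: e.g. profile A's
#' LessSleeping is being outside during sleeping hours (0--8], its Dead a
#' long stay in the store over hours (8--23).
#'
#' @param events Stream from \code{\link{simulate_profile}}.
#' @param kind One of OverSleeping, LessSleeping, NotBackHome, Dead.
#' @param day Date of the anomaly (must lie inside the stream).
#' @param profile \code{"A"} or \code{"B"}; defaults to the stream's own
#'   profile.
#' @param seed RNG seed for the injected event gaps.
#' @return List with the modified \code{events} and a \code{truth} record
#'   (kind, window start/end, room) for scoring.
#' @export
inject_anomaly <- function(events, kind = c("OverSleeping", "LessSleeping",
                                            "NotBackHome", "Dead"),
                           day, profile = NULL, seed = 1) {
  kind <- match.arg(kind)
  spec <- attr(events, "spec")
  if (is.null(profile)) profile <- if (is.null(spec)) "A" else spec$name
  info <- .ANOMALY_TABLE[[profile]][[kind]]
  w0 <- .as_utc(paste(as.character(as.Date(day)), "00:00:00")) +
    info$hours[1] * 3600
  w1 <- .as_utc(paste(as.character(as.Date(day)), "00:00:00")) +
    info$hours[2] * 3600
  if (w0 < min(events$time) || w1 > max(events$time))
    stop("injection window outside the stream's date range")
  prev <- attr(events, "truth")
  if (!is.null(prev) && w0 < prev$end && prev$start < w1)
    stop("overlapping anomaly injections")
  gaps <- list(asleep = if (is.null(spec)) 30 else spec$asleep_gap,
               active = if (is.null(spec)) 5 else spec$active_gap)
  t0 <- as.numeric(w0); t1 <- as.numeric(w1)
  if (info$mode == "extend_away") {
    # the person never comes back: silence from the last exit observation
    # (the most recent observation in the override room before the window)
    # through the window end
    before <- events$time < w0 & events$room == info$room
    if (!any(before))
      stop("no prior ", info$room, " exit to extend for NotBackHome")
    anchor <- max(events$time[before])
    keep <- events$time <= anchor | events$time >= w1
    out <- events[keep, c("time", "sensor", "room")]
    rownames(out) <- NULL
    truth <- list(kind = kind, start = w0, end = w1, room = info$room)
    attributes(out) <- c(attributes(out),
                         attributes(events)[c("spec", "layout", "start")])
    attr(out, "truth") <- truth
    return(list(events = out, truth = truth))
  }
  new_t <- .with_seed(seed, switch(
    info$mode,
    away = t0,
    dead = c(t0, t0 + 30, t0 + 60),
    {
      gap <- gaps[[info$mode]] * 60
      tt <- t0; acc <- t0
      repeat {
        tt <- tt + max(1, round(stats::rexp(1, 1 / gap)))
        if (tt >= t1) break
        acc <- c(acc, tt)
      }
      acc
    }))
  layout <- attr(events, "layout")
  if (is.null(layout)) layout <- default_home_layout()
  injected <- data.frame(
    time = .as_utc(new_t),
    sensor = names(layout$sensor_map)[match(info$room, layout$sensor_map)],
    room = info$room, stringsAsFactors = FALSE)
  r0 <- w0
  if (info$mode == "asleep") {
    # prolonged sleep: the scheduled wake-up never happens, so any wake
    # transition that jitter placed just before the window is removed too
    # (back to the last sleep observation)
    cand <- events$time < w0 & events$time >= w0 - 5400 &
      events$room == info$room
    if (any(cand)) r0 <- max(events$time[cand]) + 1
  }
  keep <- events$time < r0 | events$time >= w1
  out <- rbind(events[keep, c("time", "sensor", "room")], injected)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  truth <- list(kind = kind, start = w0, end = w1, room = info$room)
  attributes(out) <- c(attributes(out),
                       attributes(events)[c("spec", "layout", "start")])
  attr(out, "truth") <- truth
  list(events = out, truth = truth)
}

#' Read / write anomaly ground truth (JSON)
#'
#' @param truth Truth record from \code{\link{inject_anomaly}}.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(kind = truth$kind,
         start = format(truth$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         end = format(truth$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         room = truth$room),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(kind = doc$kind,
       start = as.POSIXct(doc$start, tz = "UTC",
                          tryFormats = "%Y-%m-%dT%H:%M:%S"),
       end = as.POSIXct(doc$end, tz = "UTC",
                        tryFormats = "%Y-%m-%dT%H:%M:%S"),
       room = doc$room)
}
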