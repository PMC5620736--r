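#' Fit a weekly mobility behaviour model from PIR observations
#'
#' Learns, for every weekday and time-of-day interval, the resident's room
#' occupancy and movement statistics from an observation stream:
#' \itemize{
#'   \item \strong{TS} — total stay minutes per room, averaged over the
#'     window days mapping to the cell;
#'   \item \strong{P} — the room transition matrix. Self-transitions
#'     \eqn{P^{i,i} = TS^i / \sum_j TS^j} give the probability of finding the
#'     person in room \eqn{i} during the cell; off-diagonal mass
#'     \eqn{(1 - P^{i,i})} is allocated proportionally to observed transition
#'     counts \eqn{M^{i,j}};
#'   \item \strong{AG / AE / AA} — global, inter-room and per-room activity
#'     rates (observations or transitions per minute);
#'   \item per-weekday, per-room \strong{longest continuous stays} (maximal
#'     dwell runs uninterrupted by another room).
#' }
#' Observations outside \code{[window_start, window_start + 7 \* window_weeks
#' days)} are ignored, which makes the function double as the batch rebuild
#' behind the sliding learning window (see
#' \code{\link{update.behaviour_model}}).
#'
#' @param obs Observation stream (see \code{\link{as_observations}}).
#' @param layout A \code{\link{bms_layout}}.
#' @param window_start Start of the learning window (POSIXct midnight); by
#'   default the midnight (UTC) of the first observation's day.
#' @param window_weeks Length of the learning window in whole weeks
#'   (default 4).
#' @param delta_t Time-grid interval in minutes (default 60); must divide
#'   1440. Intervals are half-open \eqn{(t, t + \Delta t]}.
#' @return An object of class \code{behaviour_model}.
#' @seealso \code{\link{detect}}, \code{\link{simulate_profile}}
#' @export
behaviour_model <- function(obs, layout, window_start = NULL,
                            window_weeks = 4, delta_t = 60) {
  delta_t <- .check_delta_t(delta_t)
  if (window_weeks < 1) stop("learning window must be at least 1 week")
  if (!all(obs$room %in% layout$rooms))
    stop("observations reference rooms not in the layout")
  if (is.null(window_start)) {
    window_start <- .as_utc(trunc(min(obs$time), "days"))
  } else window_start <- .as_utc(window_start)
  window_end <- window_start + window_weeks * 7 * 86400
  inw <- obs$time >= window_start & obs$time < window_end
  obs <- obs[inw, , drop = FALSE]
  if (nrow(obs) < 2) stop("fewer than two observations inside the window")
  counts <- .count_window(obs, layout, window_start, window_weeks, delta_t)
  m <- .finalise_model(counts, layout, delta_t)
  m$window <- list(start = window_start, end = window_end,
                   weeks = window_weeks)
  m$buffer <- obs
  m
}

# raw per-cell tallies over one learning window
.count_window <- function(obs, layout, window_start, window_weeks, delta_t) {
  rooms <- layout$rooms
  r <- length(rooms)
  nI <- 1440L %/% delta_t
  ri <- match(obs$room, rooms)
  em <- .epoch_min(obs$time)

  # dwell minutes per cell x room, from interval-split stays
  stays <- stays_from_observations(obs)
  pieces <- split_stays(stays, delta_t)
  TS <- array(0, dim = c(7, nI, r))
  if (nrow(pieces)) {
    key <- pieces$weekday + 7 * (pieces$interval - 1) +
      7 * nI * (match(pieces$room, rooms) - 1)
    tab <- rowsum(pieces$minutes, key)
    TS[as.integer(rownames(tab))] <- tab
  }

  # transition counts (cell of the later observation of each pair)
  M <- array(0, dim = c(7, nI, r, r))
  n <- length(em)
  if (n >= 2) {
    g <- .cell_at(em[-1], delta_t)
    key <- .cell_day(g, delta_t) + 7 * (.cell_interval(g, delta_t) - 1) +
      7 * nI * (ri[-n] - 1) + 7 * nI * r * (ri[-1] - 1)
    tab <- rowsum(rep(1, length(key)), key)
    M[as.integer(rownames(tab))] <- tab
  }

  # observation counts per cell x room
  OC <- array(0, dim = c(7, nI, r))
  g <- .cell_at(em, delta_t)
  key <- .cell_day(g, delta_t) + 7 * (.cell_interval(g, delta_t) - 1) +
    7 * nI * (ri - 1)
  tab <- rowsum(rep(1, length(key)), key)
  OC[as.integer(rownames(tab))] <- tab

  # number of calendar dates of each weekday inside the window
  days <- seq(window_start, by = "1 day", length.out = 7 * window_weeks)
  ndays <- tabulate(as.POSIXlt(days, tz = "UTC")$wday + 1, nbins = 7)

  # continuous stays: consecutive same-room stays merged; a run is credited
  # to the weekday on which it started
  cs_list <- rep(list(stats::setNames(rep(list(numeric(0)), r), rooms)), 7)
  if (nrow(stays)) {
    rl <- rle(stays$room)
    rid <- rep(seq_along(rl$lengths), rl$lengths)
    dur <- as.vector(rowsum(stays$duration, rid))
    first <- c(1L, cumsum(rl$lengths)[-length(rl$lengths)] + 1L)
    wd <- as.POSIXlt(stays$start[first], tz = "UTC")$wday + 1
    for (k in seq_along(rl$values))
      cs_list[[wd[k]]][[rl$values[k]]] <-
        c(cs_list[[wd[k]]][[rl$values[k]]], dur[k])
  }
  list(TS = TS, M = M, OC = OC, ndays = ndays, cs_list = cs_list)
}

# derive probabilities, activity rates and stay profiles from raw tallies
.finalise_model <- function(counts, layout, delta_t) {
  rooms <- layout$rooms
  r <- length(rooms)
  nI <- dim(counts$TS)[2]
  nd <- pmax(counts$ndays, 1L)                # weekdays absent from window
  TSn <- sweep(counts$TS, 1, nd, "/")
  Mn <- sweep(counts$M, 1, nd, "/")
  OCn <- sweep(counts$OC, 1, nd, "/")

  tot <- apply(TSn, c(1, 2), sum)             # observed minutes per cell
  pstay <- sweep(TSn, c(1, 2), ifelse(tot > 0, tot, 1), "/")
  observed <- TSn > 0

  # row-normalised transition matrix; degenerate rows (dwell observed but no
  # outgoing transitions in the cell) keep their mass on the diagonal
  selfM <- array(0, dim = dim(Mn))
  for (i in seq_len(r)) selfM[, , i, i] <- Mn[, , i, i]
  offM <- Mn - selfM
  offsum <- apply(offM, c(1, 2, 3), sum)
  P <- array(0, dim = c(7, nI, r, r))
  denom <- ifelse(offsum > 0, offsum, 1)
  for (j in seq_len(r))
    P[, , , j] <- (1 - pstay) * offM[, , , j] / denom
  for (i in seq_len(r)) {
    P[, , i, i] <- ifelse(observed[, , i] & offsum[, , i] == 0,
                          1, pstay[, , i])
    P[, , i, ][!observed[, , i]] <- 0        # unobserved room: all-zero row
  }

  AG <- apply(OCn, c(1, 2), sum) / delta_t
  AA <- OCn / delta_t
  AE <- (apply(Mn, c(1, 2), sum) - apply(selfM, c(1, 2), sum)) / delta_t

  cs_longest <- matrix(0, 7, r, dimnames = list(.WEEKDAYS, rooms))
  for (d in 1:7) for (i in seq_len(r)) {
    v <- counts$cs_list[[d]][[i]]
    if (length(v)) cs_longest[d, i] <- max(v)
  }

  structure(list(layout = layout, delta_t = delta_t, n_intervals = nI,
                 counts = counts, TS = TSn, pstay = pstay, P = P,
                 observed = observed, AG = AG, AE = AE, AA = AA,
                 cs_list = counts$cs_list, cs_longest = cs_longest,
                 max_AG = max(AG), window = NULL, buffer = NULL),
            class = "behaviour_model")
}

.wd <- function(weekday) {
  if (is.character(weekday)) {
    i <- match(weekday, .WEEKDAYS)
    if (anyNA(i)) stop("unknown weekday: ", weekday)
    i
  } else as.integer(weekday)
}

.room_i <- function(model, room) {
  i <- match(room, model$layout$rooms)
  if (anyNA(i)) stop("unknown room: ", room)
  i
}

#' Model-cell accessors
#'
#' Per-cell quantities of a fitted \code{\link{behaviour_model}}:
#' \code{self_transition_prob} is the probability of finding the person in a
#' room during the cell (dwell share of the interval);
#' \code{transition_prob} the probability of an \code{from}-to-\code{to}
#' movement; \code{total_stay_time} the day-averaged dwell minutes;
#' \code{global_activity}, \code{inter_room_activity} and
#' \code{intra_room_activity} are observation/transition rates per minute;
#' \code{longest_stay} the longest learned continuous stay (minutes) for a
#' room on a weekday.
#'
#' @param model A \code{behaviour_model}.
#' @param weekday Weekday name ("Sunday".."Saturday") or index (1 = Sunday).
#' @param interval 1-based interval index within the day (e.g. 5 is the
#'   interval (4--5] on an hourly grid).
#' @param room,from,to Room names.
#' @name model-accessors
#' @export
self_transition_prob <- function(model, weekday, interval, room)
  model$pstay[.wd(weekday), interval, .room_i(model, room)]

#' @rdname model-accessors
#' @export
transition_prob <- function(model, weekday, interval, from, to)
  model$P[.wd(weekday), interval, .room_i(model, from),
          .room_i(model, to)]

#' @rdname model-accessors
#' @export
total_stay_time <- function(model, weekday, interval, room)
  model$TS[.wd(weekday), interval, .room_i(model, room)]

#' @rdname model-accessors
#' @export
global_activity <- function(model, weekday, interval)
  model$AG[.wd(weekday), interval]

#' @rdname model-accessors
#' @export
inter_room_activity <- function(model, weekday, interval)
  model$AE[.wd(weekday), interval]

#' @rdname model-accessors
#' @export
intra_room_activity <- function(model, weekday, interval, room)
  model$AA[.wd(weekday), interval, .room_i(model, room)]

#' @rdname model-accessors
#' @export
longest_stay <- function(model, weekday, room)
  model$cs_longest[.wd(weekday), .room_i(model, room)]

#' Room the model expects the person to be in at a given instant
#'
#' The argmax of the self-transition probabilities of the grid cell
#' containing \code{when}; ties are broken by layout room order. Returns
#' \code{NA} for an unmodelled (all-zero) cell.
#'
#' @param model A \code{behaviour_model}.
#' @param when POSIXct instant(s).
#' @return Character vector of room names (or \code{NA}).
#' @export
expected_room <- function(model, when) {
  g <- .cell_at(.epoch_min(.as_utc(when)), model$delta_t)
  d <- .cell_day(g, model$delta_t)
  k <- .cell_interval(g, model$delta_t)
  vapply(seq_along(d), function(s) {
    p <- model$pstay[d[s], k[s], ]
    if (all(p == 0)) NA_character_
    else model$layout$rooms[which.max(p)]
  }, character(1))
}

#' Shift the learning window and refit
#'
#' Implements the weekly sliding-window update: the window advances by
#' \code{shift_weeks}, observations that fell out of it are dropped, the new
#' week's observations are appended to the buffer, and the model is rebuilt.
#' The result is identical to a from-scratch fit on the shifted window.
#'
#' @param object A \code{behaviour_model} fitted by
#'   \code{\link{behaviour_model}} (it must carry its observation buffer).
#' @param new_obs Observations covering the incoming shift period.
#' @param shift_weeks Window shift in weeks (default 1).
#' @param ... Unused.
#' @return The refitted \code{behaviour_model} over the shifted window.
#' @export
update.behaviour_model <- function(object, new_obs, shift_weeks = 1, ...) {
  if (is.null(object$buffer))
    stop("model carries no observation buffer (deserialised model?)")
  start <- object$window$start + shift_weeks * 7 * 86400
  end <- start + object$window$weeks * 7 * 86400
  keep <- object$buffer[object$buffer$time >= start, , drop = FALSE]
  add <- new_obs[new_obs$time >= start & new_obs$time < end, , drop = FALSE]
  add <- add[!add$time %in% keep$time, , drop = FALSE]
  comb <- rbind(keep[, c("time", "sensor", "room")],
                add[, c("time", "sensor", "room")])
  comb <- comb[order(comb$time), , drop = FALSE]
  if (nrow(add) == 0)
    warning("no new observations inside the shifted window")
  behaviour_model(comb, object$layout, window_start = start,
                  window_weeks = object$window$weeks,
                  delta_t = object$delta_t)
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat("Behaviour model (", length(x$layout$rooms), " rooms, Δt = ",
      x$delta_t, " min, ", x$n_intervals, " intervals/day)\n", sep = "")
  if (!is.null(x$window))
    cat("  window:", format(x$window$start, "%Y-%m-%d"), "to",
        format(x$window$end, "%Y-%m-%d"),
        sprintf("(%d weeks)\n", x$window$weeks))
  cat(sprintf("  max global activity: %.3f events/min\n", x$max_AG))
  cov <- mean(apply(x$TS, c(1, 2), sum) / x$delta_t)
  cat(sprintf("  mean cell coverage: %.1f%%\n", 100 * cov))
  invisible(x)
}

#' @export
summary.behaviour_model <- function(object, ...) {
  x <- object
  print(x)
  cat("\nMost probable room per interval (rows = weekdays):\n")
  arg <- matrix("", 7, x$n_intervals, dimnames = list(.WEEKDAYS, NULL))
  for (d in 1:7) for (k in seq_len(x$n_intervals)) {
    p <- x$pstay[d, k, ]
    arg[d, k] <- if (all(p == 0)) "-" else
      substr(x$layout$rooms[which.max(p)], 1, 2)
  }
  print(arg, quote = FALSE)
  invisible(arg)
}

#' @export
coef.behaviour_model <- function(object, weekday = NULL, interval = NULL,
                                 ...) {
  P <- object$P
  dimnames(P) <- list(.WEEKDAYS, NULL, object$layout$rooms,
                      object$layout$rooms)
  if (!is.null(weekday) && !is.null(interval))
    return(P[.wd(weekday), interval, , ])
  P
}

#' Location likelihood of observed rooms under the model
#'
#' For each row of \code{newdata} (columns \code{time} and \code{room}),
#' returns the model's probability of finding the person in that room during
#' the weekday/interval cell containing \code{time} — the raw location
#' likelihood used by the detection estimator. With
#' \code{normalise = TRUE} each value is divided by the cell's most probable
#' room's probability (0 for unmodelled cells).
#'
#' @param object A \code{behaviour_model}.
#' @param newdata Data frame with \code{time} (POSIXct) and \code{room}.
#' @param normalise Normalise by the cell maximum (default \code{FALSE}).
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict.behaviour_model <- function(object, newdata, normalise = FALSE,
                                    ...) {
  g <- .cell_at(.epoch_min(.as_utc(newdata$time)), object$delta_t)
  d <- .cell_day(g, object$delta_t)
  k <- .cell_interval(g, object$delta_t)
  ri <- match(newdata$room, object$layout$rooms)
  l <- ifelse(is.na(ri), 0,
              object$pstay[cbind(d, k, ifelse(is.na(ri), 1L, ri))])
  if (normalise) {
    mx <- apply(object$pstay, c(1, 2), max)[cbind(d, k)]
    l <- ifelse(mx > 0, pmin(l / mx, 1), 0)
  }
  l
}

#' Plot learned occupancy probabilities over the day
#'
#' Stacked per-interval self-transition (stay) probabilities for one weekday,
#' the usual way to inspect what daily routine the model has learned.
#'
#' @param x A \code{behaviour_model}.
#' @param weekday Weekday to plot (default Monday).
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @export
plot.behaviour_model <- function(x, weekday = "Monday", ...) {
  d <- .wd(weekday)
  m <- t(x$pstay[d, , ])
  rownames(m) <- x$layout$rooms
  graphics::barplot(m, names.arg = seq_len(ncol(m)) - 1, border = NA,
                    col = grDevices::hcl.colors(nrow(m), "Dark 3"),
                    xlab = "hour of day", ylab = "stay probability",
                    main = paste("Learned occupancy,", .WEEKDAYS[d]),
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", bg = "white"), ...)
  invisible(m)
}

#' Serialise a behaviour model to versioned JSON
#'
#' Writes grid specification, per-cell tallies, day profiles and the maximum
#' global activity. \code{model_read} rebuilds the derived probabilities from
#' the stored tallies. A deserialised model has no observation buffer, so it
#' can be used for detection but not for \code{\link[=update.behaviour_model]{update}}.
#'
#' @param model A \code{behaviour_model}.
#' @param path Output / input file path.
#' @export
model_write <- function(model, path) {
  doc <- list(
    format = "bmsense-model", version = 1L,
    delta_t = model$delta_t,
    rooms = model$layout$rooms,
    sensor_map = as.list(model$layout$sensor_map),
    adjacency = model$layout$adjacency,
    window = list(start = format(model$window$start, "%Y-%m-%dT%H:%M:%S"),
                  weeks = model$window$weeks),
    ndays = model$counts$ndays,
    # arrays stored flat in R column-major order; dims follow from the
    # grid spec (7 x intervals x rooms [x rooms])
    TS = as.vector(model$counts$TS), M = as.vector(model$counts$M),
    OC = as.vector(model$counts$OC),
    cs_list = model$counts$cs_list,
    max_AG = model$max_AG)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_write
#' @export
model_read <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "bmsense-model"))
    stop("not a bmsense model document")
  rooms <- unlist(doc$rooms)
  adjacency <- matrix(unlist(doc$adjacency), ncol = 2, byrow = TRUE)
  layout <- bms_layout(rooms, unlist(doc$sensor_map), adjacency)
  r <- length(rooms)
  delta_t <- as.integer(doc$delta_t)
  nI <- 1440L %/% delta_t
  counts <- list(
    TS = array(unlist(doc$TS), dim = c(7, nI, r)),
    M = array(unlist(doc$M), dim = c(7, nI, r, r)),
    OC = array(unlist(doc$OC), dim = c(7, nI, r)),
    ndays = as.integer(unlist(doc$ndays)),
    cs_list = lapply(seq_len(7), function(d)
      stats::setNames(lapply(rooms, function(rm) {
        v <- doc$cs_list[[d]][[rm]]
        if (is.null(v)) numeric(0) else as.numeric(unlist(v))
      }), rooms)))
  m <- .finalise_model(counts, layout, delta_t)
  start <- as.POSIXct(doc$window$start, tz = "UTC",
                      tryFormats = "%Y-%m-%dT%H:%M:%S")
  m$window <- list(start = start,
                   end = start + doc$window$weeks * 7 * 86400,
                   weeks = doc$window$weeks)
  m
}
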