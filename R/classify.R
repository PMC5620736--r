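## Rule-based classification of confirmed deviations.
##
## The classifier combines the automaton state with the remaining model
## dimensions: the current continuous stay against the learned longest stay,
## the weighted model activity against the sampled activity, and the
## detected room against the model's expected room.

#' Weighted global activity at an instant
#'
#' Convex combination of the model's global activity in the current and
#' previous grid cells, weighted by the minutes elapsed in the current
#' interval: at the start of an interval it equals the previous cell's rate,
#' at the end the current cell's.
#'
#' @param model A \code{\link{behaviour_model}}.
#' @param now POSIXct instant(s).
#' @return Expected events-per-minute rate(s).
#' @export
weighted_global_activity <- function(model, now) {
  dt <- model$delta_t
  m <- .epoch_min(.as_utc(now))
  gcur <- .cell_at(m, dt)
  gprev <- gcur - 1
  minutes <- m - gcur * dt
  cur <- model$AG[cbind(.cell_day(gcur, dt), .cell_interval(gcur, dt))]
  prev <- model$AG[cbind(.cell_day(gprev, dt), .cell_interval(gprev, dt))]
  minutes / dt * cur + (dt - minutes) / dt * prev
}

#' Sampled global activity at an instant
#'
#' Observation count in the trailing window of one grid interval ending at
#' \code{now}, divided by the interval length — the live counterpart of the
#' model's global activity rate.
#'
#' @param obs Observation stream.
#' @param now POSIXct instant(s).
#' @param delta_t Window length in minutes (default 60).
#' @return Events-per-minute rate(s).
#' @export
sampled_global_activity <- function(obs, now, delta_t = 60) {
  os <- as.numeric(obs$time)
  ns <- as.numeric(.as_utc(now))
  (findInterval(ns, os) - findInterval(ns - delta_t * 60, os)) / delta_t
}

.LEVELS <- c("VeryLow", "Low", "Medium", "High", "VeryHigh")

# band index 1..5 of x relative to max_AG (equal 0.2-wide bands)
.activity_band <- function(x, max_AG) {
  if (max_AG <= 0) return(rep(1L, length(x)))
  pmin(pmax(findInterval(x / max_AG, c(0.2, 0.4, 0.6, 0.8)) + 1L, 1L), 5L)
}

#' Quantise an activity rate into five levels
#'
#' Rates are expressed as a fraction of the model's maximum global activity
#' and cut into five equal bands: below 20\% is VeryLow, 80\% and above is
#' VeryHigh.
#'
#' @param x Activity rate(s) (events per minute).
#' @param max_AG The model's maximum global activity.
#' @return Factor with levels VeryLow, Low, Medium, High, VeryHigh.
#' @export
activity_level <- function(x, max_AG)
  factor(.LEVELS[.activity_band(x, max_AG)], levels = .LEVELS)

#' Match weighted and sampled activity levels
#'
#' Two activity levels agree ("Normal") when they differ by at most one
#' band; a larger discrepancy between what the model expects and what the
#' stream shows is "Abnormal". Over the five levels this yields the
#' tridiagonal 5x5 agreement matrix.
#'
#' @param level_w,level_s Levels (as from \code{\link{activity_level}}).
#' @return \code{"Normal"} or \code{"Abnormal"} per pair.
#' @export
activity_match <- function(level_w, level_s) {
  iw <- match(as.character(level_w), .LEVELS)
  is <- match(as.character(level_s), .LEVELS)
  ifelse(abs(iw - is) <= 1, "Normal", "Abnormal")
}

#' Classify the current continuous stay
#'
#' \code{"High"} when the ongoing continuous stay in a room has reached the
#' expected longest continuous stay learned for it (a stay equal to the
#' learned longest already fails "less than expected"), otherwise
#' \code{"Normal"}. A zero-length current stay is always Normal. By default
#' the expectation is the room's longest learned stay over the whole week;
#' passing a \code{weekday} compares against that weekday's own profile
#' instead (a stricter check, noisy when the window holds only a few
#' occurrences of each weekday).
#'
#' @param current_cs Ongoing continuous stay in minutes.
#' @param model A \code{\link{behaviour_model}}.
#' @param room Room of the stay.
#' @param weekday Optional weekday name or index (1 = Sunday).
#' @return \code{"Normal"} or \code{"High"}.
#' @export
stay_state <- function(current_cs, model, room, weekday = NULL) {
  expected <- if (is.null(weekday))
    max(model$cs_longest[, .room_i(model, room)])
  else longest_stay(model, weekday, room)
  ifelse(current_cs > 0 & current_cs >= expected, "High", "Normal")
}

#' Label a detection chain with anomaly classes
#'
#' Applies the rule cascade to each sample of a chain produced by
#' \code{\link{detect}}. No anomaly label is ever emitted while the
#' automaton is in its Normal state; the remaining rules fire in order:
#' \enumerate{
#'   \item detected room is the bedroom and the continuous stay is High:
#'     \strong{OverSleeping};
#'   \item the model expects the bedroom (sleeping time) but the person is
#'     detected elsewhere: \strong{LessSleeping};
#'   \item detected Outside with a High stay: \strong{NotBackHome};
#'   \item detected in another room with a High stay, mismatching activity
#'     and a VeryLow sampled activity, with the deviation fully confirmed
#'     (Abnormal state): \strong{Dead};
#'   \item otherwise the sample stays Normal (an unclassified deviation).
#' }
#' OverSleeping and LessSleeping are tested first because bedroom presence
#' and expected sleeping time are the least ambiguous evidence; a
#' non-bedroom presence during expected sleep is always read as
#' LessSleeping, whichever room it occurs in.
#'
#' @param model A \code{\link{behaviour_model}}.
#' @param chain A \code{bms_detection} data frame.
#' @param obs The observation stream the chain was computed from.
#' @param bedroom,outside Names of the sleeping room and virtual outside
#'   room.
#' @return The chain with added columns \code{label}, \code{expected},
#'   \code{cs}, \code{S}, \code{W_AG}, \code{S_AG}, \code{W}.
#' @export
classify_chain <- function(model, chain, obs, bedroom = "Bedroom",
                           outside = "Outside") {
  n <- nrow(chain)
  times <- chain$time

  # ongoing continuous stay: minutes since the detected room last changed,
  # traced through the observation stream
  os <- as.numeric(obs$time)
  newrun <- c(TRUE, obs$room[-1] != obs$room[-nrow(obs)])
  run_start <- os[newrun][cumsum(newrun)]
  idx <- findInterval(as.numeric(times), os)
  cs <- ifelse(idx > 0,
               (as.numeric(times) - run_start[pmax(idx, 1)]) / 60, 0)

  expd <- expected_room(model, times)
  week_max <- apply(model$cs_longest, 2, max)
  exp_long <- week_max[match(chain$room, model$layout$rooms)]
  S <- ifelse(cs > 0 & !is.na(exp_long) & cs >= exp_long, "High", "Normal")

  W_AG <- weighted_global_activity(model, times)
  S_AG <- sampled_global_activity(obs, times, model$delta_t)
  bw <- .activity_band(W_AG, model$max_AG)
  bs <- .activity_band(S_AG, model$max_AG)
  W <- ifelse(abs(bw - bs) <= 1, "Normal", "Abnormal")

  active <- chain$state != "Normal" & !chain$warmup
  room <- chain$room
  label <- rep("Normal", n)
  r5 <- active & chain$state == "Abnormal" &
    !(room %in% c(bedroom, outside)) & S == "High" &
    W == "Abnormal" & bs == 1L
  r4 <- active & room == outside & S == "High"
  r3 <- active & !is.na(expd) & expd == bedroom & room != bedroom
  r2 <- active & room == bedroom & S == "High"
  label[r5 %in% TRUE] <- "Dead"
  label[r4 %in% TRUE] <- "NotBackHome"
  label[r3 %in% TRUE] <- "LessSleeping"
  label[r2 %in% TRUE] <- "OverSleeping"

  chain$label <- label
  chain$expected <- expd
  chain$cs <- cs
  chain$S <- S
  chain$W_AG <- W_AG
  chain$S_AG <- S_AG
  chain$W <- W
  chain
}

#' Write a detection chain / alarm log to CSV
#'
#' @param chain A \code{bms_detection} data frame.
#' @param path Output path.
#' @export
write_chain_csv <- function(chain, path) {
  out <- chain
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
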