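## Observation streams, the weekly time grid, and stay extraction.
##
## An observation is one PIR trigger <timestamp, sensor>. Streams are plain
## data frames with columns `time` (POSIXct, UTC), `sensor` and `room`.
## Timestamps are stored to the second; durations are fractional minutes.

# Boundary convention: grid intervals are half-open (t, t + delta_t], so an
# event falling exactly on a boundary belongs to the earlier-labelled cell.
# EPS (minutes) implements that convention for instantaneous events.
.EPS <- 1e-7

# minutes since the Unix epoch (1970-01-01 00:00 UTC, a Thursday)
.epoch_min <- function(t) as.numeric(t) / 60

# global grid-cell index of an epoch-minute instant, boundary -> earlier cell
.cell_at <- function(m, delta_t) floor((m - .EPS) / delta_t)

# weekday (1 = Sunday .. 7 = Saturday) and within-day interval (1-based) of a
# global cell index
.cell_day <- function(g, delta_t) ((g * delta_t) %/% 1440 + 4) %% 7 + 1
.cell_interval <- function(g, delta_t) ((g * delta_t) %% 1440) %/% delta_t + 1

.WEEKDAYS <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
               "Friday", "Saturday")

.check_delta_t <- function(delta_t) {
  if (length(delta_t) != 1 || delta_t <= 0 || 1440 %% delta_t != 0)
    stop("delta_t must divide 1440 minutes")
  as.integer(delta_t)
}

.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x),
                                               origin = "1970-01-01",
                                               tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

#' Coerce a sensor event log to an observation stream
#'
#' Maps sensor identifiers to rooms through the layout, drops records from
#' unknown sensors with a warning (the count is kept in the
#' \code{"n_dropped"} attribute), and validates time ordering. Duplicate
#' timestamps from distinct sensors are kept in file order; the resulting
#' zero-length stay still records the room transition.
#'
#' @param x Data frame with columns \code{time} (or \code{timestamp}) and
#'   \code{sensor} (or \code{sensor_id}); a \code{room} column, if present,
#'   is taken as already mapped.
#' @param layout A \code{\link{bms_layout}}; required unless \code{x} already
#'   carries a \code{room} column.
#' @return Data frame with columns \code{time}, \code{sensor}, \code{room},
#'   sorted by time.
#' @export
as_observations <- function(x, layout = NULL) {
  nm <- names(x)
  tcol <- intersect(c("time", "timestamp", "ts"), nm)[1]
  if (is.na(tcol)) stop("no time/timestamp column")
  time <- .as_utc(x[[tcol]])
  if (is.unsorted(as.numeric(time))) stop("observations must be sorted by time")
  scol <- intersect(c("sensor", "sensor_id"), nm)[1]
  sensor <- if (!is.na(scol)) as.character(x[[scol]]) else NA_character_
  if ("room" %in% nm) {
    room <- as.character(x$room)
    keep <- rep(TRUE, length(room))
  } else {
    if (is.null(layout)) stop("layout required to map sensors to rooms")
    room <- unname(layout$sensor_map[sensor])
    keep <- !is.na(room)
    if (any(!keep))
      warning(sum(!keep), " observation(s) from unknown sensors dropped")
  }
  out <- data.frame(time = time[keep], sensor = sensor[keep],
                    room = room[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read / write an observation event log (CSV)
#'
#' The on-disk format is a CSV with header \code{timestamp,sensor_id} and
#' ISO-8601 timestamps (UTC).
#'
#' @param path File path.
#' @param layout A \code{\link{bms_layout}} used to map sensors to rooms.
#' @return \code{read_events_csv}: an observation stream
#'   (see \code{\link{as_observations}}).
#' @export
read_events_csv <- function(path, layout) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- as.POSIXct(df$timestamp, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS"))
  as_observations(df, layout)
}

#' @rdname read_events_csv
#' @param obs Observation stream to write.
#' @export
write_events_csv <- function(obs, path) {
  utils::write.csv(
    data.frame(timestamp = format(obs$time, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               sensor_id = obs$sensor),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an observation stream into dwell episodes (stays)
#'
#' A stay is the interval between two consecutive observations, attributed to
#' the room of the earlier one: for observations \eqn{o_{k-1}, o_k} the stay
#' spans \eqn{[ts_{k-1}, ts_k]} in room \eqn{room(o_{k-1})}. \eqn{n}
#' observations yield \eqn{n-1} stays. Zero-duration stays (duplicate
#' timestamps) are retained; they contribute transitions but no dwell time.
#'
#' @param obs Observation stream (columns \code{time}, \code{room}), sorted.
#' @param layout Optional \code{\link{bms_layout}}; with
#'   \code{strict = TRUE}, observed transitions between non-adjacent rooms
#'   raise a warning.
#' @param strict Warn on adjacency violations (default \code{FALSE}).
#' @return Data frame with columns \code{room}, \code{start}, \code{end},
#'   \code{duration} (minutes).
#' @examples
#' obs <- data.frame(
#'   time = as.POSIXct(c("2024-01-01 04:00:00", "2024-01-01 05:30:00"),
#'                     tz = "UTC"),
#'   room = c("Bedroom", "Bathroom"))
#' stays_from_observations(obs)   # one 90-min stay in the Bedroom
#' @export
stays_from_observations <- function(obs, layout = NULL, strict = FALSE) {
  if (nrow(obs) == 0) stop("empty observation stream")
  if (is.unsorted(as.numeric(obs$time))) stop("observations must be sorted")
  n <- nrow(obs)
  if (n < 2)
    return(data.frame(room = character(0),
                      start = obs$time[0], end = obs$time[0],
                      duration = numeric(0)))
  st <- data.frame(room = obs$room[-n],
                   start = obs$time[-n],
                   end = obs$time[-1],
                   stringsAsFactors = FALSE)
  st$duration <- as.numeric(st$end - st$start, units = "mins")
  if (strict && !is.null(layout)) {
    to <- obs$room[-1]
    bad <- mapply(function(a, b) a != b && !is_adjacent(layout, a, b),
                  st$room, to)
    if (any(bad))
      warning(sum(bad), " transition(s) between non-adjacent rooms")
  }
  st
}

#' Split stays across time-grid cells
#'
#' A stay overlapping several grid intervals (or a midnight weekday boundary)
#' is cut at every cell boundary and its duration distributed exactly among
#' the pieces: a stay from 04:00 to 05:30 on a 60-min grid yields 60 min in
#' interval (4--5] and 30 min in (5--6]. Piece minutes always sum to the
#' stay's duration.
#'
#' @param stays Data frame as returned by
#'   \code{\link{stays_from_observations}}.
#' @param delta_t Grid interval length in minutes (must divide 1440).
#' @return Data frame with columns \code{room}, \code{weekday} (1 = Sunday),
#'   \code{interval} (1-based index within the day), \code{minutes}, and the
#'   piece \code{start}/\code{end} times.
#' @export
split_stays <- function(stays, delta_t = 60) {
  delta_t <- .check_delta_t(delta_t)
  if (nrow(stays) == 0)
    return(data.frame(room = character(0), weekday = integer(0),
                      interval = integer(0), minutes = numeric(0)))
  m0 <- .epoch_min(stays$start)
  m1 <- .epoch_min(stays$end)
  if (any(m1 < m0)) stop("stay with end before start")
  c0 <- floor(m0 / delta_t)            # cell of the piece containing start
  c1 <- .cell_at(pmax(m1, m0 + .EPS), delta_t)
  np <- pmax(c1 - c0, 0) + 1
  idx <- rep(seq_len(nrow(stays)), np)
  g <- c0[idx] + (sequence(np) - 1)
  ps <- pmax(m0[idx], g * delta_t)
  pe <- pmin(m1[idx], (g + 1) * delta_t)
  data.frame(room = stays$room[idx],
             weekday = .cell_day(g, delta_t),
             interval = .cell_interval(g, delta_t),
             minutes = pe - ps,
             start = .as_utc(ps * 60),
             end = .as_utc(pe * 60),
             stringsAsFactors = FALSE)
}

#' Read a CASAS-format smart-home event log
#'
#' Parses the whitespace-separated text format of the CASAS Smart Home
#' Project datasets (date, time, sensor id, value, ...). Only PIR motion
#' sensors are kept (ids beginning with \code{"M"}) and only their
#' \code{"ON"} triggers, matching the trigger-on-motion semantics of PIR
#' hardware. Malformed lines are counted and skipped; motion sensors absent
#' from \code{sensor_map} are skipped with a warning.
#'
#' @param path Path to the text log.
#' @param sensor_map Named character vector, sensor id to room name.
#' @return Observation stream; attributes \code{n_malformed} and
#'   \code{n_unmapped} carry the skip counts.
#' @export
read_casas <- function(path, sensor_map) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  ok <- lengths(parts) >= 4
  n_malformed <- sum(!ok)
  parts <- parts[ok]
  if (!length(parts))
    stop("no parseable records in ", path)
  date <- vapply(parts, `[[`, "", 1)
  tod <- vapply(parts, `[[`, "", 2)
  sensor <- vapply(parts, `[[`, "", 3)
  value <- vapply(parts, `[[`, "", 4)
  keep <- startsWith(sensor, "M") & toupper(value) == "ON"
  time <- as.POSIXct(paste(date[keep], tod[keep]), tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS"))
  bad_time <- is.na(time)
  n_malformed <- n_malformed + sum(bad_time)
  sensor <- sensor[keep][!bad_time]
  time <- time[!bad_time]
  room <- unname(sensor_map[sensor])
  unmapped <- is.na(room)
  if (any(unmapped))
    warning(sum(unmapped), " motion observation(s) from unmapped sensors skipped")
  df <- data.frame(time = time[!unmapped], sensor = sensor[!unmapped],
                   room = room[!unmapped], stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_malformed") <- n_malformed
  attr(df, "n_unmapped") <- sum(unmapped)
  df
}
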