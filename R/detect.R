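#' Run the real-time anomaly detection pipeline over an event stream
#'
#' Samples the stream at a fixed period (default every minute), independently
#' of when observations arrive, and produces one output record per sample:
#' \describe{
#'   \item{estimator}{the detected room is the room of the most recent
#'     observation; its location likelihood \eqn{l_n} (the model's stay
#'     probability for that room in the current weekday/interval cell) is
#'     normalised by the cell's most probable room, smoothed with an
#'     unweighted moving average over \code{smoothing} minutes
#'     (\eqn{g_n}), and thresholded: \eqn{h_n = 1} iff \eqn{g_n <}
#'     \code{threshold}.}
#'   \item{automaton}{a three-state machine (Normal, PotentialAbnormal,
#'     Abnormal) with one timer filters transient flags. In Normal, abnormal
#'     samples increment the timer and a single normal sample resets it;
#'     exceeding \code{n1} enters PotentialAbnormal, where normal samples
#'     only decrement (no reset): the timer reaching \code{n2} confirms
#'     Abnormal, draining to zero returns to Normal. Abnormal is left after a
#'     sustained normal streak of \code{n1} minutes unless
#'     \code{latch_abnormal}.}
#'   \item{classifier}{confirmed deviations are mapped to OverSleeping,
#'     LessSleeping, NotBackHome or Dead using the model's activity and
#'     longest-stay dimensions (see \code{\link{classify_chain}}).}
#' }
#' No abnormality is emitted during the warm-up (the first full smoothing
#' window), while the filter state is undefined.
#'
#' @param model A fitted \code{\link{behaviour_model}}.
#' @param obs Observation stream to monitor; should include some history
#'   before \code{from} so the detected room and current stay are defined.
#' @param from,to Monitoring span (POSIXct); defaults to the span of
#'   \code{obs}.
#' @param threshold Abnormality threshold on the smoothed likelihood
#'   (default 0.25).
#' @param n1 Normal timeout in minutes (default 5): abnormal runs shorter
#'   than this never leave the Normal state.
#' @param n2 Abnormal timeout in minutes (default 10): timer value that
#'   confirms the Abnormal state.
#' @param sampling Sampling period in minutes (default 1).
#' @param smoothing Moving-average window in minutes (default 10).
#' @param classify Run the rule-based anomaly classifier (default TRUE).
#' @param latch_abnormal Hold the Abnormal state until the end of the run
#'   instead of auto-releasing (default FALSE).
#' @param bedroom,outside Names of the sleeping room and the virtual outside
#'   room in the layout.
#' @return A data frame of class \code{bms_detection} with one row per
#'   sample: \code{time}, \code{room}, \code{l}, \code{g}, \code{h},
#'   \code{state}, and (when classified) \code{label} plus the supporting
#'   evidence columns.
#' @export
detect <- function(model, obs, from = NULL, to = NULL, threshold = 0.25,
                   n1 = 5, n2 = 10, sampling = 1, smoothing = 10,
                   classify = TRUE, latch_abnormal = FALSE,
                   bedroom = "Bedroom", outside = "Outside") {
  if (is.null(from)) from <- min(obs$time)
  if (is.null(to)) to <- max(obs$time)
  from <- .as_utc(from); to <- .as_utc(to)
  n_samp <- floor(as.numeric(to - from, units = "mins") / sampling)
  if (n_samp < 1) stop("monitoring span shorter than one sampling period")
  times <- from + seq_len(n_samp) * sampling * 60

  obs_sec <- as.numeric(obs$time)
  idx <- findInterval(as.numeric(times), obs_sec)
  room <- ifelse(idx > 0, obs$room[pmax(idx, 1)], NA_character_)

  l <- predict(model, data.frame(time = times, room = room))
  ln <- predict(model, data.frame(time = times, room = room),
                normalise = TRUE)

  W <- max(1L, as.integer(round(smoothing / sampling)))
  g <- as.numeric(stats::filter(ln, rep(1 / W, W), sides = 1))
  if (W > 1) {
    head_n <- seq_len(min(W - 1, length(ln)))
    g[head_n] <- cumsum(ln)[head_n] / head_n
  }
  warmup <- seq_along(g) < W
  h <- as.integer(g < threshold & !warmup)

  st <- .automaton_run(h, sampling, n1, n2, latch_abnormal)

  chain <- data.frame(time = times, room = room, l = l, g = g, h = h,
                      state = st$state, stringsAsFactors = FALSE)
  chain$warmup <- warmup
  attr(chain, "params") <- list(threshold = threshold, n1 = n1, n2 = n2,
                                sampling = sampling, smoothing = smoothing)
  class(chain) <- c("bms_detection", "data.frame")
  if (classify)
    chain <- classify_chain(model, chain, obs, bedroom = bedroom,
                            outside = outside)
  chain
}

# three-state confirmation automaton; h is the per-sample binary abnormality,
# dt the sampling period in minutes
.automaton_run <- function(h, dt, n1, n2, latch = FALSE) {
  n <- length(h)
  state <- integer(n)
  s <- 1L           # 1 Normal, 2 PotentialAbnormal, 3 Abnormal
  timer <- 0
  streak <- 0       # normal streak inside Abnormal
  for (k in seq_len(n)) {
    if (s == 1L) {
      timer <- if (h[k]) timer + dt else 0
      if (timer > n1) s <- 2L
    } else if (s == 2L) {
      timer <- timer + if (h[k]) dt else -dt
      if (timer >= n2) {
        s <- 3L
        streak <- 0
      } else if (timer <= 0) {
        s <- 1L
        timer <- 0
      }
    } else {
      if (h[k]) {
        streak <- 0
        timer <- timer + dt
      } else {
        streak <- streak + dt
      }
      if (!latch && streak >= n1) {
        s <- 1L
        timer <- 0
        streak <- 0
      }
    }
    state[k] <- s
  }
  list(state = factor(c("Normal", "PotentialAbnormal", "Abnormal")[state],
                      levels = c("Normal", "PotentialAbnormal", "Abnormal")))
}

#' Single step of the confirmation automaton
#'
#' Exposed mainly for inspection and testing; \code{\link{detect}} runs the
#' same transition rules over a whole sample chain.
#'
#' @param state One of \code{"Normal"}, \code{"PotentialAbnormal"},
#'   \code{"Abnormal"}.
#' @param timer Current timer value (minutes).
#' @param h Binary abnormality sample (0/1).
#' @param dt Sampling period in minutes.
#' @param n1,n2 Normal and abnormal timeouts (minutes).
#' @param streak Normal streak inside the Abnormal state (minutes).
#' @param latch_abnormal Hold Abnormal until acknowledged.
#' @return List with updated \code{state}, \code{timer}, \code{streak}.
#' @export
automaton_step <- function(state, timer, h, dt = 1, n1 = 5, n2 = 10,
                           streak = 0, latch_abnormal = FALSE) {
  if (state == "Normal") {
    timer <- if (h) timer + dt else 0
    if (timer > n1) state <- "PotentialAbnormal"
  } else if (state == "PotentialAbnormal") {
    timer <- timer + if (h) dt else -dt
    if (timer >= n2) {
      state <- "Abnormal"
      streak <- 0
    } else if (timer <= 0) {
      state <- "Normal"
      timer <- 0
    }
  } else {
    if (h) {
      streak <- 0
      timer <- timer + dt
    } else streak <- streak + dt
    if (!latch_abnormal && streak >= n1) {
      state <- "Normal"
      timer <- 0
      streak <- 0
    }
  }
  list(state = state, timer = timer, streak = streak)
}

#' Normalise a location likelihood by the cell maximum
#'
#' @param l Raw location likelihood.
#' @param cell_probs Self-transition probabilities of all rooms in the cell.
#' @return \code{l / max(cell_probs)} clipped to [0, 1]; 0 for an unmodelled
#'   (all-zero) cell.
#' @export
normalise_likelihood <- function(l, cell_probs) {
  mx <- max(cell_probs)
  if (mx <= 0) return(0)
  min(l / mx, 1)
}

#' @export
print.bms_detection <- function(x, ...) {
  p <- attr(x, "params")
  cat("Detection chain:", nrow(x), "samples,",
      format(min(x$time), "%Y-%m-%d %H:%M"), "to",
      format(max(x$time), "%Y-%m-%d %H:%M"), "\n")
  cat(sprintf("  threshold %.2f, N1 %g min, N2 %g min, sampling %g min, smoothing %g min\n",
              p$threshold, p$n1, p$n2, p$sampling, p$smoothing))
  cat("  abnormal samples (h):", sum(x$h), "  automaton:",
      paste(names(table(x$state)), table(x$state), collapse = ", "), "\n")
  if (!is.null(x$label)) {
    tl <- table(x$label[x$label != "Normal"])
    if (length(tl)) cat("  labels:", paste(names(tl), tl, collapse = ", "),
                        "\n")
  }
  invisible(x)
}
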