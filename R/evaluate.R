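## Evaluation metrics: detection delay, confirmation time, weekly false
## positives and per-class accuracy, each computable at the estimator,
## automaton or classifier level of a detection chain.

# per-sample abnormality flags of a chain at a given level;
# for the classifier, `kind` restricts to one anomaly class
.level_flags <- function(chain, level = c("estimator", "automaton",
                                          "classifier"), kind = NULL) {
  level <- match.arg(level)
  switch(level,
         estimator = chain$h == 1,
         automaton = chain$state == "Abnormal",
         classifier = if (is.null(kind)) chain$label != "Normal"
                      else chain$label == kind)
}

#' Anomaly detection delay (ADD)
#'
#' Minutes from the anomaly onset to the first sample flagging it at the
#' requested level: first \eqn{h_n = 1} sample (estimator), first entry into
#' the Abnormal state (automaton), or first sample carrying the injected
#' class label (classifier). \code{NA} when the anomaly is never flagged
#' inside its window (a miss).
#'
#' @param chain A \code{bms_detection} chain covering the anomaly window.
#' @param truth Ground-truth record (list with \code{kind}, \code{start},
#'   \code{end}), as produced by \code{\link{inject_anomaly}}.
#' @param level \code{"estimator"}, \code{"automaton"} or
#'   \code{"classifier"}.
#' @return Delay in minutes, or \code{NA}.
#' @export
anomaly_detection_delay <- function(chain, truth,
                                    level = c("classifier", "estimator",
                                              "automaton")) {
  level <- match.arg(level)
  flags <- .level_flags(chain, level,
                        if (level == "classifier") truth$kind)
  inw <- chain$time > truth$start & chain$time <= truth$end
  hit <- which(flags & inw)
  if (!length(hit)) return(NA_real_)
  as.numeric(chain$time[hit[1]] - truth$start, units = "mins")
}

#' Anomaly confirmation time (ACT)
#'
#' Total time within the anomaly window during which the level reports the
#' abnormal condition — the duration for which a caregiver alarm would have
#' been sustained. Bounded above by the window length.
#'
#' @inheritParams anomaly_detection_delay
#' @return Hours of confirmed abnormality.
#' @export
anomaly_confirmation_time <- function(chain, truth,
                                      level = c("classifier", "estimator",
                                                "automaton")) {
  level <- match.arg(level)
  flags <- .level_flags(chain, level,
                        if (level == "classifier") truth$kind)
  inw <- chain$time > truth$start & chain$time <= truth$end
  sampling <- attr(chain, "params")$sampling
  sum(flags & inw) * sampling / 60
}

#' Average weekly false-positive alerts (FP)
#'
#' Counts alert episodes on a chain that should be anomaly-free and averages
#' them per week. One episode is a maximal run of \eqn{h_n = 1} samples
#' (estimator), one entry into the Abnormal state (automaton), or a maximal
#' run of non-Normal labels (classifier).
#'
#' @param chain A \code{bms_detection} chain over anomaly-free data.
#' @param level Evaluation level.
#' @param weeks Number of weeks the chain spans; by default its time span.
#' @return Alert episodes per week.
#' @export
weekly_false_positives <- function(chain,
                                   level = c("classifier", "estimator",
                                             "automaton"),
                                   weeks = NULL) {
  level <- match.arg(level)
  if (is.null(weeks)) {
    sampling <- attr(chain, "params")$sampling
    weeks <- (nrow(chain) * sampling) / (7 * 1440)
  }
  if (level == "automaton") {
    ab <- chain$state == "Abnormal"
    episodes <- sum(ab & !c(FALSE, ab[-length(ab)]))
  } else {
    f <- .level_flags(chain, level)
    r <- rle(as.vector(f))
    episodes <- sum(r$values)
  }
  episodes / weeks
}

#' Per-class classification accuracy
#'
#' Fraction (percent) of detection samples inside the injected anomaly
#' window whose classifier label equals the injected kind.
#'
#' @inheritParams anomaly_detection_delay
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(chain, truth) {
  inw <- chain$time > truth$start & chain$time <= truth$end
  if (!any(inw)) return(NA_real_)
  100 * mean(chain$label[inw] == truth$kind)
}

#' Run a full simulate-learn-inject-detect-score experiment
#'
#' Generates a synthetic profile stream, trains the behaviour model on the
#' four weeks preceding the anomaly week, injects one anomaly, runs
#' detection over the anomaly day and scores it at the three levels. The
#' defaults mirror the standard run configuration: 4-week learning window
#' shifted weekly, 1-min sampling, 10-min smoothing, timeouts 5 and 10 min.
#'
#' @param profile \code{"A"} or \code{"B"}.
#' @param kind Anomaly class to inject.
#' @param seed RNG seed (drives generation and injection).
#' @param weeks Simulated weeks (default 12).
#' @param inject_week Week (1-based) whose Wednesday receives the anomaly
#'   (default 6; must leave at least 4 full prior weeks for training).
#' @param threshold,n1,n2,sampling,smoothing Detection parameters, see
#'   \code{\link{detect}}.
#' @param window_weeks Learning window length in weeks (default 4).
#' @return List with the fitted \code{model}, the \code{chain}, the
#'   \code{truth} record and a \code{metrics} data frame (one row per level:
#'   ADD minutes, ACT hours, accuracy percent).
#' @export
run_experiment <- function(profile = "A", kind = "LessSleeping", seed = 1,
                           weeks = 12, inject_week = 6, threshold = 0.25,
                           n1 = 5, n2 = 10, sampling = 1, smoothing = 10,
                           window_weeks = 4) {
  if (inject_week <= window_weeks)
    stop("inject_week must leave ", window_weeks,
         " full weeks for training")
  spec <- profile_spec(profile, weeks = weeks)
  ev <- simulate_profile(spec, seed = seed)
  start <- attr(ev, "start")
  day <- as.Date(start) + (inject_week - 1) * 7 + 3   # a Wednesday
  inj <- inject_anomaly(ev, kind, day, seed = seed + 1000L)
  train_start <- start + (inject_week - 1 - window_weeks) * 7 * 86400
  model <- behaviour_model(inj$events, attr(ev, "layout"),
                           window_start = train_start,
                           window_weeks = window_weeks)
  day0 <- .as_utc(paste(day, "00:00:00"))
  chain <- detect(model, inj$events, from = day0 - 3600,
                  to = day0 + 86400, threshold = threshold, n1 = n1,
                  n2 = n2, sampling = sampling, smoothing = smoothing)
  metrics <- do.call(rbind, lapply(
    c("estimator", "automaton", "classifier"), function(lv)
      data.frame(level = lv,
                 add_minutes = anomaly_detection_delay(chain, inj$truth,
                                                       lv),
                 act_hours = anomaly_confirmation_time(chain, inj$truth,
                                                       lv),
                 accuracy = if (lv == "classifier")
                   classification_accuracy(chain, inj$truth)
                 else NA_real_)))
  list(model = model, chain = chain, truth = inj$truth, metrics = metrics)
}

#' False-positive experiment over anomaly-free weeks
#'
#' Trains on the first \code{window_weeks} weeks of a clean synthetic
#' stream, then monitors the following weeks with the model re-fitted
#' weekly over its sliding window, and counts alert episodes per week at
#' each level.
#'
#' @inheritParams run_experiment
#' @param monitor_weeks How many post-training weeks to monitor (default:
#'   all remaining).
#' @return Data frame with one row per level and the weekly false-positive
#'   rate.
#' @export
fp_experiment <- function(profile = "B", seed = 1, weeks = 12,
                          window_weeks = 4, monitor_weeks = NULL,
                          threshold = 0.25, n1 = 5, n2 = 10, sampling = 1,
                          smoothing = 10) {
  spec <- profile_spec(profile, weeks = weeks)
  ev <- simulate_profile(spec, seed = seed)
  start <- attr(ev, "start")
  if (is.null(monitor_weeks)) monitor_weeks <- weeks - window_weeks
  model <- behaviour_model(ev, attr(ev, "layout"), window_start = start,
                           window_weeks = window_weeks)
  chains <- vector("list", monitor_weeks)
  for (w in seq_len(monitor_weeks)) {
    w0 <- start + (window_weeks + w - 1) * 7 * 86400
    chains[[w]] <- detect(model, ev, from = w0 - 3600,
                          to = w0 + 7 * 86400, threshold = threshold,
                          n1 = n1, n2 = n2, sampling = sampling,
                          smoothing = smoothing)
    if (w < monitor_weeks) model <- update(model, ev)
  }
  params <- attr(chains[[1]], "params")
  chain <- do.call(rbind, chains)
  attr(chain, "params") <- params
  class(chain) <- c("bms_detection", "data.frame")
  do.call(rbind, lapply(
    c("estimator", "automaton", "classifier"), function(lv)
      data.frame(level = lv,
                 fp_weekly = weekly_false_positives(chain, lv,
                                                    weeks = monitor_weeks))))
}
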