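# Real-time orchestration: the escalating fall-alarm state machine, the
# frame-loop monitor driving it from classifier observations, and the
# rehabilitation session driver.

ALARM_STAGES <- c("Normal", "Abnormal", "Urgent", "Emergency")

#' Monitor configuration
#'
#' @param safety_time Seconds a fallen subject may stay down before the
#'   episode escalates from Abnormal to Urgent (default 10; standing up within
#'   this window discards the episode).
#' @param urgent_grace Additional seconds in Urgent before the alarm fires and
#'   the stage latches at Emergency (default 5).
#' @param frame_rate Expected stream frame rate in Hz.
#' @return Object of class `monitor_config`.
#' @export
monitor_config <- function(safety_time = 10, urgent_grace = 5, frame_rate = 30) {
  stopifnot(safety_time > 0, urgent_grace > 0, frame_rate > 0)
  structure(list(safety_time = safety_time, urgent_grace = urgent_grace,
                 frame_rate = frame_rate), class = "monitor_config")
}

#' Fresh monitor state
#'
#' @return Object of class `monitor_state`: stage `Normal`, no fall timer, no
#'   active alarm.
#' @export
monitor_state <- function() {
  structure(list(stage = "Normal", fall_start = NA_real_, alarm_active = FALSE,
                 last_t = -Inf),
            class = "monitor_state")
}

alarm_event <- function(kind, timestamp, from_stage, to_stage) {
  data.frame(kind = kind, timestamp = timestamp,
             from_stage = from_stage, to_stage = to_stage,
             stringsAsFactors = FALSE)
}

no_events <- function() {
  data.frame(kind = character(), timestamp = numeric(),
             from_stage = character(), to_stage = character(),
             stringsAsFactors = FALSE)
}

#' Step the fall-alarm state machine
#'
#' One observation drives the four-stage escalation: a fall observed in
#' `Normal` starts the episode timer (`Abnormal`); standing up while
#' `Abnormal` or `Urgent` discards the episode; staying down longer than
#' `safety_time` escalates to `Urgent`, and longer than
#' `safety_time + urgent_grace` fires the alarm and latches `Emergency`,
#' which ignores every observation until [manual_reset()]. `no-observation`
#' frames leave the episode timer running.
#'
#' @param state A `monitor_state`.
#' @param observation One of `"fall"`, `"no_fall"`, `"stand_up"`,
#'   `"no-observation"`.
#' @param t Observation timestamp in seconds (must not run backwards).
#' @param config A [monitor_config()].
#' @return List with the new `state` and a data frame of `events`.
#' @export
step_fall_monitor <- function(state, observation, t, config = monitor_config()) {
  stopifnot(inherits(state, "monitor_state"))
  observation <- match.arg(observation, c("fall", "no_fall", "stand_up", "no-observation"))
  if (t < state$last_t)
    stop_skel(sprintf("time running backwards: %.3f after %.3f", t, state$last_t),
              "time_monotonicity")
  state$last_t <- t
  events <- no_events()
  emit <- function(kind, from, to) events <<- rbind(events, alarm_event(kind, t, from, to))
  if (state$stage == "Emergency") return(list(state = state, events = events))

  if (observation == "stand_up" && state$stage %in% c("Abnormal", "Urgent")) {
    emit("alarm_discarded", state$stage, "Normal")
    emit("stage_change", state$stage, "Normal")
    state$stage <- "Normal"; state$fall_start <- NA_real_
    return(list(state = state, events = events))
  }
  if (observation == "fall" && state$stage == "Normal") {
    emit("stage_change", "Normal", "Abnormal")
    state$stage <- "Abnormal"; state$fall_start <- t
  }
  # time-driven escalation (one episode timer; continuous falls do not restart it)
  if (state$stage == "Abnormal" && (t - state$fall_start) > config$safety_time) {
    emit("stage_change", "Abnormal", "Urgent")
    state$stage <- "Urgent"
  }
  if (state$stage == "Urgent" &&
      (t - state$fall_start) > config$safety_time + config$urgent_grace) {
    emit("stage_change", "Urgent", "Emergency")
    emit("alarm_started", "Urgent", "Emergency")
    state$stage <- "Emergency"; state$alarm_active <- TRUE
  }
  list(state = state, events = events)
}

#' Manually reset an emergency
#'
#' Only an authorized manual action clears a latched Emergency. Outside
#' Emergency this is a no-op that emits a warning event.
#'
#' @param state A `monitor_state`.
#' @param t Timestamp of the reset.
#' @return List with the new `state` and `events`.
#' @export
manual_reset <- function(state, t = state$last_t) {
  stopifnot(inherits(state, "monitor_state"))
  if (state$stage != "Emergency") {
    return(list(state = state,
                events = alarm_event("reset_ignored", t, state$stage, state$stage)))
  }
  ev <- rbind(alarm_event("reset", t, "Emergency", "Normal"),
              alarm_event("stage_change", t, "Emergency", "Normal"))
  state$stage <- "Normal"; state$fall_start <- NA_real_; state$alarm_active <- FALSE
  list(state = state, events = ev)
}

# Precompute per-frame observations for a stream: fall/no_fall from sliding
# head windows (the window buffer resets whenever the head is lost), stand_up
# from the lower-body classifier debounced over `stand_hold` seconds plus a
# head-height recovery test.
stream_observations <- function(stream, fall_bundle, lower_bundle, calibration,
                                config, stand_hold = 0.5) {
  n <- length(stream)
  obs <- rep("no-observation", n)
  if (n == 0L) return(obs)
  W <- fall_bundle$window
  head_ok <- vapply(stream, function(f) f$detected[["head"]], logical(1L))
  head_xyz <- t(vapply(stream, function(f) {
    p <- f$positions["head", ]; if (anyNA(p)) c(0, 0, 0) else p
  }, numeric(3L)))
  ts <- vapply(stream, `[[`, numeric(1L), "timestamp")

  # head windows over runs of consecutive detections
  run_id <- cumsum(!head_ok)
  full <- logical(n)
  feats <- NULL; rows <- integer()
  for (i in seq_len(n)) {
    if (!head_ok[i] || i < W) next
    if (all(head_ok[(i - W + 1L):i])) { full[i] <- TRUE; rows <- c(rows, i) }
  }
  if (length(rows)) {
    feats <- t(vapply(rows, function(i)
      fall_window_features(head_xyz[(i - W + 1L):i, , drop = FALSE], calibration),
      numeric(3L * W)))
    lab <- predict(fall_bundle$mlp, feats,
                   threshold = fall_bundle$confidence_threshold,
                   margin = fall_bundle$margin)
    lab[lab == "none"] <- "no_fall"   # an uncertain window is not a fall
    obs[rows] <- lab
  }

  if (!is.null(lower_bundle)) {
    js <- lower_bundle$joint_set
    lower_ok <- vapply(stream, function(f)
      all(f$detected[js]) && all(f$detected[c("left_hip", "right_hip")]), logical(1L))
    standing <- logical(n)
    idx <- which(lower_ok)
    if (length(idx)) {
      lx <- t(vapply(idx, function(i)
        as.numeric(extract_features(stream[[i]], js, calibration)),
        numeric(3L * length(js))))
      lab <- predict(lower_bundle$mlp, lx,
                     threshold = lower_bundle$confidence_threshold,
                     margin = lower_bundle$margin)
      standing[idx] <- lab == "standing"
    }
    # head-height recovery: within 20% of the standing head level
    recovered <- head_ok &
      head_xyz[, 2L] >= calibration$standing_head_y - 0.2 * calibration$height
    up <- standing & recovered
    # require `up` sustained for stand_hold seconds
    hold_n <- max(1L, ceiling(stand_hold * config$frame_rate))
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (up[i]) run + 1L else 0L
      if (run >= hold_n) obs[i] <- "stand_up"
    }
  }
  obs
}

#' Run the fall monitor over a frame stream
#'
#' Per frame, the fall bundle classifies the most recent window of
#' consecutive head positions (frames with the head out of view leave the
#' episode timer running), a stand-up observation is derived from the
#' lower-body classifier reporting standing together with the head recovering
#' to within 20% of its standing level for at least half a second, and the
#' observation drives [step_fall_monitor()].
#'
#' @param stream List of [skel_frame()]s sorted by time.
#' @param fall_bundle Fall `classifier_bundle`.
#' @param lower_bundle Optional lower-body `classifier_bundle` (enables
#'   stand-up discards).
#' @param calibration A [skel_calibration()].
#' @param config A [monitor_config()].
#' @param on_alarm Optional function called with each `alarm_started` event row.
#' @return Data frame of alarm events (possibly empty), in timestamp order.
#' @export
run_monitor <- function(stream, fall_bundle, lower_bundle = NULL, calibration,
                        config = monitor_config(), on_alarm = NULL) {
  if (length(stream) == 0L) return(no_events())
  obs <- stream_observations(stream, fall_bundle, lower_bundle, calibration, config)
  state <- monitor_state()
  events <- list()
  for (i in seq_along(stream)) {
    st <- step_fall_monitor(state, obs[i], stream[[i]]$timestamp, config)
    state <- st$state
    if (nrow(st$events)) {
      events[[length(events) + 1L]] <- st$events
      if (!is.null(on_alarm)) {
        started <- st$events[st$events$kind == "alarm_started", , drop = FALSE]
        if (nrow(started)) for (r in seq_len(nrow(started))) on_alarm(started[r, ])
      }
    }
  }
  if (length(events)) do.call(rbind, events) else no_events()
}

#' Rehabilitation plan
#'
#' @param postures Ordered target postures for the session.
#' @param max_train Maximum attempts per posture (default 3).
#' @return Object of class `rehab_plan`.
#' @export
rehab_plan <- function(postures, max_train = 3L) {
  if (length(postures) == 0L) stop_skel("empty rehabilitation plan", "bad_plan")
  structure(list(postures = postures, max_train = as.integer(max_train)),
            class = "rehab_plan")
}

#' Run a rehabilitation session
#'
#' Walks the plan in order. An attempt is one evaluation window
#' (`attempt_window` seconds of stream); it succeeds when at least
#' `success_frac` of its classifiable frames report the target posture. A
#' posture is abandoned after `max_train` failed attempts; if the stream runs
#' out, the remaining postures are marked not attempted.
#'
#' @param stream List of [skel_frame()]s.
#' @param plan A [rehab_plan()].
#' @param upper_bundle Upper-body posture `classifier_bundle`.
#' @param calibration A [skel_calibration()].
#' @param attempt_window Seconds per attempt (default 2).
#' @param success_frac Fraction of frames that must match (default 0.7).
#' @return Object of class `session_report`: per-posture attempts, achieved
#'   flag, attempt timestamps, plus the emitted try-again prompts.
#' @export
run_rehab_session <- function(stream, plan, upper_bundle, calibration,
                              attempt_window = 2, success_frac = 0.7) {
  stopifnot(inherits(plan, "rehab_plan"))
  if (length(stream) == 0L) stop_skel("empty stream", "bad_inputs")
  ts <- vapply(stream, `[[`, numeric(1L), "timestamp")
  labels <- vapply(stream, function(f) {
    tryCatch(classify_frame(upper_bundle, f, calibration),
             skelwatch_joint_missing = function(e) "no-observation")
  }, character(1L))
  fr_dt <- if (length(ts) > 1L) stats::median(diff(ts)) else 1 / 30
  win_n <- max(1L, round(attempt_window / fr_dt))
  pos <- 1L
  prompts <- list()
  rows <- lapply(plan$postures, function(target) {
    attempts <- 0L; achieved <- FALSE; t_start <- NA_real_; t_end <- NA_real_
    while (attempts < plan$max_train && pos <= length(labels)) {
      j <- min(pos + win_n - 1L, length(labels))
      if (j - pos + 1L < win_n %/% 2L) { pos <<- length(labels) + 1L; break }
      attempts <- attempts + 1L
      if (is.na(t_start)) t_start <- ts[pos]
      seg <- labels[pos:j]
      ok <- seg == target
      achieved <- mean(ok) >= success_frac
      t_end <- ts[j]
      pos <<- j + 1L
      if (achieved) break
      if (attempts < plan$max_train)
        prompts[[length(prompts) + 1L]] <<- list(posture = target, time = ts[min(j, length(ts))])
    }
    data.frame(posture = target, attempts = attempts, achieved = achieved,
               attempted = attempts > 0L, t_start = t_start, t_end = t_end,
               stringsAsFactors = FALSE)
  })
  structure(list(postures = do.call(rbind, rows), prompts = prompts,
                 max_train = plan$max_train),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report: %d/%d postures achieved>\n",
              sum(x$postures$achieved), nrow(x$postures)))
  print(x$postures)
  invisible(x)
}
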