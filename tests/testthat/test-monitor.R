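cfg5 <- monitor_config(safety_time = 5, urgent_grace = 5)

advance <- function(state, obs, t, cfg = cfg5) step_fall_monitor(state, obs, t, cfg)

test_that("the full stage/observation transition table is as specified", {
  # build a state in each stage, then check every observation
  in_stage <- function(stage) {
    s <- monitor_state()
    if (stage == "Normal") return(s)
    s <- advance(s, "fall", 0)$state                       # Abnormal
    if (stage == "Abnormal") return(s)
    s <- advance(s, "no_fall", 5.5)$state                  # Urgent
    if (stage == "Urgent") return(s)
    advance(s, "no_fall", 10.5)$state                      # Emergency
  }
  expected <- list(
    Normal    = c(fall = "Abnormal", no_fall = "Normal", stand_up = "Normal",
                  `no-observation` = "Normal"),
    Abnormal  = c(fall = "Abnormal", no_fall = "Abnormal", stand_up = "Normal",
                  `no-observation` = "Abnormal"),
    Urgent    = c(fall = "Urgent", no_fall = "Urgent", stand_up = "Normal",
                  `no-observation` = "Urgent"),
    Emergency = c(fall = "Emergency", no_fall = "Emergency", stand_up = "Emergency",
                  `no-observation` = "Emergency")
  )
  for (stage in names(expected)) {
    for (obs in names(expected[[stage]])) {
      s <- in_stage(stage)
      # advance by a hair so no additional time threshold is crossed
      t_next <- if (is.finite(s$last_t)) s$last_t + 1e-4 else 0
      nxt <- advance(s, obs, t_next)$state
      expect_equal(nxt$stage, unname(expected[[stage]][obs]),
                   label = sprintf("%s + %s", stage, obs))
    }
  }
})

test_that("standing up within the safety time discards the episode silently", {
  s <- monitor_state()
  s <- advance(s, "fall", 0)$state
  st <- advance(s, "stand_up", 2)
  expect_equal(st$state$stage, "Normal")
  expect_true("alarm_discarded" %in% st$events$kind)
  expect_false(st$state$alarm_active)
  expect_false("alarm_started" %in% st$events$kind)
})

test_that("a persistent fall escalates on schedule and fires one alarm", {
  s <- monitor_state()
  ev <- list()
  for (t in seq(0, 12, by = 0.5)) {
    st <- advance(s, if (t == 0) "fall" else "no_fall", t)
    s <- st$state
    if (nrow(st$events)) ev[[length(ev) + 1L]] <- st$events
  }
  ev <- do.call(rbind, ev)
  expect_equal(s$stage, "Emergency")
  expect_true(s$alarm_active)
  started <- ev[ev$kind == "alarm_started", ]
  expect_equal(nrow(started), 1L)
  expect_equal(started$timestamp, 10.5)  # first step past safety + grace
  urg <- ev[ev$kind == "stage_change" & ev$to_stage == "Urgent", ]
  expect_equal(urg$timestamp, 5.5)
  # timer does not restart on continued falls
  s2 <- monitor_state()
  s2 <- advance(s2, "fall", 0)$state
  s2 <- advance(s2, "fall", 3)$state
  expect_equal(s2$fall_start, 0)
})

test_that("Emergency latches until a manual reset clears it", {
  s <- monitor_state()
  s <- advance(s, "fall", 0)$state
  s <- advance(s, "no_fall", 5.5)$state
  s <- advance(s, "no_fall", 10.5)$state
  expect_equal(s$stage, "Emergency")
  s2 <- advance(s, "stand_up", 11)$state
  expect_equal(s2$stage, "Emergency")

  rr <- manual_reset(s2, 12)
  expect_equal(rr$state$stage, "Normal")
  expect_true("reset" %in% rr$events$kind)
  # fresh cycle afterwards
  s3 <- advance(rr$state, "fall", 13)$state
  expect_equal(s3$stage, "Abnormal")
  expect_equal(s3$fall_start, 13)

  # reset outside Emergency is a warned no-op
  nr <- manual_reset(monitor_state(), 0)
  expect_equal(nr$state$stage, "Normal")
  expect_equal(nr$events$kind, "reset_ignored")
})

test_that("time running backwards raises a monotonicity error", {
  s <- monitor_state()
  s <- advance(s, "fall", 5)$state
  expect_error(advance(s, "no_fall", 4), class = "skelwatch_time_monotonicity")
})

test_that("a scripted fall raises exactly one alarm and a quick sit raises none", {
  fb <- small_fall_bundle()
  cam <- skelwatch:::fall_watch_camera(2.5)
  subj <- subject_model(1.7)
  cal <- skelwatch:::calibration_for(subj, cam)

  fall_stream <- render_script(subj,
    motion_script(script_hold("standing", 1), script_fall(0.6, 18)),
    cam, jitter_sigma = 0.02, seed = 31)
  ev <- run_monitor(fall_stream, fb, calibration = cal)
  expect_equal(sum(ev$kind == "alarm_started"), 1L)
  # events in time order, alarm after safety + grace of continuous fall
  expect_true(all(diff(ev$timestamp) >= 0))
  first_fall <- min(ev$timestamp[ev$to_stage == "Abnormal"])
  alarm_t <- ev$timestamp[ev$kind == "alarm_started"]
  expect_gt(alarm_t - first_fall, 15)
  expect_lt(alarm_t - first_fall, 15 + 3 / 30)

  sit_stream <- render_script(subj,
    motion_script(script_hold("standing", 1), script_quick_sit(18)),
    cam, jitter_sigma = 0.02, seed = 32)
  ev2 <- run_monitor(sit_stream, fb, calibration = cal)
  expect_equal(sum(ev2$kind == "alarm_started"), 0L)

  expect_equal(nrow(run_monitor(list(), fb, calibration = cal)), 0L)
})

test_that("standing back up mid-episode discards instead of alarming", {
  fb <- small_fall_bundle()
  lb <- small_lower_bundle()
  cam <- camera_model(distance = 2.5)   # full-visibility mount for the lower body
  subj <- subject_model(1.7)
  cal <- skelwatch:::calibration_for(subj, cam)
  stream <- render_script(subj,
    motion_script(script_hold("standing", 1), script_fall(0.6, 4),
                  script_stand_up(1), script_hold("standing", 14)),
    cam, jitter_sigma = 0.02, seed = 33)
  ev <- run_monitor(stream, fb, lower_bundle = lb, calibration = cal)
  expect_equal(sum(ev$kind == "alarm_started"), 0L)
  expect_true("alarm_discarded" %in% ev$kind)
})

test_that("monitor runs are deterministic for identical inputs", {
  fb <- small_fall_bundle()
  cam <- skelwatch:::fall_watch_camera(3)
  subj <- subject_model(1.6)
  cal <- skelwatch:::calibration_for(subj, cam)
  stream <- render_script(subj,
    motion_script(script_hold("standing", 1), script_fall(0.8, 17)),
    cam, jitter_sigma = 0.02, seed = 34)
  e1 <- run_monitor(stream, fb, calibration = cal)
  e2 <- run_monitor(stream, fb, calibration = cal)
  expect_identical(e1, e2)
})

test_that("rehab sessions walk the plan, bound attempts and survive exhaustion", {
  ub <- small_upper_bundle()
  cam <- camera_model()
  subj <- subject_model(1.7)
  cal <- skelwatch:::calibration_for(subj, cam)
  plan <- rehab_plan(c("both_arms_raised", "arms_outstretched"), max_train = 3)
  stream <- render_script(subj,
    motion_script(script_hold("both_arms_raised", 2.2),
                  script_hold("arms_outstretched", 2.6)),
    cam, jitter_sigma = 0.01, seed = 41)
  rep <- run_rehab_session(stream, plan, ub, cal)
  expect_true(all(rep$postures$achieved))
  expect_true(all(rep$postures$attempts <= 2))

  # posture never shown: attempts exhausted, not achieved
  stream2 <- render_script(subj, motion_script(script_hold("both_arms_down", 16)),
                           cam, jitter_sigma = 0.01, seed = 42)
  rep2 <- run_rehab_session(stream2, rehab_plan("both_arms_raised", max_train = 3),
                            ub, cal)
  expect_false(rep2$postures$achieved[1])
  expect_equal(rep2$postures$attempts[1], 3L)

  # stream exhausted mid-plan leaves the tail not attempted
  short <- render_script(subj, motion_script(script_hold("both_arms_raised", 2.2)),
                         cam, jitter_sigma = 0.01, seed = 43)
  rep3 <- run_rehab_session(short,
                            rehab_plan(c("both_arms_raised", "arms_outstretched")),
                            ub, cal)
  expect_false(rep3$postures$attempted[2])

  expect_error(rehab_plan(character()), class = "skelwatch_bad_plan")
})
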