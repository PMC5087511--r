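# Evaluation harness: detection-rate bookkeeping over positive and negative
# trial pools, and the four seeded study sweeps (hidden neurons, training-set
# size, camera distance, camera angles).
#
# Rate convention: true positives are counted over the positive trials and
# true negatives over the negative trials, so FP = 100 - TP and
# FN = 100 - TN by construction. A trial is one rendered situation (a posture
# hold or one scripted event), not one frame.

#' Detection rates over positive and negative trials
#'
#' @param truth Character vector of true trial labels; negative trials carry
#'   `negative_label`.
#' @param predicted Predicted labels in the same space (`negative_label` or
#'   `"none"` meaning "nothing detected").
#' @param negative_label Label marking negative trials (default `"none"`).
#' @return Object of class `eval_report`: `tp_pct`, `tn_pct`, `fp_pct`,
#'   `fn_pct`, `n_positive_trials`, `n_negative_trials`.
#' @examples
#' confusion_rates(truth = c(rep("fall", 20), rep("none", 20)),
#'                 predicted = c(rep("fall", 19), "none", rep("none", 20)))
#' @export
confusion_rates <- function(truth, predicted, negative_label = "none") {
  stopifnot(length(truth) == length(predicted))
  pos <- truth != negative_label
  if (!any(pos) || all(pos))
    stop_skel("rates undefined: need at least one positive and one negative trial",
              "undefined_rate")
  tp <- 100 * mean(predicted[pos] == truth[pos])
  tn <- 100 * mean(predicted[!pos] == negative_label)
  structure(list(tp_pct = tp, tn_pct = tn, fp_pct = 100 - tp, fn_pct = 100 - tn,
                 n_positive_trials = sum(pos), n_negative_trials = sum(!pos)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %.1f%%  FP %.1f%%  TN %.1f%%  FN %.1f%%  (%d positive, %d negative trials)\n",
              x$tp_pct, x$fp_pct, x$tn_pct, x$fn_pct,
              x$n_positive_trials, x$n_negative_trials))
  invisible(x)
}

#' Train and evaluate the posture classifiers under one condition
#'
#' Generates fresh training/test posture sets and distractor frames, trains
#' the upper- and lower-body classifiers, and reports the detection rates on
#' held-out positives (TP) and distractor rejections (TN). This is the unit
#' of work all posture sweeps repeat per level and seed.
#'
#' @param n_train Named vector `c(upper=, lower=)` of training instances.
#' @param n_test Held-out positive frames per body half.
#' @param n_distract Distractor frames per body half (0 skips TN).
#' @param hidden Named vector `c(upper=, lower=)` of hidden neurons.
#' @param subjects,camera,jitter_sigma Generator settings.
#' @param seed Integer seed for the whole condition.
#' @param transfer,max_epochs,... Passed to the trainer.
#' @return Data frame with one row per body half: `tp_pct`, `tn_pct`,
#'   `converged`.
#' @export
evaluate_posture_classifiers <- function(n_train = c(upper = 632L, lower = 735L),
                                   n_test = 500L, n_distract = 500L,
                                   hidden = c(upper = 12L, lower = 10L),
                                   subjects = subject_pool(),
                                   camera = camera_model(),
                                   jitter_sigma = 0.02, seed = 1L,
                                   transfer = "sigmoid",
                                   max_epochs = 20000L, ...) {
  res <- lapply(c("upper", "lower"), function(body) {
    classes <- if (body == "upper") upper_postures() else lower_postures()
    tr <- generate_dataset(classes, n_train[[body]], subjects, camera,
                           jitter_sigma, seed = next_child_seed(seed, 1))
    te <- generate_dataset(classes, n_test, subjects, camera,
                           jitter_sigma, seed = next_child_seed(seed, 2))
    builder <- if (body == "upper") build_upper_classifier else build_lower_classifier
    bundle <- tryCatch(
      builder(tr, n_hidden = hidden[[body]], seed = next_child_seed(seed, 3),
              transfer = transfer, max_epochs = max_epochs, ...),
      skelwatch_training_diverged = function(e) NULL)
    if (is.null(bundle)) {
      return(data.frame(body = body, tp_pct = NA_real_, tn_pct = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    pred_pos <- predict(bundle$mlp, te$x, threshold = bundle$confidence_threshold,
                        margin = bundle$margin)
    dx <- if (n_distract > 0L)
      generate_distractors(n_distract, body, subjects, camera, jitter_sigma,
                           seed = next_child_seed(seed, 4)) else NULL
    pred_neg <- if (!is.null(dx))
      predict(bundle$mlp, dx, threshold = bundle$confidence_threshold,
              margin = bundle$margin) else character()
    tp <- 100 * mean(pred_pos == as.character(te$labels))
    tn <- if (length(pred_neg)) 100 * mean(pred_neg == "none") else NA_real_
    data.frame(body = body, tp_pct = tp, tn_pct = tn,
               converged = bundle$mlp$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Train the fall classifier under reference conditions
#'
#' Generates head-trajectory windows from scripted falls and confounders at
#' the reference camera (2.5 m, level, full visibility) and trains the
#' fall/no-fall network.
#'
#' @param seed Integer seed.
#' @param n_fall,n_nonfall Window counts per class.
#' @param subjects Subject pool.
#' @param train_camera Camera for training-data rendering.
#' @param jitter_sigma Pose jitter sigma (meters).
#' @param max_epochs,... Passed to the trainer.
#' @return A fall `classifier_bundle`.
#' @export
train_fall_bundle <- function(seed, n_fall = 600L, n_nonfall = 600L,
                              subjects = subject_pool(),
                              train_camera = camera_model(distance = 2.5),
                              jitter_sigma = 0.02, max_epochs = 20000L, ...) {
  ds <- generate_fall_dataset(n_fall, n_nonfall, window = 10L,
                              subjects = subjects, camera = train_camera,
                              jitter_sigma = jitter_sigma,
                              seed = next_child_seed(seed, 11))
  build_fall_classifier(ds, seed = next_child_seed(seed, 12),
                        max_epochs = max_epochs, ...)
}

# camera used when the monitor watches for falls: mounted low so the
# on-ground head stays inside the frustum from 1 m outward
fall_watch_camera <- function(distance, vertical_angle = 0, horizontal_rotation = 0) {
  camera_model(distance = distance, vertical_angle = vertical_angle,
               horizontal_rotation = horizontal_rotation, mount_height = 0.7)
}

#' Run scripted situations through the full monitor pipeline
#'
#' Renders `n_seq` scripted sequences (falls when `positive`, alternating
#' quick sits and bends otherwise) under cameras drawn per sequence from the
#' given ranges, runs the monitor, and reports whether each sequence raised
#' an alarm. The watch camera is mounted low (0.7 m) so the on-ground head
#' stays in the frustum from about 1 m outward.
#'
#' @param bundle Trained fall `classifier_bundle`.
#' @param n_seq Number of sequences.
#' @param distance,vertical_angle,horizontal_rotation Sampling ranges
#'   (length-1 or 2, uniform within).
#' @param positive Render falls (`TRUE`) or confounders (`FALSE`).
#' @param subjects Subject pool.
#' @param jitter_sigma Pose jitter sigma (meters).
#' @param seed Integer seed.
#' @param config Monitor configuration.
#' @param on_ground Seconds the subject stays down (falls) or holds
#'   (confounders).
#' @return Logical vector: alarm raised per sequence.
#' @export
evaluate_fall_monitor <- function(bundle, n_seq, distance = c(1, 4.5),
                                  vertical_angle = 0, horizontal_rotation = 0,
                                  positive = TRUE, subjects = subject_pool(),
                                  jitter_sigma = 0.02, seed = 1L,
                                  config = monitor_config(), on_ground = 20) {
  rg <- function(r) if (length(r) == 2L) stats::runif(1L, r[1L], r[2L]) else r
  camera_fn <- function() fall_watch_camera(rg(distance), rg(vertical_angle),
                                            rg(horizontal_rotation))
  vapply(seq_len(n_seq), function(i) {
    sseed <- next_child_seed(seed, 100 + i)
    set.seed(sseed)
    subj <- subjects[[(i - 1L) %% length(subjects) + 1L]]
    cam <- camera_fn()
    sc <- if (positive) {
      motion_script(script_hold("standing", 1.0),
                    script_fall(stats::runif(1L, 0.5, 1.0), on_ground))
    } else if (i %% 2L == 0L) {
      motion_script(script_hold("standing", 1.0), script_quick_sit(on_ground))
    } else {
      motion_script(script_hold("standing", 1.0), script_bend_down(1.0),
                    script_hold("standing", on_ground - 3))
    }
    stream <- render_script(subj, sc, cam, jitter_sigma,
                            seed = next_child_seed(sseed, 1))
    cal <- calibration_for(subj, cam)
    ev <- run_monitor(stream, bundle, lower_bundle = NULL,
                      calibration = cal, config = config)
    any(ev$kind == "alarm_started")
  }, logical(1L))
}

sweep_frame <- function(rows) {
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' @export
print.sweep_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  agg <- stats::aggregate(df[num & names(df) != "seed"],
                          by = list(case = df$case), FUN = mean)
  cat("Per-condition means over seeds:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Sweep the number of hidden neurons
#'
#' Trains the upper/lower posture classifiers at each (upper, lower)
#' hidden-count pair on freshly generated data and evaluates detection rates
#' on held-out positives and distractor negatives. Training failures are
#' recorded per cell (NA rates, `converged = FALSE`), not fatal.
#'
#' @param levels List of `c(upper, lower)` hidden-neuron pairs.
#' @param seeds Integer seeds; one full study per seed.
#' @param n_train Named vector `c(upper=, lower=)` of training instances.
#' @param n_test,n_distract Held-out positive / distractor counts per body half.
#' @param max_epochs Training epoch cap.
#' @param ... Further arguments to the dataset generator/trainer.
#' @return A `sweep_table` data frame, one row per case x seed x body half.
#' @export
sweep_hidden <- function(levels = list(c(8, 6), c(10, 8), c(12, 10), c(14, 12), c(16, 14)),
                         seeds = 1:5,
                         n_train = c(upper = 632L, lower = 735L),
                         n_test = 500L, n_distract = 500L,
                         max_epochs = 20000L, ...) {
  if (length(levels) == 0L) stop_skel("no sweep levels", "bad_sweep")
  rows <- list()
  for (li in seq_along(levels)) {
    hv <- levels[[li]]
    for (s in seeds) {
      r <- evaluate_posture_classifiers(n_train = n_train, n_test = n_test,
                                  n_distract = n_distract,
                                  hidden = c(upper = hv[1L], lower = hv[2L]),
                                  seed = s, max_epochs = max_epochs, ...)
      r$case <- sprintf("%d/%d", hv[1L], hv[2L])
      r$seed <- s
      rows[[length(rows) + 1L]] <- r
    }
  }
  sweep_frame(rows)
}

#' Sweep the training-set size
#'
#' @param levels List of `c(upper, lower)` instance counts.
#' @inheritParams sweep_hidden
#' @return A `sweep_table`.
#' @export
sweep_instances <- function(levels = list(c(200, 260), c(500, 600), c(632, 735),
                                          c(800, 900), c(1100, 1200)),
                            seeds = 1:5, n_test = 500L, n_distract = 500L,
                            max_epochs = 20000L, ...) {
  if (length(levels) == 0L) stop_skel("no sweep levels", "bad_sweep")
  rows <- list()
  for (li in seq_along(levels)) {
    nv <- levels[[li]]
    for (s in seeds) {
      r <- evaluate_posture_classifiers(n_train = c(upper = nv[1L], lower = nv[2L]),
                                  n_test = n_test, n_distract = n_distract,
                                  seed = s, max_epochs = max_epochs, ...)
      r$case <- sprintf("%d/%d", nv[1L], nv[2L])
      r$seed <- s
      rows[[length(rows) + 1L]] <- r
    }
  }
  sweep_frame(rows)
}

#' Sweep the camera distance for fall detection
#'
#' Per distance range and seed, trains the fall classifier under reference
#' conditions, then runs scripted falls (positives) and quick-sit/bend
#' confounders (negatives) through the full monitor pipeline at distances
#' sampled from the range. TP is the fraction of fall sequences that raise an
#' alarm; TN the fraction of confounders that do not.
#'
#' @param levels Named list of `c(min, max)` distance ranges in meters.
#' @param seeds Integer seeds.
#' @param n_seq Sequences per class per condition and seed.
#' @param n_fall_train,max_epochs Fall-classifier training controls.
#' @param jitter_sigma Pose jitter sigma in meters.
#' @param subjects Subject pool.
#' @return A `sweep_table`, one row per case x seed.
#' @export
sweep_distance <- function(levels = list("<1m" = c(0.5, 1), "1-4.5m" = c(1, 4.5),
                                         ">4.5m" = c(4.5, 7)),
                           seeds = 1:5, n_seq = 20L, n_fall_train = 600L,
                           max_epochs = 20000L, jitter_sigma = 0.02,
                           subjects = subject_pool()) {
  if (length(levels) == 0L) stop_skel("no sweep levels", "bad_sweep")
  rows <- list()
  for (s in seeds) {
    bundle <- train_fall_bundle(s, n_fall_train, n_fall_train,
                                subjects = subjects, jitter_sigma = jitter_sigma,
                                max_epochs = max_epochs)
    for (li in seq_along(levels)) {
      rg <- levels[[li]]
      pos <- evaluate_fall_monitor(bundle, n_seq, distance = rg, positive = TRUE,
                                   subjects = subjects, jitter_sigma = jitter_sigma,
                                   seed = next_child_seed(s, 1000 + li))
      neg <- evaluate_fall_monitor(bundle, n_seq, distance = rg, positive = FALSE,
                                   subjects = subjects, jitter_sigma = jitter_sigma,
                                   seed = next_child_seed(s, 2000 + li))
      rows[[length(rows) + 1L]] <- data.frame(
        case = names(levels)[li] %||% sprintf("case%d", li), seed = s,
        tp_pct = 100 * mean(pos), tn_pct = 100 * mean(!neg),
        stringsAsFactors = FALSE)
    }
  }
  sweep_frame(rows)
}

#' Sweep camera angles for fall detection
#'
#' Conditions give a vertical camera angle range (degrees above the subject)
#' and a horizontal subject-rotation range; sequences sample uniformly within
#' them at a fixed 2.5 m distance.
#'
#' @param conditions Named list of `list(vertical = c(min,max), horizontal = c(min,max))`.
#' @inheritParams sweep_distance
#' @return A `sweep_table`.
#' @export
sweep_angles <- function(conditions = list(
                           "v0_h0-45"  = list(vertical = c(0, 0),  horizontal = c(0, 45)),
                           "v0_h45-90" = list(vertical = c(0, 0),  horizontal = c(45, 90)),
                           "v>45_h0"   = list(vertical = c(50, 60), horizontal = c(0, 0))),
                         seeds = 1:5, n_seq = 20L, n_fall_train = 600L,
                         max_epochs = 20000L, jitter_sigma = 0.02,
                         subjects = subject_pool()) {
  if (length(conditions) == 0L) stop_skel("no sweep conditions", "bad_sweep")
  if (anyDuplicated(names(conditions)))
    stop_skel("duplicate condition labels", "bad_sweep")
  rows <- list()
  for (s in seeds) {
    bundle <- train_fall_bundle(s, n_fall_train, n_fall_train,
                                subjects = subjects, jitter_sigma = jitter_sigma,
                                max_epochs = max_epochs)
    for (li in seq_along(conditions)) {
      cd <- conditions[[li]]
      pos <- evaluate_fall_monitor(bundle, n_seq, distance = 2.5,
                                   vertical_angle = cd$vertical,
                                   horizontal_rotation = cd$horizontal,
                                   positive = TRUE, subjects = subjects,
                                   jitter_sigma = jitter_sigma,
                                   seed = next_child_seed(s, 3000 + li))
      neg <- evaluate_fall_monitor(bundle, n_seq, distance = 2.5,
                                   vertical_angle = cd$vertical,
                                   horizontal_rotation = cd$horizontal,
                                   positive = FALSE, subjects = subjects,
                                   jitter_sigma = jitter_sigma,
                                   seed = next_child_seed(s, 4000 + li))
      rows[[length(rows) + 1L]] <- data.frame(
        case = names(conditions)[li], seed = s,
        tp_pct = 100 * mean(pos), tn_pct = 100 * mean(!neg),
        stringsAsFactors = FALSE)
    }
  }
  sweep_frame(rows)
}
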