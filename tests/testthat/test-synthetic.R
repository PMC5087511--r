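noiseless <- function(...) camera_model(..., noise_sigma0 = 0)

test_that("a noiseless standing render puts the head at subject height with all joints seen", {
  for (h in c(1.50, 1.72, 1.95)) {
    f <- render_posture(subject_model(h), "standing", noiseless(distance = 2.5))
    expect_true(all(f$detected))
    # camera frame: head sits mount_height below its world height
    expect_equal(f$positions["head", "y"], h - 1.05, tolerance = 1e-9)
    # feet joints sit at ankle level, so the subtraction runs ~4% short
    expect_equal(estimate_height(f), h * (1 - 0.039), tolerance = 1e-6)
  }
})

test_that("posture templates are mutually distinct well beyond jitter scale", {
  classes <- upper_postures()
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i >= j) next
    pi_ <- skelwatch:::pose_local(posture_template(classes[i]))
    pj <- skelwatch:::pose_local(posture_template(classes[j]))
    d <- max(abs(pi_ - pj)) * 1.5  # meters on the shortest subject
    expect_gt(d, 3 * 0.02)
  }
  pl <- skelwatch:::pose_local(posture_template("standing"))
  ps <- skelwatch:::pose_local(posture_template("sitting"))
  expect_gt(max(abs(pl - ps)) * 1.5, 3 * 0.02)
})

test_that("the ratio baseline classifies noiseless lower-body templates correctly", {
  for (h in c(1.50, 1.70, 1.95)) {
    subj <- subject_model(h)
    cam <- noiseless()
    cal <- skel_calibration(h, h - cam$mount_height)
    expect_equal(ratio_posture(render_posture(subj, "standing", cam), cal), "standing")
    expect_equal(ratio_posture(render_posture(subj, "sitting", cam), cal), "sitting")
  }
})

test_that("a close camera loses the standing head in the frustum", {
  f <- render_posture(subject_model(1.7), "standing", noiseless(distance = 0.8))
  expect_false(f$detected[["head"]])
  f2 <- render_posture(subject_model(1.7), "standing", noiseless(distance = 2.5))
  expect_true(f2$detected[["head"]])
})

test_that("frustum dropout is monotone in distance at zero angles", {
  for (j in c("head", "left_hand", "left_foot")) {
    seen <- vapply(seq(0.6, 4.5, by = 0.3), function(d) {
      render_posture(subject_model(1.8), "both_arms_raised",
                     noiseless(distance = d))$detected[[j]]
    }, logical(1))
    # once visible, stays visible out to 4.5 m
    if (any(seen)) expect_true(all(seen[which(seen)[1]:length(seen)]))
  }
})

test_that("horizontal rotation preserves the head height trajectory", {
  subj <- subject_model(1.7)
  sc <- motion_script(script_hold("standing", 0.5), script_fall(0.6, 1, direction = 45))
  s0 <- render_script(subj, sc, noiseless(horizontal_rotation = 0), 0, seed = 3)
  s60 <- render_script(subj, sc, noiseless(horizontal_rotation = 60), 0, seed = 3)
  y0 <- vapply(s0, function(f) f$positions["head", "y"], numeric(1))
  y60 <- vapply(s60, function(f) f$positions["head", "y"], numeric(1))
  expect_equal(y0, y60, tolerance = 1e-9)
})

test_that("rendered subjects keep their segment lengths across a script", {
  stream <- render_script(subject_model(1.8),
                          motion_script(script_hold("standing", 0.3),
                                        script_hold("both_arms_raised", 0.3)),
                          noiseless(), 0, seed = 2)
  ts <- vapply(stream, `[[`, numeric(1), "timestamp")
  held <- ts < 0.29 | ts > 0.71     # exclude the interpolated transition
  arm <- vapply(stream[held], function(f)
    sqrt(sum((f$positions["left_shoulder", ] - f$positions["left_elbow", ])^2)),
    numeric(1))
  expect_lt(max(arm) - min(arm), 1e-6)
  expect_equal(arm[1], 0.19 * 1.8, tolerance = 1e-6)
})

test_that("fall scripts descend the head to a fifth of the height on schedule", {
  subj <- subject_model(1.7)
  stream <- render_script(subj,
                          motion_script(script_hold("standing", 0.5),
                                        script_fall(0.6, 12, direction = 90)),
                          noiseless(), 0, seed = 4)
  expect_gte(length(stream), (0.5 + 0.6 + 12) * 30 - 2)
  y <- vapply(stream, function(f) f$positions["head", "y"], numeric(1))
  ts <- vapply(stream, `[[`, numeric(1), "timestamp")
  descent <- which(ts > 0.5 & ts <= 1.1)
  expect_gte(length(descent), 17)                     # >= 18 frames nominally
  expect_true(all(diff(y[descent]) <= 1e-9))          # monotone descent
  expect_equal(y[length(y)], 0.2 * 1.7 - 1.05, tolerance = 1e-6)
  # quick sit ends at the sitting template's head height
  sit <- render_script(subj, motion_script(script_hold("standing", 0.3),
                                           script_quick_sit(0.5)),
                       noiseless(), 0, seed = 5)
  sit_tpl <- render_posture(subj, "sitting", noiseless())
  expect_equal(sit[[length(sit)]]$positions["head", "y"],
               sit_tpl$positions["head", "y"], tolerance = 1e-6)
})

test_that("script rendering is deterministic per seed", {
  subj <- subject_model(1.6)
  sc <- motion_script(script_hold("standing", 0.4), script_fall(0.7, 1))
  a <- render_script(subj, sc, camera_model(), 0.02, seed = 9)
  b <- render_script(subj, sc, camera_model(), 0.02, seed = 9)
  expect_identical(a, b)
  c_ <- render_script(subj, sc, camera_model(), 0.02, seed = 10)
  expect_false(identical(a, c_))
  expect_error(motion_script(list(list(bogus = 1))), class = "skelwatch_bad_script")
})

test_that("dataset generation stratifies, labels and round-trips through TXT", {
  ds <- generate_dataset(upper_postures(), 50, seed = 6)
  expect_equal(nrow(ds$x), 50L)
  expect_equal(ncol(ds$x), 15L)
  expect_true(all(table(ds$labels) == 10L))
  expect_true(all(ds$x >= 0 & ds$x <= 1))

  # 632 instances: class counts differ by at most one
  counts <- skelwatch:::stratified_counts(upper_postures(), 632)
  expect_equal(sum(counts), 632L)
  expect_lte(max(counts) - min(counts), 1L)

  p <- withr::local_tempfile(fileext = ".txt")
  write_dataset(ds, p)
  back <- read_dataset(p)
  expect_equal(back$x, unname(ds$x), tolerance = 1e-6)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$joint_set, ds$joint_set)

  expect_error(generate_dataset(c("both_arms_raised", "no_such_pose"), 10),
               class = "skelwatch_no_template")
})

test_that("distractor poses stay well away from every class template", {
  x <- generate_distractors(40, "upper", seed = 7)
  expect_equal(dim(x), c(40L, 15L))
  expect_true(all(x >= 0 & x <= 1))
  x2 <- generate_distractors(20, "lower", seed = 8)
  expect_equal(dim(x2), c(20L, 18L))
})
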