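# Parametric skeleton/camera simulator standing in for a depth sensor and for
# recorded subjects: posture templates, fall and confounder motion scripts, a
# pinhole view frustum with depth-dependent jitter, and labeled dataset
# generation.

# Segment geometry as fractions of standing height. Head is the top-of-head
# joint (so a noiseless standing head sits at y = height); foot joints are the
# ankle centers just above the ground.
SEGMENT_RATIOS <- list(
  head = 1.0, shoulder = 0.818, hip = 0.53, knee = 0.285, foot = 0.039,
  shoulder_halfwidth = 0.129, hip_halfwidth = 0.096,
  upper_arm = 0.19, lower_arm = 0.21
)

#' Synthetic subject model
#'
#' @param height Standing height in meters (the simulator's subjects span
#'   1.50--1.95 m).
#' @param ratios Segment lengths as fractions of height; see the methods
#'   vignette for the default anthropometry.
#' @param id Optional label.
#' @return Object of class `subject_model`.
#' @export
subject_model <- function(height = 1.70, ratios = SEGMENT_RATIOS, id = NULL) {
  stopifnot(height > 0.5, height < 2.5)
  structure(list(height = height, ratios = ratios, id = id %||% sprintf("s%.2f", height)),
            class = "subject_model")
}

#' Default subject pool
#'
#' Six subjects with heights evenly spaced over 1.50--1.95 m, emulating a
#' small mixed-constitution study population.
#'
#' @param n Number of subjects.
#' @param heights Heights in meters.
#' @return List of [subject_model()]s.
#' @export
subject_pool <- function(n = 6L, heights = seq(1.50, 1.95, length.out = n)) {
  lapply(heights, subject_model)
}

#' Synthetic camera model
#'
#' A pinhole camera with a rectangular view frustum and depth-dependent
#' additive jitter. `distance` is the horizontal camera-subject distance. A
#' positive `vertical_angle` raises the camera and pitches it down so its
#' optical axis passes through the subject plane at `mount_height`;
#' `horizontal_rotation` turns the subject about the vertical axis. Joints
#' outside the frustum are reported undetected. Per-joint noise sigma is
#' `noise_sigma0 * (1 + noise_z_scale * max(0, z - 4.5))` on top of any pose
#' jitter, growing past the sensor's reliable depth range.
#'
#' @param distance Camera-subject distance in meters.
#' @param vertical_angle Degrees above the subject (camera raised, pitched down).
#' @param horizontal_rotation Subject turn in degrees about the vertical axis.
#' @param v_fov,h_fov Vertical/horizontal field of view in degrees.
#' @param mount_height Camera optical-axis height at the subject plane, meters.
#' @param noise_sigma0 Baseline sensor noise sigma in meters.
#' @param noise_z_scale Per-meter noise growth beyond 4.5 m depth.
#' @param frame_rate Frames per second for rendered streams.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(distance = 2.5, vertical_angle = 0, horizontal_rotation = 0,
                         v_fov = 45, h_fov = 58, mount_height = 1.05,
                         noise_sigma0 = 0.005, noise_z_scale = 0.08,
                         frame_rate = 30) {
  stopifnot(distance > 0, v_fov > 0, h_fov > 0, frame_rate > 0)
  structure(list(distance = distance, vertical_angle = vertical_angle,
                 horizontal_rotation = horizontal_rotation,
                 v_fov = v_fov, h_fov = h_fov, mount_height = mount_height,
                 noise_sigma0 = noise_sigma0, noise_z_scale = noise_z_scale,
                 frame_rate = frame_rate),
            class = "camera_model")
}

#' Posture classes
#'
#' @return Character vector of the five upper-body or two lower-body posture
#'   classes the simulator has templates for.
#' @export
upper_postures <- function() {
  c("both_arms_raised", "right_arm_raised", "left_arm_raised",
    "arms_outstretched", "both_arms_down")
}

#' @rdname upper_postures
#' @export
lower_postures <- function() c("standing", "sitting")

# Template parameters: arm elevation in degrees from straight down in the
# coronal plane (10 = hanging, 90 = outstretched, 125 = raised above the
# head), and the leg configuration.
POSTURE_TEMPLATES <- list(
  both_arms_raised  = list(arms = c(left = 125, right = 125), legs = "standing"),
  right_arm_raised  = list(arms = c(left = 10,  right = 125), legs = "standing"),
  left_arm_raised   = list(arms = c(left = 125, right = 10),  legs = "standing"),
  arms_outstretched = list(arms = c(left = 90,  right = 90),  legs = "standing"),
  both_arms_down    = list(arms = c(left = 10,  right = 10),  legs = "standing"),
  standing          = list(arms = c(left = 10,  right = 10),  legs = "standing"),
  sitting           = list(arms = c(left = 10,  right = 10),  legs = "sitting")
)

#' Posture template
#'
#' @param class One of [upper_postures()] or [lower_postures()].
#' @return List with the template's arm elevations (degrees) and leg
#'   configuration.
#' @export
posture_template <- function(class) {
  t <- POSTURE_TEMPLATES[[class]]
  if (is.null(t)) stop_skel(paste("no template for class:", class), "no_template")
  c(list(name = class), t)
}

# 14 x 3 joint positions in the subject-local frame (x left, y up, z toward
# the camera at zero rotation), in units of subject height.
pose_local <- function(template, crouch = 0) {
  r <- SEGMENT_RATIOS
  sit <- identical(template$legs, "sitting")
  # leg/torso layout; `crouch` in [0,1] interpolates standing -> sitting for
  # intermediate (distractor) configurations
  s <- if (sit) 1 else crouch
  hip_y  <- (1 - s) * r$hip + s * 0.30
  knee_y <- (1 - s) * r$knee + s * 0.30
  knee_z <- s * 0.22
  foot_y <- (1 - s) * r$foot + s * 0.054
  foot_z <- s * 0.24
  drop   <- r$hip - hip_y                      # pelvis drop carries the torso
  sh_y   <- r$shoulder - drop
  head_y <- r$head - drop * 0.96               # sitting head ~0.77 of height
  p <- matrix(0, 14L, 3L, dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  p["head", ] <- c(0, head_y, 0)
  p["center_shoulder", ] <- c(0, sh_y, 0)
  p["left_shoulder", ]  <- c( r$shoulder_halfwidth, sh_y, 0)
  p["right_shoulder", ] <- c(-r$shoulder_halfwidth, sh_y, 0)
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    e <- template$arms[[side]] * pi / 180
    dir <- c(sgn * sin(e), -cos(e), 0)
    sh <- p[paste0(side, "_shoulder"), ]
    el <- sh + r$upper_arm * dir
    hd <- el + r$lower_arm * dir
    p[paste0(side, "_elbow"), ] <- el
    p[paste0(side, "_hand"), ]  <- hd
  }
  p["left_hip", ]   <- c( r$hip_halfwidth, hip_y, 0)
  p["right_hip", ]  <- c(-r$hip_halfwidth, hip_y, 0)
  p["left_knee", ]  <- c( r$hip_halfwidth, knee_y, knee_z)
  p["right_knee", ] <- c(-r$hip_halfwidth, knee_y, knee_z)
  p["left_foot", ]  <- c( r$hip_halfwidth, foot_y, foot_z)
  p["right_foot", ] <- c(-r$hip_halfwidth, foot_y, foot_z)
  p
}

# lying-on-the-ground pose: the body folds and comes to rest extending from
# the feet along `direction` (degrees in the subject-local frame, 0 = toward
# the camera at zero rotation); a fall crumples rather than toppling rigidly,
# so the head lands about 0.3 of the height away from the feet, at
# 0.2 * height above the ground
lying_local <- function(direction = 90) {
  up <- pose_local(POSTURE_TEMPLATES$standing)
  y_lying <- c(head = 0.20, center_shoulder = 0.14, left_shoulder = 0.14,
               right_shoulder = 0.14, left_elbow = 0.12, right_elbow = 0.12,
               left_hand = 0.10, right_hand = 0.10, left_hip = 0.12,
               right_hip = 0.12, left_knee = 0.10, right_knee = 0.10,
               left_foot = 0.08, right_foot = 0.08)
  a <- direction * pi / 180
  u <- c(sin(a), 0, cos(a))       # horizontal extension direction
  v <- c(cos(a), 0, -sin(a))      # sideways spread
  p <- up
  for (j in JOINT_NAMES) {
    p[j, ] <- u * (0.30 * up[j, "y"]) + v * (0.3 * up[j, "x"])
    p[j, "y"] <- y_lying[[j]]
  }
  p
}

# head drops to ~55% of height and the trunk folds forward; legs stay put
bent_local <- function() {
  p <- pose_local(POSTURE_TEMPLATES$standing)
  p["head", ] <- c(0, 0.55, 0.28)
  p["center_shoulder", ] <- c(0, 0.50, 0.25)
  p["left_shoulder", ]  <- c( SEGMENT_RATIOS$shoulder_halfwidth, 0.50, 0.25)
  p["right_shoulder", ] <- c(-SEGMENT_RATIOS$shoulder_halfwidth, 0.50, 0.25)
  p["left_elbow", ]  <- c( 0.16, 0.36, 0.22)
  p["right_elbow", ] <- c(-0.16, 0.36, 0.22)
  p["left_hand", ]   <- c( 0.16, 0.22, 0.20)
  p["right_hand", ]  <- c(-0.16, 0.22, 0.20)
  p
}

# world transform + frustum + jitter: local pose (units of height) -> camera
# frame. `pose` may be a 14x3 matrix or an n x 14 x 3 array (one per frame).
render_pose_matrix <- function(pose, subject, camera, jitter_sigma = 0, n = 1L) {
  if (length(dim(pose)) == 2L) pose <- array(rep(t(pose), n), c(3L, 14L, n))
  else pose <- aperm(pose, c(3L, 2L, 1L))            # 3 x 14 x n
  m <- matrix(pose, nrow = 3L)                        # columns: joint-frame pairs
  m <- m * subject$height
  yaw <- camera$horizontal_rotation * pi / 180
  cy <- cos(yaw); sy <- sin(yaw)
  xw <- cy * m[1L, ] + sy * m[3L, ]
  zw <- -sy * m[1L, ] + cy * m[3L, ]
  yw <- m[2L, ]
  # camera at (0, cam_y, -distance) looking at the subject plane point at
  # mount_height; pitch angle = vertical_angle
  v <- camera$vertical_angle * pi / 180
  cam_y <- camera$mount_height + camera$distance * tan(v)
  yr <- yw - cam_y
  zr <- zw + camera$distance
  yc <- yr * cos(v) + zr * sin(v)
  zc <- -yr * sin(v) + zr * cos(v)
  xc <- xw
  sigma <- jitter_sigma + camera$noise_sigma0 * (1 + camera$noise_z_scale * pmax(0, zc - 4.5))
  if (any(sigma > 0)) {
    k <- length(xc)
    xc <- xc + stats::rnorm(k, 0, sigma)
    yc <- yc + stats::rnorm(k, 0, sigma)
    zc <- zc + stats::rnorm(k, 0, sigma)
  }
  detected <- zc > 0.05 &
    abs(atan2(xc, zc)) <= (camera$h_fov / 2) * pi / 180 &
    abs(atan2(yc, zc)) <= (camera$v_fov / 2) * pi / 180
  list(x = xc, y = yc, z = zc, detected = detected, n = dim(pose)[3L])
}

frames_from_render <- function(r, timestamps) {
  n <- r$n
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1L) * 14L + 1L):(i * 14L)
    pos <- cbind(x = r$x[idx], y = r$y[idx], z = r$z[idx])
    rownames(pos) <- JOINT_NAMES
    pos[!r$detected[idx], ] <- NA_real_
    f <- list(timestamp = timestamps[i], positions = pos,
              detected = stats::setNames(r$detected[idx], JOINT_NAMES))
    class(f) <- "skel_frame"
    f
  })
}

#' Render a single posture frame
#'
#' @param subject A [subject_model()].
#' @param template A posture class name or [posture_template()].
#' @param camera A [camera_model()].
#' @param jitter_sigma Pose jitter sigma in meters (on top of sensor noise).
#' @param seed Optional integer seed.
#' @param timestamp Frame time in seconds.
#' @return A [skel_frame()]; joints outside the view frustum are undetected.
#' @export
render_posture <- function(subject, template, camera = camera_model(),
                           jitter_sigma = 0, seed = NULL, timestamp = 0) {
  if (is.character(template)) template <- posture_template(template)
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- render_pose_matrix(pose_local(template), subject, camera, jitter_sigma)
  frames_from_render(r, timestamp)[[1L]]
}

#' Motion script events
#'
#' Build the timed events a [render_script()] stream is made of: holding a
#' posture, a fall (head descends to 0.2 of the subject height within
#' `duration_down` seconds, then stays on the ground), a quick sit (descent to
#' the sitting template over 0.8 s -- a fall-like confounder), bending down
#' (head drops to ~55% of height and recovers), and standing up.
#'
#' @param posture Posture class name to hold.
#' @param duration,duration_down,duration_on_ground,hold Durations in seconds.
#' @param direction Fall direction in degrees (subject-local; `NULL` = drawn
#'   uniformly from 0--360 when the script is rendered).
#' @return An event object for [motion_script()].
#' @export
script_hold <- function(posture, duration) {
  list(kind = "hold", posture = posture, duration = duration)
}

#' @rdname script_hold
#' @export
script_fall <- function(duration_down = 0.7, duration_on_ground = 12, direction = NULL) {
  stopifnot(duration_down >= 0.5, duration_down <= 1.0, duration_on_ground > 0)
  list(kind = "fall", duration_down = duration_down,
       duration_on_ground = duration_on_ground, direction = direction)
}

#' @rdname script_hold
#' @export
script_quick_sit <- function(hold = 5) list(kind = "quick_sit", hold = hold)

#' @rdname script_hold
#' @export
script_bend_down <- function(hold = 1) list(kind = "bend_down", hold = hold)

#' @rdname script_hold
#' @export
script_stand_up <- function(duration = 1) list(kind = "stand_up", duration = duration)

#' @rdname script_hold
#' @param ... Events in order.
#' @export
motion_script <- function(...) {
  ev <- list(...)
  if (length(ev) == 1L && is.null(ev[[1L]]$kind)) ev <- ev[[1L]]
  for (e in ev) if (is.null(e$kind)) stop_skel("invalid script event", "bad_script")
  structure(ev, class = "motion_script")
}

ease <- function(u) (1 - cos(pi * u)) / 2  # smooth 0 -> 1

#' Render a motion script to a frame stream
#'
#' Produces frames at the camera frame rate with strictly increasing
#' timestamps; deterministic for a given seed. Fall events interpolate the
#' whole skeleton from the current pose to a lying pose whose head rests at
#' 0.2 of the subject height; segments between key poses use cosine easing.
#'
#' @param subject A [subject_model()].
#' @param script A [motion_script()] (or list of events).
#' @param camera A [camera_model()].
#' @param jitter_sigma Pose jitter sigma in meters.
#' @param seed Integer seed for jitter and any unset fall directions.
#' @return List of [skel_frame()]s (a frame stream).
#' @export
render_script <- function(subject, script, camera = camera_model(),
                          jitter_sigma = 0.02, seed = 1L) {
  if (!inherits(script, "motion_script")) script <- motion_script(script)
  set.seed(as.integer(seed))
  cur <- pose_local(POSTURE_TEMPLATES$standing)
  segs <- list()  # each: list(from, to, duration) with cosine easing, or hold
  add <- function(to, duration) segs[[length(segs) + 1L]] <<- list(from = cur, to = to, duration = duration)
  for (e in script) {
    switch(e$kind,
      hold = {
        tpl <- pose_local(posture_template(e$posture))
        if (!isTRUE(all.equal(cur, tpl))) add(tpl, 0.4)  # brief transition
        cur <- tpl
        add(tpl, e$duration)
      },
      fall = {
        dir <- e$direction %||% stats::runif(1L, 0, 360)
        ly <- lying_local(dir)
        add(ly, e$duration_down); cur <- ly
        add(ly, e$duration_on_ground)
      },
      quick_sit = {
        sit <- pose_local(POSTURE_TEMPLATES$sitting)
        add(sit, 0.8); cur <- sit
        add(sit, e$hold)
      },
      bend_down = {
        prev <- cur
        bent <- bent_local()
        add(bent, 0.8); cur <- bent
        add(bent, e$hold)
        add(prev, 0.8); cur <- prev
      },
      stand_up = {
        up <- pose_local(POSTURE_TEMPLATES$standing)
        add(up, e$duration); cur <- up
        add(up, 0.2)
      },
      stop_skel(paste("invalid script event:", e$kind), "bad_script")
    )
  }
  fr <- camera$frame_rate
  total <- sum(vapply(segs, `[[`, numeric(1L), "duration"))
  n <- max(1L, floor(total * fr))
  ts <- (seq_len(n) - 1L) / fr
  poses <- array(0, c(n, 14L, 3L))
  t0 <- 0
  for (s in segs) {
    t1 <- t0 + s$duration
    sel <- which(ts >= t0 - 1e-9 & ts < t1 - 1e-9)
    if (length(sel)) {
      u <- ease((ts[sel] - t0) / s$duration)
      for (i in seq_along(sel))
        poses[sel[i], , ] <- (1 - u[i]) * s$from + u[i] * s$to
    }
    t0 <- t1
  }
  r <- render_pose_matrix(poses, subject, camera, jitter_sigma)
  frames_from_render(r, ts)
}

# analytic calibration for a simulated subject under a given camera: standing
# head level in camera coordinates at zero vertical angle ("enrollment" is
# done with the camera level with the subject)
calibration_for <- function(subject, camera) {
  skel_calibration(subject$height, subject$height - camera$mount_height)
}

next_child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483587 + 1)
}

stratified_counts <- function(classes, n_total) {
  k <- length(classes)
  base <- n_total %/% k
  extra <- n_total %% k
  stats::setNames(base + c(rep(1L, extra), rep(0L, k - extra)), classes)
}

#' Generate a labeled posture training set
#'
#' Renders stratified, shuffled labeled frames across the subject pool and
#' extracts normalized features. Samples whose required joints fall outside
#' the view frustum (possible for extreme jitter draws) are redrawn.
#'
#' @param classes Posture classes (all upper-body or all lower-body).
#' @param n_total Total number of samples; class counts differ by at most 1.
#' @param subjects List of [subject_model()]s.
#' @param camera A [camera_model()].
#' @param jitter_sigma Pose jitter sigma in meters.
#' @param seed Integer seed.
#' @param joint_set Joint set for the features (defaults to the body half the
#'   classes belong to).
#' @param file Optional path: also writes the dataset TXT.
#' @return A `posture_dataset`: list with feature matrix `x`, factor `labels`,
#'   `joint_set`, `window`, `seed`.
#' @export
generate_dataset <- function(classes, n_total, subjects = subject_pool(),
                             camera = camera_model(), jitter_sigma = 0.02,
                             seed = 1L, joint_set = NULL, file = NULL) {
  stopifnot(n_total >= length(classes))
  for (cl in classes) posture_template(cl)  # validate up front
  upper <- all(classes %in% upper_postures())
  joint_set <- joint_set %||% if (upper) upper_joint_set() else lower_joint_set()
  set.seed(as.integer(seed))
  counts <- stratified_counts(classes, n_total)
  labs <- sample(rep(names(counts), counts))
  nfeat <- 3L * length(joint_set)
  x <- matrix(NA_real_, length(labs), nfeat)
  subj_i <- sample(rep_len(seq_along(subjects), length(labs)))
  for (i in seq_along(labs)) {
    subj <- subjects[[subj_i[i]]]
    cal <- calibration_for(subj, camera)
    for (try in 1:100) {
      f <- render_posture(subj, labs[i], camera, jitter_sigma)
      ok <- tryCatch({
        x[i, ] <- extract_features(f, joint_set, cal); TRUE
      }, skelwatch_joint_missing = function(e) FALSE)
      if (ok) break
      if (try == 100L) stop_skel("could not render a fully visible sample", "render_failed")
    }
  }
  ds <- structure(list(x = x, labels = factor(labs, levels = classes),
                       joint_set = joint_set, window = 1L,
                       seed = as.integer(seed)),
                  class = "posture_dataset")
  if (!is.null(file)) write_dataset(ds, file)
  ds
}

#' @export
print.posture_dataset <- function(x, ...) {
  cat(sprintf("<posture_dataset: %d samples x %d features, window %d>\n",
              nrow(x$x), ncol(x$x), x$window))
  print(table(x$labels))
  invisible(x)
}

#' Generate distractor frames for rejection testing
#'
#' Random intermediate body configurations matching no trained posture class:
#' arm elevations drawn between the trained templates (at least 20 degrees
#' from every template combination) for the upper body, and partial crouches
#' between standing and sitting for the lower body. Every accepted pose is
#' additionally at least 3 pose-jitter sigmas from each class template in
#' joint space.
#'
#' @param n Number of distractor samples.
#' @param body `"upper"` or `"lower"`.
#' @inheritParams generate_dataset
#' @return Feature matrix with one row per distractor.
#' @export
generate_distractors <- function(n, body = c("upper", "lower"),
                                 subjects = subject_pool(), camera = camera_model(),
                                 jitter_sigma = 0.02, seed = 1L) {
  body <- match.arg(body)
  set.seed(as.integer(seed))
  joint_set <- if (body == "upper") upper_joint_set() else lower_joint_set()
  classes <- if (body == "upper") upper_postures() else lower_postures()
  combos <- lapply(classes, function(cl) POSTURE_TEMPLATES[[cl]]$arms)
  tpl_poses <- lapply(classes, function(cl) pose_local(POSTURE_TEMPLATES[[cl]]))
  x <- matrix(NA_real_, n, 3L * length(joint_set))
  subj_i <- sample(rep_len(seq_along(subjects), n))
  min_sep <- 3 * jitter_sigma
  for (i in seq_len(n)) {
    subj <- subjects[[subj_i[i]]]
    cal <- calibration_for(subj, camera)
    for (try in 1:200) {
      if (body == "upper") {
        # one arm forced into the ambiguous mid range, the other free
        a <- c(stats::runif(1L, 30, 70), stats::runif(1L, 0, 135))
        if (stats::runif(1L) < 0.5) a <- rev(a)
        arms <- c(left = a[1L], right = a[2L])
        near <- any(vapply(combos, function(cb) max(abs(arms - cb)) < 20, logical(1L)))
        if (near) next
        pose <- pose_local(list(arms = arms, legs = "standing"))
      } else {
        pose <- pose_local(list(arms = c(left = 10, right = 10), legs = "standing"),
                           crouch = stats::runif(1L, 0.3, 0.7))
      }
      sep <- min(vapply(tpl_poses, function(tp)
        max(abs((pose - tp)[joint_set, ])) * subj$height, numeric(1L)))
      if (sep < min_sep) next
      r <- render_pose_matrix(pose, subj, camera, jitter_sigma)
      f <- frames_from_render(r, 0)[[1L]]
      ok <- tryCatch({
        x[i, ] <- extract_features(f, joint_set, cal); TRUE
      }, skelwatch_joint_missing = function(e) FALSE)
      if (ok) break
    }
    if (anyNA(x[i, ])) stop_skel("could not render a distractor", "render_failed")
  }
  x
}

# candidate fall/no-fall windows from rendered scripts
slice_head_windows <- function(frames, window) {
  head_ok <- vapply(frames, function(f) f$detected[["head"]], logical(1L))
  xyz <- t(vapply(frames, function(f) {
    p <- f$positions["head", ]; if (any(is.na(p))) c(0, 0, 0) else p
  }, numeric(3L)))
  starts <- which(vapply(seq_len(length(frames) - window + 1L), function(s)
    all(head_ok[s:(s + window - 1L)]), logical(1L)))
  list(xyz = xyz, starts = starts)
}

#' Generate a fall/no-fall training set of head-trajectory windows
#'
#' Renders fall scripts (random direction, descent duration 0.5--1.0 s) and
#' confounder/posture scripts across the subject pool, slices sliding windows
#' of `window` consecutive head positions, and labels a window `fall` when it
#' overlaps the descent or lies on the ground within a fall script; windows
#' from standing/sitting holds, quick sits and bends are `no_fall`.
#'
#' @param n_fall,n_nonfall Target window counts per class.
#' @param window Window length in frames (default 10 at 30 Hz).
#' @inheritParams generate_dataset
#' @return A `posture_dataset` with `joint_set = "head"` and the given window.
#' @export
generate_fall_dataset <- function(n_fall = 600L, n_nonfall = 600L, window = 10L,
                                  subjects = subject_pool(), camera = camera_model(),
                                  jitter_sigma = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  fall_feats <- list(); nonfall_feats <- list()
  script_no <- 0L
  fr <- camera$frame_rate
  while (length(fall_feats) < n_fall || length(nonfall_feats) < n_nonfall) {
    script_no <- script_no + 1L
    subj <- subjects[[(script_no - 1L) %% length(subjects) + 1L]]
    cal <- calibration_for(subj, camera)
    kind <- c("fall", "stand", "sit", "quick_sit", "bend")[(script_no - 1L) %% 5L + 1L]
    sseed <- next_child_seed(seed, script_no)
    if (kind == "fall") {
      dd <- stats::runif(1L, 0.5, 1.0)
      sc <- motion_script(script_hold("standing", 0.8), script_fall(dd, 2.5))
      frames <- render_script(subj, sc, camera, jitter_sigma, sseed)
      # fall phase boundaries in frames (transition 0.4s + hold 0.8s precede)
      fall_t0 <- 0.8
      sw <- slice_head_windows(frames, window)
      for (s in sw$starts) {
        t_end <- frames[[s + window - 1L]]$timestamp
        # skip the ambiguous onset: a window is a clear fall only once its
        # last frame is >= 0.25 s into the descent
        if (t_end > fall_t0 && t_end <= fall_t0 + 0.25) next
        lab_fall <- t_end > fall_t0 + 0.25
        if (lab_fall && length(fall_feats) < n_fall)
          fall_feats[[length(fall_feats) + 1L]] <-
            fall_window_features(sw$xyz[s:(s + window - 1L), , drop = FALSE], cal)
        if (!lab_fall && length(nonfall_feats) < n_nonfall)
          nonfall_feats[[length(nonfall_feats) + 1L]] <-
            fall_window_features(sw$xyz[s:(s + window - 1L), , drop = FALSE], cal)
      }
    } else {
      sc <- switch(kind,
        stand = motion_script(script_hold("standing", 2.0)),
        sit = motion_script(script_hold("standing", 0.5), script_hold("sitting", 1.5)),
        quick_sit = motion_script(script_hold("standing", 0.5), script_quick_sit(1.5)),
        bend = motion_script(script_hold("standing", 0.5), script_bend_down(1.0)))
      frames <- render_script(subj, sc, camera, jitter_sigma, sseed)
      sw <- slice_head_windows(frames, window)
      for (s in sw$starts) {
        if (length(nonfall_feats) >= n_nonfall) break
        nonfall_feats[[length(nonfall_feats) + 1L]] <-
          fall_window_features(sw$xyz[s:(s + window - 1L), , drop = FALSE], cal)
      }
    }
    if (script_no > 50L * (n_fall + n_nonfall)) stop_skel("window generation stalled", "render_failed")
  }
  x <- rbind(do.call(rbind, fall_feats), do.call(rbind, nonfall_feats))
  labs <- c(rep("fall", n_fall), rep("no_fall", n_nonfall))
  ord <- sample(length(labs))
  structure(list(x = x[ord, , drop = FALSE],
                 labels = factor(labs[ord], levels = c("fall", "no_fall")),
                 joint_set = "head", window = as.integer(window),
                 seed = as.integer(seed)),
            class = "posture_dataset")
}
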