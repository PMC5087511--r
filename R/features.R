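# Normalization pipeline feeding the networks. Features are made invariant to
# where the subject stands (body-anchored origin) and how tall they are
# (division by calibrated height), then affinely mapped from [-1, 1] to [0, 1]
# and clipped so they sit in the sigmoid's input range.

UPPER_JOINTS <- c("head", "center_shoulder", "left_shoulder", "right_shoulder",
                  "left_elbow", "right_elbow", "left_hand", "right_hand")

#' Default joint sets
#'
#' Joint subsets feeding the upper-body (15 coordinates from 5 joints: the
#' shoulder midpoint plus elbows and hands) and lower-body (18 coordinates
#' from hips, knees and feet) posture classifiers. The shoulders themselves
#' enter the upper features through the anchor (their midpoint), which both
#' centers the features and stands in for the shoulder pair.
#'
#' @return Ordered character vector of joint names.
#' @export
upper_joint_set <- function() {
  c("center_shoulder", "left_elbow", "right_elbow", "left_hand", "right_hand")
}

#' @rdname upper_joint_set
#' @export
lower_joint_set <- function() {
  c("left_hip", "right_hip", "left_knee", "right_knee", "left_foot", "right_foot")
}

#' @rdname upper_joint_set
#' @export
upper_joint_set18 <- function() {
  # 6-joint variant (both shoulders listed explicitly), 18 inputs
  c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_hand", "right_hand")
}

# anchor point for a posture frame given the joint set
feature_anchor <- function(frame, joint_set) {
  upper <- all(joint_set %in% UPPER_JOINTS)
  if (upper) {
    sh <- c("left_shoulder", "right_shoulder")
    if (all(frame$detected[sh])) return(colMeans(frame$positions[sh, , drop = FALSE]))
    if (frame$detected[["center_shoulder"]]) return(frame$positions["center_shoulder", ])
    stop_skel("joint missing: shoulder anchor (shoulders or center_shoulder)", "joint_missing")
  }
  hp <- c("left_hip", "right_hip")
  if (all(frame$detected[hp])) return(colMeans(frame$positions[hp, , drop = FALSE]))
  stop_skel("joint missing: hip anchor (left_hip, right_hip)", "joint_missing")
}

scale01 <- function(v) pmin(pmax((v + 1) / 2, 0), 1)

# Fall-window features from a W x 3 matrix of head positions. The y origin is
# the calibrated standing head level; x and z are anchored at the first frame
# of the window so the features stay translation invariant. Used both when
# building training sets and per-frame in the monitor.
fall_window_features <- function(head_xyz, calibration) {
  anchor <- c(head_xyz[1L, 1L], calibration$standing_head_y, head_xyz[1L, 3L])
  rel <- sweep(head_xyz, 2L, anchor) / calibration$height
  as.numeric(t(scale01(rel)))  # frame-major: x,y,z per frame, oldest first
}

#' Extract normalized features from skeleton frames
#'
#' Turns one or more frames into the normalized feature vector a classifier
#' consumes. For single-frame posture features, joint positions are translated
#' to a body-anchored origin (shoulder midpoint for upper-body joint sets, hip
#' midpoint for lower-body sets), divided by the calibrated subject height,
#' affinely mapped from \[-1, 1\] to \[0, 1\] and clipped. For multi-frame fall
#' windows (`joint_set = "head"`), the vertical origin is the calibrated
#' standing head level and the horizontal origin is the head position in the
#' oldest frame. Output order is joint-set order with x, y, z per joint, frames
#' concatenated oldest first; length is `3 * length(joint_set) * n_frames`.
#'
#' @param frames A [skel_frame()] or list of frames (oldest first).
#' @param joint_set Ordered character vector of joint names, or `"head"` for
#'   fall windows.
#' @param calibration A [skel_calibration()].
#' @return Numeric feature vector in \[0, 1\] with attributes `joint_set` and
#'   `window`.
#' @export
extract_features <- function(frames, joint_set, calibration) {
  stopifnot(inherits(calibration, "skel_calibration"))
  if (inherits(frames, "skel_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  if (identical(joint_set, "head")) {
    head_xyz <- t(vapply(frames, function(f) {
      if (!f$detected[["head"]]) stop_skel("joint missing: head", "joint_missing")
      f$positions["head", ]
    }, numeric(3L)))
    vals <- fall_window_features(head_xyz, calibration)
    return(structure(vals, joint_set = "head", window = length(frames)))
  }
  bad <- setdiff(joint_set, JOINT_NAMES)
  if (length(bad)) stop_skel(paste("unknown joints:", paste(bad, collapse = ", ")), "bad_joint")
  vals <- unlist(lapply(frames, function(f) {
    missing <- joint_set[!f$detected[joint_set]]
    if (length(missing))
      stop_skel(paste("joint missing:", paste(missing, collapse = ", ")), "joint_missing")
    anchor <- feature_anchor(f, joint_set)
    rel <- sweep(f$positions[joint_set, , drop = FALSE], 2L, anchor) / calibration$height
    as.numeric(t(scale01(rel)))
  }), use.names = FALSE)
  structure(vals, joint_set = joint_set, window = length(frames))
}
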