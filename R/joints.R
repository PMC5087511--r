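# Joint-coordinate data model: named body joints, per-frame 3D positions in
# the camera frame (x right, y up, z depth away from the camera, meters).

JOINT_NAMES <- c(
  "head", "center_shoulder", "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow", "left_hand", "right_hand",
  "left_hip", "right_hip", "left_knee", "right_knee",
  "left_foot", "right_foot"
)

#' Body joint names
#'
#' The closed set of named body joints tracked per frame.
#'
#' @return Character vector of the 14 joint names.
#' @export
skel_joints <- function() JOINT_NAMES

stop_skel <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("skelwatch_", class), "skelwatch_error")))
}

#' Construct a skeleton frame
#'
#' A timestamped mapping from named body joints to 3D positions. A joint has a
#' position iff it was detected; undetected joints carry `NA` rows.
#'
#' @param timestamp Time of the frame in seconds.
#' @param positions Named list of length-3 numeric vectors (x, y, z in meters,
#'   camera frame), or a 14 x 3 matrix with joint names as row names. Joints
#'   absent from the list are marked undetected.
#' @return An object of class `skel_frame` with elements `timestamp`,
#'   `positions` (14 x 3 matrix, `NA` rows for undetected joints) and
#'   `detected` (named logical).
#' @examples
#' f <- skel_frame(0, list(head = c(0, 1.7, 2.5), left_foot = c(0.1, -0.1, 2.5)))
#' f$detected[["head"]]
#' @export
skel_frame <- function(timestamp, positions) {
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L, is.finite(timestamp))
  pos <- matrix(NA_real_, nrow = length(JOINT_NAMES), ncol = 3L,
                dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  if (is.matrix(positions)) {
    bad <- setdiff(rownames(positions), JOINT_NAMES)
    if (length(bad)) stop_skel(paste("unknown joints:", paste(bad, collapse = ", ")), "bad_joint")
    pos[rownames(positions), ] <- positions
  } else if (is.list(positions)) {
    bad <- setdiff(names(positions), JOINT_NAMES)
    if (length(bad)) stop_skel(paste("unknown joints:", paste(bad, collapse = ", ")), "bad_joint")
    for (j in names(positions)) {
      p <- positions[[j]]
      stopifnot(is.numeric(p), length(p) == 3L)
      pos[j, ] <- p
    }
  } else stop_skel("positions must be a named list or matrix", "bad_frame")
  det <- stats::setNames(rowSums(is.na(pos)) == 0L, JOINT_NAMES)
  if (any(is.finite(pos[det, "z"]) & pos[det, "z"] <= 0)) {
    # depth must be positive for a detected joint; tolerate only via explicit NA
    stop_skel("detected joints must have z > 0", "bad_frame")
  }
  structure(list(timestamp = timestamp, positions = pos, detected = det),
            class = "skel_frame")
}

#' @export
print.skel_frame <- function(x, ...) {
  cat(sprintf("<skel_frame t=%.3fs, %d/%d joints detected>\n",
              x$timestamp, sum(x$detected), length(x$detected)))
  invisible(x)
}

joint_pos <- function(frame, joint) frame$positions[joint, ]

joints_detected <- function(frame, joints) all(frame$detected[joints])

#' Estimate subject height from a standing frame
#'
#' Height is the vertical distance between the head and the feet: the head
#' y-coordinate minus the mean y of the detected feet. A single detected foot
#' is accepted as a fallback for partial tracking.
#'
#' @param frame A [skel_frame()] with the head and at least one foot detected.
#' @return Height in meters (positive).
#' @examples
#' f <- skel_frame(0, list(head = c(0, 1.7, 2.5),
#'                         left_foot = c(0.1, -0.1, 2.5),
#'                         right_foot = c(-0.1, -0.1, 2.5)))
#' estimate_height(f) # 1.8
#' @export
estimate_height <- function(frame) {
  stopifnot(inherits(frame, "skel_frame"))
  feet <- c("left_foot", "right_foot")
  det <- frame$detected
  if (!det[["head"]] || !any(det[feet]))
    stop_skel("calibration impossible: head and at least one foot must be detected",
              "calibration_impossible")
  h <- frame$positions["head", "y"] - mean(frame$positions[feet[det[feet]], "y", drop = TRUE])
  if (!is.finite(h) || h <= 0)
    stop_skel("calibration impossible: non-positive height", "calibration_impossible")
  h
}

#' Subject calibration
#'
#' Stores the subject height and the head y-coordinate observed while standing,
#' both in the coordinate frame of the camera session they were measured in.
#' The standing head level anchors fall-window features, so it must come from
#' the same camera setup the features are later extracted in.
#'
#' @param height Subject height in meters (0.5 < height < 2.5).
#' @param standing_head_y Head y-coordinate while standing, camera frame, meters.
#' @return An object of class `skel_calibration`.
#' @export
skel_calibration <- function(height, standing_head_y) {
  stopifnot(is.numeric(height), length(height) == 1L,
            is.numeric(standing_head_y), length(standing_head_y) == 1L)
  if (!is.finite(height) || height <= 0.5 || height >= 2.5)
    stop_skel("implausible subject height (must be in (0.5, 2.5) m)", "calibration_impossible")
  structure(list(height = height, standing_head_y = standing_head_y),
            class = "skel_calibration")
}

#' Calibrate a subject from a standing frame
#'
#' @param frame A standing [skel_frame()] with head and feet visible.
#' @return A [skel_calibration()] with height from [estimate_height()] and
#'   `standing_head_y` set to the observed head y.
#' @export
calibrate_subject <- function(frame) {
  skel_calibration(estimate_height(frame), frame$positions["head", "y"])
}

#' Ratio-based standing/sitting baseline
#'
#' The simple first-pass posture rule: a standing person keeps a head-to-knee
#' vertical distance of at least two thirds of their height; sitting roughly
#' halves that proportion. The boundary case (distance exactly 2/3 of height)
#' is assigned to standing.
#'
#' @param frame A [skel_frame()] with head and at least one knee detected.
#' @param calibration A [skel_calibration()].
#' @return `"standing"` or `"sitting"`.
#' @export
ratio_posture <- function(frame, calibration) {
  stopifnot(inherits(frame, "skel_frame"), inherits(calibration, "skel_calibration"))
  knees <- c("left_knee", "right_knee")
  det <- frame$detected
  if (!det[["head"]] || !any(det[knees]))
    stop_skel("joint missing: head and at least one knee required", "joint_missing")
  knee_y <- mean(frame$positions[knees[det[knees]], "y", drop = TRUE])
  dist <- frame$positions["head", "y"] - knee_y
  if (dist >= (2 / 3) * calibration$height) "standing" else "sitting"
}
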