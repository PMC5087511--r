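# Classifier bundles: a trained perceptron plus everything needed to apply it
# to raw frames (joint set, window length, decoding thresholds).

#' Construct a posture dataset
#'
#' Container pairing a feature matrix with labels and the metadata the
#' features were extracted under.
#'
#' @param x Numeric feature matrix, values in \[0, 1\].
#' @param labels Factor (or character) class labels, one per row.
#' @param joint_set Ordered joint names (or `"head"` for fall windows).
#' @param window Frames per sample (1 for postures).
#' @param seed Seed recorded for provenance.
#' @return Object of class `posture_dataset`.
#' @export
posture_dataset <- function(x, labels, joint_set, window = 1L, seed = NA_integer_) {
  x <- as.matrix(x)
  labels <- if (is.factor(labels)) labels else factor(labels)
  stopifnot(nrow(x) == length(labels))
  nf <- if (identical(joint_set, "head")) 3L * window else 3L * length(joint_set) * window
  if (ncol(x) != nf)
    stop_skel(sprintf("feature length %d does not match joint set/window (%d expected)",
                      ncol(x), nf), "shape")
  structure(list(x = x, labels = labels, joint_set = joint_set,
                 window = as.integer(window), seed = seed),
            class = "posture_dataset")
}

check_classes <- function(dataset, expected) {
  missing <- setdiff(expected, as.character(unique(dataset$labels)))
  if (length(missing))
    stop_skel(paste("classes absent from training data:", paste(missing, collapse = ", ")),
              "missing_class")
}

build_classifier <- function(dataset, expected_classes, n_in, n_hidden,
                             confidence_threshold = 0.5, margin = 0.05, ...) {
  stopifnot(inherits(dataset, "posture_dataset"))
  if (nrow(dataset$x) == 0L) stop_skel("empty training set", "bad_inputs")
  if (ncol(dataset$x) != n_in)
    stop_skel(sprintf("dataset has %d features, classifier expects %d", ncol(dataset$x), n_in),
              "shape")
  check_classes(dataset, expected_classes)
  net <- mlp(dataset$x, factor(dataset$labels, levels = expected_classes),
             n_hidden = n_hidden, ...)
  structure(list(mlp = net, joint_set = dataset$joint_set,
                 window = dataset$window,
                 confidence_threshold = confidence_threshold, margin = margin),
            class = "classifier_bundle")
}

#' Build the upper-body posture classifier
#'
#' 15 inputs (shoulder midpoint, elbows, hands), 5 posture classes; default
#' 12 hidden neurons. All five classes must be present in the training data.
#'
#' @param dataset A [posture_dataset()] of upper-body features.
#' @param n_hidden Hidden neurons (default 12).
#' @param confidence_threshold,margin Decoding rule for [classify_frame()].
#' @param ... Passed to [mlp()] (`learning_rate`, `max_epochs`, `seed`, ...).
#' @return A `classifier_bundle`.
#' @export
build_upper_classifier <- function(dataset, n_hidden = 12L,
                                   confidence_threshold = 0.5, margin = 0.05, ...) {
  if (!all(dataset$joint_set %in% UPPER_JOINTS))
    stop_skel("dataset joint set is not an upper-body joint set", "shape")
  n_in <- 3L * length(dataset$joint_set)
  build_classifier(dataset, upper_postures(), n_in, n_hidden,
                   confidence_threshold, margin, ...)
}

#' Build the lower-body posture classifier
#'
#' 18 inputs (hips, knees, feet), standing/sitting; default 10 hidden neurons.
#'
#' @inheritParams build_upper_classifier
#' @return A `classifier_bundle`.
#' @export
build_lower_classifier <- function(dataset, n_hidden = 10L,
                                   confidence_threshold = 0.5, margin = 0.05, ...) {
  build_classifier(dataset, lower_postures(), 18L, n_hidden,
                   confidence_threshold, margin, ...)
}

#' Build the fall/no-fall classifier
#'
#' Consumes sliding windows of consecutive head positions (default 10 frames,
#' about a third of a second at 30 Hz), 3 x window inputs, 2 outputs.
#'
#' @inheritParams build_upper_classifier
#' @param n_hidden Hidden neurons; defaults to [size_hidden()].
#' @return A `classifier_bundle`.
#' @export
build_fall_classifier <- function(dataset, n_hidden = NULL,
                                  confidence_threshold = 0.5, margin = 0.05, ...) {
  n_in <- 3L * dataset$window
  n_hidden <- n_hidden %||% size_hidden(n_in, 2L)
  build_classifier(dataset, c("fall", "no_fall"), n_in, n_hidden,
                   confidence_threshold, margin, ...)
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle: %s | window %d | threshold %.2f margin %.2f>\n",
              paste(x$joint_set, collapse = ","), x$window,
              x$confidence_threshold, x$margin))
  print(x$mlp)
  invisible(x)
}

#' Classify skeleton frames with a bundle
#'
#' Extracts features with the bundle's joint set and window, forwards them
#' through the network and decodes the label. For a fall bundle, a missing
#' head yields `"no-observation"` (the camera cannot see the subject's head);
#' for posture bundles a missing required joint raises a joint-missing error.
#'
#' @param bundle A `classifier_bundle`.
#' @param frames A [skel_frame()] or list of `window` frames (oldest first).
#' @param calibration A [skel_calibration()].
#' @return Class label, `"none"` (low confidence) or `"no-observation"`.
#' @export
classify_frame <- function(bundle, frames, calibration) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  if (inherits(frames, "skel_frame")) frames <- list(frames)
  if (length(frames) != bundle$window)
    stop_skel(sprintf("expected %d frame(s), got %d", bundle$window, length(frames)), "shape")
  if (identical(bundle$joint_set, "head")) {
    if (!all(vapply(frames, function(f) f$detected[["head"]], logical(1L))))
      return("no-observation")
  }
  feats <- extract_features(frames, bundle$joint_set, calibration)
  predict(bundle$mlp, feats, threshold = bundle$confidence_threshold,
          margin = bundle$margin)
}
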