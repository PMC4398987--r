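feature_orientations <- c(
  duration = "reject_below",
  instability = "reject_above",
  shape_change = "reject_above",
  edge_density = "reject_above",
  texture_variation = "reject_above"
)

#' Estimate a safe rejection threshold for one feature
#'
#' Walks a grid anchored at 0 with the given step and fixes the threshold
#' at the value that (a) keeps every true detection in the accepted subset
#' and (b) makes that subset minimal on the grid. For `reject_above`
#' features this is the smallest grid value at or above the maximum true
#' value; for `reject_below` (duration) the largest grid value at or below
#' the minimum true value. False-positive values do not move the threshold
#' -- they only determine how many false detections the safe value happens
#' to reject.
#'
#' @param tp_values feature values of true detections (non-empty).
#' @param fp_values feature values of false detections (may be empty).
#' @param orientation `"reject_above"` or `"reject_below"`.
#' @param step positive grid step.
#' @param feature optional feature name to record.
#' @return an object of class `threshold_rule`: `feature`, `orientation`,
#'   `threshold`, `step`, and `n_fp_rejected` on the calibration data.
#' @export
estimate_safe_threshold <- function(tp_values, fp_values = numeric(),
                                    orientation = c("reject_above",
                                                    "reject_below"),
                                    step, feature = NA_character_) {
  orientation <- match.arg(orientation)
  if (length(tp_values) == 0L) stop("'tp_values' must be non-empty")
  if (step <= 0) stop("'step' must be positive")
  threshold <- if (orientation == "reject_above")
    step * ceiling(max(tp_values) / step)
  else
    step * floor(min(tp_values) / step)
  rejected <- if (orientation == "reject_above")
    fp_values > threshold else fp_values < threshold
  structure(
    list(feature = feature, orientation = orientation,
         threshold = threshold, step = step,
         n_fp_rejected = sum(rejected)),
    class = "threshold_rule"
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<rule %s: %s %g (step %g)>\n",
              x$feature, if (x$orientation == "reject_above") ">" else "<",
              x$threshold, x$step))
  invisible(x)
}

#' Calibrate safe-threshold rules from a labeled feature table
#'
#' One rule per feature, each estimated independently with
#' [estimate_safe_threshold()]. Orientations are fixed by the features'
#' meaning: long duration is good (`reject_below`); high instability,
#' shape change, edge density and texture variation are suspicious
#' (`reject_above`). The default step per feature is 1/100 of the observed
#' value range.
#'
#' @param features feature table (see [feature_table()]).
#' @param labels logical vector, `TRUE` for true detections.
#' @param steps optional named numeric of per-feature steps.
#' @param use which features to calibrate (default all five).
#' @return named list of `threshold_rule`s.
#' @export
calibrate_rules <- function(features, labels,
                            steps = NULL,
                            use = names(feature_orientations)) {
  stopifnot(nrow(features) == length(labels))
  if (!any(labels)) stop("no true detections in the calibration set")
  lapply(stats::setNames(use, use), function(f) {
    v <- features[[f]]
    step <- if (!is.null(steps) && !is.na(steps[f])) steps[[f]]
    else max(diff(range(v)) / 100, 1e-6)
    estimate_safe_threshold(v[labels], v[!labels],
                            feature_orientations[[f]], step, feature = f)
  })
}

#' Validate tracks by thresholded features combined with logical AND
#'
#' A track is confirmed only if it passes every rule; a single rejecting
#' feature rejects the whole track. Comparisons are strict
#' (`value > threshold` rejects for `reject_above`), so values exactly at
#' the calibrated safe threshold pass. An empty rule list accepts
#' everything (validation disabled).
#'
#' @param features feature table with one row per track.
#' @param rules list of `threshold_rule`s.
#' @return logical vector, `TRUE` = accepted.
#' @export
validate_tracks <- function(features, rules) {
  ok <- rep(TRUE, nrow(features))
  for (rule in rules) {
    if (!rule$feature %in% names(features))
      stop("no feature column for rule '", rule$feature, "'")
    v <- features[[rule$feature]]
    rej <- if (rule$orientation == "reject_above")
      v > rule$threshold else v < rule$threshold
    ok <- ok & !rej
  }
  ok
}

#' @rdname validate_tracks
#' @param feature_vector one-row feature data frame.
#' @return `validate_track()`: a single logical.
#' @export
validate_track <- function(feature_vector, rules) {
  validate_tracks(feature_vector, rules)[1]
}

#' Train an SVM validator on spatiotemporal features
#'
#' The alternative to threshold validation: a binary SVM over the
#' five-feature space, fitted on labeled tracks. Accuracy is estimated by
#' fivefold cross-validation.
#'
#' @param features feature table.
#' @param labels logical (`TRUE` = true detection) or two-level factor.
#' @param kernel `"linear"`, `"rbf"` or `"polynomial"`.
#' @param ... passed on to [e1071::svm()] (e.g. `gamma`, `degree`).
#' @return an object of class `svm_validator` with a `predict()` method
#'   returning logicals.
#' @export
train_svm_validator <- function(features, labels,
                                kernel = c("linear", "rbf", "polynomial"),
                                ...) {
  kernel <- match.arg(kernel)
  y <- if (is.logical(labels))
    factor(ifelse(labels, "true", "false"), levels = c("false", "true"))
  else factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(features[, c("duration", "instability", "shape_change",
                              "edge_density", "texture_variation")])
  k <- c(linear = "linear", rbf = "radial", polynomial = "polynomial")[kernel]
  fit <- e1071::svm(x, y, kernel = k, cross = 5, ...)
  structure(list(fit = fit, kernel = kernel,
                 cv_accuracy = fit$tot.accuracy / 100),
            class = "svm_validator")
}

#' @export
print.svm_validator <- function(x, ...) {
  cat(sprintf("SVM validator (%s kernel), fivefold CV accuracy %.2f%%\n",
              x$kernel, 100 * x$cv_accuracy))
  invisible(x)
}

#' @export
predict.svm_validator <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, c("duration", "instability", "shape_change",
                             "edge_density", "texture_variation")])
  as.character(stats::predict(object$fit, x)) == "true"
}

#' Serialize threshold rules to YAML
#'
#' @param rules list of `threshold_rule`s.
#' @param path output file.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(lapply(unname(rules), function(r)
    list(feature = r$feature, orientation = r$orientation,
         threshold = r$threshold, step = r$step)), path)
  invisible(path)
}

#' @rdname write_rules
#' @return `read_rules()`: the restored named rule list.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(r)
    structure(list(feature = r$feature, orientation = r$orientation,
                   threshold = r$threshold, step = r$step,
                   n_fp_rejected = NA_integer_),
              class = "threshold_rule"))
  stats::setNames(rules, vapply(rules, `[[`, character(1), "feature"))
}
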