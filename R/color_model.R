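#' Extract labeled color samples from a training image
#'
#' Splits a labeled image into a foreground image and a background image,
#' preprocesses and segments each side independently, and returns one color
#' sample per segment: its mean LUV color tagged with the side's label.
#' Internally the other side's pixels are replaced by a sentinel color far
#' outside the LUV gamut so that mean-shift never fuses regions across the
#' label boundary; sentinel segments are discarded.
#'
#' @param image an RGB [et_frame()].
#' @param mask logical (or 0/1) matrix at the image's native size; `TRUE`
#'   marks foreground (the animal).
#' @param scale working-scale fraction passed to [preprocess_frame()].
#' @param spatial_bandwidth,range_bandwidth,min_segment_size segmentation
#'   parameters, see [mean_shift_segment()].
#' @return data frame of color samples with columns `L`, `u`, `v`,
#'   `label` (`"foreground"`/`"background"`) and `source`.
#' @export
extract_training_colors <- function(image, mask, scale = 0.25,
                                    spatial_bandwidth = 8,
                                    range_bandwidth = 8,
                                    min_segment_size = 20) {
  stopifnot(inherits(image, "et_frame"), image$space == "RGB")
  mask <- mask != 0
  if (!all(dim(mask) == c(image$height, image$width)))
    stop("mask dimensions must match the image")
  luv <- preprocess_frame(image, scale)
  # mask at working scale: area-average occupancy >= 0.5
  occ <- resize_area(array(as.numeric(mask), c(dim(mask), 1)), scale)[, , 1]
  mask_s <- occ >= 0.5
  if (all(mask_s) || !any(mask_s))
    warning("mask selects only one class; only one side will yield samples")
  side <- function(keep, label) {
    if (!any(keep)) return(NULL)
    px <- luv$pixels
    sent <- !keep
    px[, , 1][sent] <- -1000; px[, , 2][sent] <- 0; px[, , 3][sent] <- 0
    sm <- mean_shift_segment(et_frame(px, luv$index, "LUV"),
                             spatial_bandwidth, range_bandwidth,
                             min_segment_size)
    cols <- t(vapply(sm$segments, `[[`, numeric(3), "mean_color"))
    real <- cols[, 1] > -100
    if (!any(real)) return(NULL)
    data.frame(L = cols[real, 1], u = cols[real, 2], v = cols[real, 3],
               label = label, source = "segment_mean")
  }
  out <- rbind(side(mask_s, "foreground"), side(!mask_s, "background"))
  rownames(out) <- NULL
  out
}

#' Remove near-black and near-white foreground colors
#'
#' Very dark and very bright colors cannot be classified reliably; removing
#' them from the foreground list means such segments are rejected at
#' detection time. Limits are percentages of the theoretical L range
#' (0--100). Background samples pass through untouched. `(0, 100)` is the
#' identity (filter off); `(10, 90)` and `(20, 80)` are the medium and
#' strong settings.
#'
#' @param samples color-sample data frame (see [extract_training_colors()]).
#' @param lower_pct,upper_pct keep foreground samples with
#'   `lower_pct <= L <= upper_pct` (L in 0--100).
#' @return filtered sample data frame.
#' @export
luminance_filter <- function(samples, lower_pct = 0, upper_pct = 100) {
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("require 0 <= lower_pct < upper_pct <= 100")
  drop <- samples$label == "foreground" &
    (samples$L < lower_pct | samples$L > upper_pct)
  samples[!drop, , drop = FALSE]
}

default_gamma_grid <- function() 10^seq(-3, 2, by = 1)

#' Train the discriminative foreground/background color model
#'
#' Fits a binary classifier over LUV colors. The default backend is a
#' support vector machine with a radial basis function kernel. Class
#' weights are inverse-frequency balanced (the background color list is
#' always much longer than the foreground list), and on top of that the
#' foreground class carries `cost_ratio` times the background's
#' misclassification cost, which biases the detector towards a high
#' detection rate (false positives are handled later by spatiotemporal
#' validation). The RBF width `gamma` is selected from `gamma_grid` as the
#' value yielding the fewest support vectors (ties go to the smaller gamma,
#' i.e. the smoother boundary). Foreground samples are passed through
#' [luminance_filter()] with `luminance_limits` before fitting. Training
#' accuracy is estimated by fivefold cross-validation.
#'
#' @param samples color-sample data frame with both classes present.
#' @param cost_ratio foreground/background misclassification cost ratio
#'   (>= 1).
#' @param gamma_grid candidate RBF widths.
#' @param luminance_limits `c(lower_pct, upper_pct)` for the luminance
#'   filter.
#' @param backend optional custom classifier backend: a list with elements
#'   `name`, `fit(x, y)` and `predict(fit, x)` (y and the return of predict
#'   are factors with levels background/foreground). When supplied,
#'   `gamma_grid` is ignored.
#' @return an object of class `color_model` with elements `fit`, `gamma`,
#'   `cost_ratio`, `luminance_limits`, `cv_accuracy`, `n_sv`, `backend`.
#' @export
train_color_model <- function(samples, cost_ratio = 2,
                              gamma_grid = default_gamma_grid(),
                              luminance_limits = c(0, 100),
                              backend = NULL) {
  samples <- luminance_filter(samples, luminance_limits[1],
                              luminance_limits[2])
  if (!all(c("foreground", "background") %in% samples$label)) {
    if (!any(samples$label == "foreground"))
      stop("no foreground samples remain (check the luminance filter)")
    stop("both classes must be present in 'samples'")
  }
  x <- as.matrix(samples[, c("L", "u", "v")])
  y <- factor(samples$label, levels = c("background", "foreground"))
  if (!is.null(backend)) {
    fit <- backend$fit(x, y)
    model <- list(fit = fit, gamma = NA_real_, cost_ratio = cost_ratio,
                  luminance_limits = luminance_limits,
                  cv_accuracy = cv_accuracy_backend(backend, x, y),
                  n_sv = NA_integer_, backend = backend)
    return(structure(model, class = "color_model"))
  }
  if (length(gamma_grid) == 0L) stop("'gamma_grid' must be non-empty")
  if (cost_ratio < 1) stop("'cost_ratio' must be >= 1")
  n_by_class <- table(y)
  wts <- c(background = 1,
           foreground = cost_ratio *
             unname(n_by_class["background"] / n_by_class["foreground"]))
  fits <- lapply(sort(gamma_grid), function(g)
    e1071::svm(x, y, kernel = "radial", gamma = g, cost = 1,
               class.weights = wts, scale = TRUE))
  nsv <- vapply(fits, function(f) f$tot.nSV, integer(1))
  best <- which.min(nsv)   # ties: which.min takes the first = smallest gamma
  gamma <- sort(gamma_grid)[best]
  cv <- e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = 1,
                   class.weights = wts, scale = TRUE, cross = 5)
  structure(
    list(fit = fits[[best]], gamma = gamma, cost_ratio = cost_ratio,
         luminance_limits = luminance_limits,
         cv_accuracy = cv$tot.accuracy / 100,
         n_sv = nsv[best], backend = NULL),
    class = "color_model"
  )
}

# fivefold CV accuracy for a custom backend, deterministic fold assignment
cv_accuracy_backend <- function(backend, x, y) {
  n <- nrow(x)
  fold <- rep(seq_len(5), length.out = n)
  acc <- vapply(seq_len(5), function(k) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) return(NA_real_)
    f <- backend$fit(x[tr, , drop = FALSE], y[tr])
    mean(backend$predict(f, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

#' @export
print.color_model <- function(x, ...) {
  nm <- if (is.null(x$backend)) "RBF-SVM" else x$backend$name
  cat(sprintf("Color model (%s)\n", nm))
  if (is.null(x$backend))
    cat(sprintf("  gamma %.4g, %d support vectors\n", x$gamma, x$n_sv))
  cat(sprintf("  cost ratio fg/bg: %.2f\n", x$cost_ratio))
  cat(sprintf("  luminance filter: (%g, %g)\n",
              x$luminance_limits[1], x$luminance_limits[2]))
  cat(sprintf("  fivefold CV accuracy: %.2f%%\n", 100 * x$cv_accuracy))
  invisible(x)
}

#' Classify LUV colors with a color model
#'
#' @param object a `color_model`.
#' @param newdata N x 3 matrix of LUV colors.
#' @param ... unused.
#' @return logical vector, `TRUE` = foreground.
#' @export
predict.color_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = 3L)
  colnames(newdata) <- c("L", "u", "v")
  pred <- if (is.null(object$backend))
    stats::predict(object$fit, newdata)
  else
    object$backend$predict(object$fit, newdata)
  as.character(pred) == "foreground"
}

#' Classify one segment as candidate or background
#'
#' One-stage classification decides on the segment's mean color alone.
#' Two-stage classification classifies every pixel of the segment with the
#' same color model and accepts the segment only if the fraction of
#' positively classified pixels is strictly above `vote_threshold`
#' (two thirds by default) -- a majority vote that is robust against
#' segments whose mean color resembles the foreground while their pixel
#' colors do not.
#'
#' @param model a `color_model`.
#' @param segment an `et_segment`.
#' @param frame the LUV frame the segment was extracted from (required for
#'   two-stage mode).
#' @param mode `"two_stage"` or `"one_stage"`.
#' @param vote_threshold strict acceptance threshold in (0, 1).
#' @return `TRUE` if the segment is a candidate detection.
#' @export
classify_segment <- function(model, segment, frame = NULL,
                             mode = c("two_stage", "one_stage"),
                             vote_threshold = 2 / 3) {
  mode <- match.arg(mode)
  if (vote_threshold <= 0 || vote_threshold >= 1)
    stop("'vote_threshold' must be in (0, 1)")
  if (mode == "one_stage")
    return(predict(model, matrix(segment$mean_color, 1)))
  if (is.null(frame)) stop("two-stage mode needs the LUV frame")
  if (frame$index != segment$frame_index ||
      !all(dim(frame) == segment$dim))
    stop("segment does not belong to 'frame'")
  px <- matrix(frame$pixels, ncol = 3L)[segment$pixels, , drop = FALSE]
  mean(predict(model, px)) > vote_threshold
}

#' Detect candidate segments in a frame
#'
#' Applies [classify_segment()] to every segment of a segmentation and
#' keeps the segments predicted to be foreground. Pixel predictions are
#' batched across segments for speed; the result is order-independent.
#'
#' @param model a `color_model`.
#' @param seg_map a `segment_map` built from `frame`.
#' @param frame the LUV frame.
#' @param mode,vote_threshold see [classify_segment()].
#' @return list of candidate `et_segment`s.
#' @export
detect_candidates <- function(model, seg_map, frame,
                              mode = c("two_stage", "one_stage"),
                              vote_threshold = 2 / 3) {
  mode <- match.arg(mode)
  segs <- seg_map$segments
  if (length(segs) == 0L) return(list())
  if (mode == "one_stage") {
    cols <- t(vapply(segs, `[[`, numeric(3), "mean_color"))
    keep <- predict(model, cols)
  } else {
    if (frame$index != seg_map$frame_index)
      stop("'seg_map' was not built from 'frame'")
    pxm <- matrix(frame$pixels, ncol = 3L)
    pos <- predict(model, pxm)
    keep <- vapply(segs, function(s)
      mean(pos[s$pixels]) > vote_threshold, logical(1))
  }
  segs[keep]
}

#' Serialize a color model to a self-describing file
#'
#' A single versioned JSON document: backend name, hyperparameters,
#' luminance limits and CV accuracy in the header, and the fitted
#' classifier as a base64-encoded serialized payload.
#'
#' @param model a `color_model` (custom backends are not serializable).
#' @param path output file.
#' @export
write_color_model <- function(model, path) {
  if (!is.null(model$backend))
    stop("custom-backend models cannot be serialized")
  doc <- list(
    format = "elephtrack-color-model", version = 1L,
    backend = "rbf_svm", gamma = model$gamma,
    cost_ratio = model$cost_ratio,
    luminance_limits = model$luminance_limits,
    cv_accuracy = model$cv_accuracy, n_sv = model$n_sv,
    payload = jsonlite::base64_enc(serialize(model$fit, NULL))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_color_model
#' @param path input file.
#' @return the restored `color_model`.
#' @export
read_color_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "elephtrack-color-model"))
    stop("not a color-model file")
  structure(
    list(fit = unserialize(jsonlite::base64_dec(doc$payload)),
         gamma = doc$gamma, cost_ratio = doc$cost_ratio,
         luminance_limits = doc$luminance_limits,
         cv_accuracy = doc$cv_accuracy, n_sv = doc$n_sv, backend = NULL),
    class = "color_model"
  )
}
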