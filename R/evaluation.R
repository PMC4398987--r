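#' Spatiotemporal ground truth
#'
#' Per-frame label masks of the regions to detect. Animals whose image
#' regions overlap form one ground-truth region. The evaluation counting
#' unit is the frame-level region instance aggregated over the sequence.
#'
#' @param masks list (one per frame) of integer label matrices; 0 is
#'   background, region ids are unique within a frame.
#' @param regions optional data frame `(frame, id, occluded)`; derived from
#'   `masks` when omitted (with `occluded = FALSE`).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(masks, regions = NULL) {
  stopifnot(length(masks) >= 1L)
  if (is.null(regions)) {
    regions <- do.call(rbind, lapply(seq_along(masks), function(i) {
      ids <- setdiff(sort(unique(as.vector(masks[[i]]))), 0L)
      if (length(ids) == 0L) return(NULL)
      data.frame(frame = i - 1L, id = ids, occluded = FALSE)
    }))
    if (is.null(regions))
      regions <- data.frame(frame = integer(), id = integer(),
                            occluded = logical())
  }
  structure(list(masks = masks, regions = regions,
                 dim = dim(masks[[1]]), n_frames = length(masks)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d frames, %d region instances>\n",
              x$n_frames, nrow(x$regions)))
  invisible(x)
}

#' Match per-frame detections against ground truth
#'
#' A detection hits a ground-truth region if their pixel overlap divided by
#' the detection's area reaches `min_overlap` (any positive overlap when
#' `min_overlap = 0`). A region hit by several detections is counted once.
#' Detections hitting no region are false detections; a detection that
#' overlaps both a region and background counts as a hit, not as false
#' (set `strict_background = TRUE` to flip that reading: any background
#' overlap above `1 - min_overlap` of the detection does not occur --
#' instead, under the strict reading a detection must not contain any
#' ground-truth-free majority, i.e. it is false unless at least half its
#' area lies on regions).
#'
#' @param detections list (one per frame) of lists of detection masks
#'   (logical matrices or integer pixel-index vectors).
#' @param gt a [ground_truth()].
#' @param min_overlap required overlap fraction of the detection area.
#' @param strict_background alternative false-detection reading (see
#'   above); default `FALSE`.
#' @return list of class `detection_match`: `hits` data frame
#'   `(frame, id)`, `false` data frame `(frame, det)`, `n_detections`,
#'   `n_regions`.
#' @export
match_detections <- function(detections, gt, min_overlap = 0,
                             strict_background = FALSE) {
  if (min_overlap < 0 || min_overlap > 1)
    stop("'min_overlap' must be in [0, 1]")
  hits <- list(); falses <- list()
  n_det <- 0L
  for (f in seq_along(detections)) {
    dets <- detections[[f]]
    if (length(dets) == 0L) next
    lab <- gt$masks[[f]]
    if (is.null(lab)) stop("ground truth missing for frame ", f - 1L)
    for (j in seq_along(dets)) {
      d <- dets[[j]]
      px <- if (is.matrix(d)) which(d) else d
      if (is.matrix(d) && !all(dim(d) == dim(lab)))
        stop("detection/ground-truth grid mismatch")
      n_det <- n_det + 1L
      if (length(px) == 0L) next
      on <- lab[px]
      ov <- tabulate(on[on > 0L])
      frac <- ov / length(px)
      hit_ids <- if (min_overlap == 0) which(frac > 0)
      else which(frac >= min_overlap)
      is_hit <- length(hit_ids) > 0L &&
        (!strict_background || sum(frac[hit_ids]) >= 0.5)
      if (is_hit)
        hits[[length(hits) + 1L]] <-
          data.frame(frame = f - 1L, id = hit_ids)
      else
        falses[[length(falses) + 1L]] <-
          data.frame(frame = f - 1L, det = j)
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits))
  else data.frame(frame = integer(), id = integer())
  falses <- if (length(falses)) do.call(rbind, falses)
  else data.frame(frame = integer(), det = integer())
  structure(list(hits = hits, false = falses, n_detections = n_det,
                 n_regions = nrow(gt$regions)),
            class = "detection_match")
}

#' Detection rate
#'
#' Number of ground-truth regions hit by a detection divided by the total
#' number of ground-truth regions (frame-level instances).
#'
#' @param match a `detection_match`.
#' @return fraction in `[0, 1]`.
#' @export
detection_rate <- function(match) {
  if (match$n_regions == 0L) stop("no ground-truth regions")
  nrow(match$hits) / match$n_regions
}

#' False-positive rate
#'
#' Number of false detections divided by the total number of detections;
#' defined as 0 when there are no detections.
#'
#' @param match a `detection_match`.
#' @return fraction in `[0, 1]`.
#' @export
false_positive_rate <- function(match) {
  if (match$n_detections == 0L) return(0)
  nrow(match$false) / match$n_detections
}

# per-frame detection masks from a list of tracks
tracks_to_detections <- function(tracks, n_frames) {
  out <- vector("list", n_frames)
  for (tr in tracks) {
    for (f in tr$frames) {
      out[[f + 1L]] <- c(out[[f + 1L]], list(tr$masks[[as.character(f)]]))
    }
  }
  out
}

#' Evaluate tracks against ground truth
#'
#' Converts tracks to per-frame detections, matches them against the
#' ground truth, and reports both rates.
#'
#' @param tracks list of `st_track` (or a per-frame detection list).
#' @param gt a [ground_truth()].
#' @param min_overlap see [match_detections()].
#' @return list `detection_rate`, `false_positive_rate`, `match`.
#' @export
evaluate_detections <- function(tracks, gt, min_overlap = 0) {
  dets <- if (length(tracks) && inherits(tracks[[1]], "st_track"))
    tracks_to_detections(tracks, gt$n_frames)
  else tracks
  if (length(dets) < gt$n_frames)
    dets <- c(dets, vector("list", gt$n_frames - length(dets)))
  m <- match_detections(dets, gt, min_overlap)
  list(detection_rate = detection_rate(m),
       false_positive_rate = false_positive_rate(m),
       match = m)
}

#' Label tracks as true or false detections against ground truth
#'
#' A track is a true detection if it coincides with ground-truth regions in
#' more than `frame_fraction` of its observed frames. Per frame,
#' coincidence means that more than `min_pixel_fraction` of the track's
#' mask pixels lie on ground-truth regions -- the default 0 (any overlap)
#' mirrors the hit criterion of [match_detections()], so a track counts as
#' true exactly when its frames would count as successful detections.
#' Tracks that merge an animal with adjacent similar-colored background
#' remain true detections under this reading, which matters when the
#' labels calibrate safe thresholds: excluding them would tighten the
#' thresholds against the very tracks that carry the detections. Used to
#' label calibration tracks for [calibrate_rules()] and
#' [train_svm_validator()].
#'
#' @param tracks list of `st_track`.
#' @param gt a [ground_truth()].
#' @param frame_fraction fraction of frames that must coincide.
#' @param min_pixel_fraction per-frame mask fraction that must lie on
#'   ground truth (strictly exceeded; 0 = any overlap).
#' @return logical vector (`TRUE` = true detection).
#' @export
label_tracks <- function(tracks, gt, frame_fraction = 0.5,
                         min_pixel_fraction = 0) {
  vapply(tracks, function(tr) {
    hit <- vapply(tr$frames, function(f) {
      px <- tr$masks[[as.character(f)]]
      mean(gt$masks[[f + 1L]][px] > 0L) > min_pixel_fraction
    }, logical(1))
    mean(hit) > frame_fraction
  }, logical(1))
}
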