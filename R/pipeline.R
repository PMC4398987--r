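#' Pipeline configuration
#'
#' Collects the tunable parameters of the detection pipeline with their
#' defaults: preprocessing (`scale`), segmentation (`spatial_bandwidth`,
#' `range_bandwidth`, `min_segment_size` -- 150 px for near/intermediate
#' distances, 20 px for far-distant animals), classification (`mode`,
#' `vote_threshold`), tracking (`w`, `C`), features (`edge_threshold`,
#' `duration_mode`) and evaluation (`min_overlap`).
#'
#' @param scale preprocessing downscale fraction.
#' @param spatial_bandwidth,range_bandwidth,min_segment_size see
#'   [mean_shift_segment()].
#' @param mode,vote_threshold see [classify_segment()].
#' @param w,C see [track_candidates()].
#' @param edge_threshold,duration_mode see [extract_features()].
#' @param min_overlap see [match_detections()].
#' @param ... overrides of the above when reading from file.
#' @return named list of class `et_config`.
#' @export
et_config <- function(scale = 0.25, spatial_bandwidth = 8,
                      range_bandwidth = 8, min_segment_size = 150,
                      mode = "two_stage", vote_threshold = 2 / 3,
                      w = 5L, C = 0.5, edge_threshold = 11,
                      duration_mode = "span", min_overlap = 0) {
  structure(list(scale = scale, spatial_bandwidth = spatial_bandwidth,
                 range_bandwidth = range_bandwidth,
                 min_segment_size = min_segment_size, mode = mode,
                 vote_threshold = vote_threshold, w = as.integer(w), C = C,
                 edge_threshold = edge_threshold,
                 duration_mode = duration_mode, min_overlap = min_overlap),
            class = "et_config")
}

#' Read a pipeline configuration from YAML
#'
#' File keys override the [et_config()] defaults.
#'
#' @param path YAML file.
#' @return an `et_config`.
#' @export
read_config <- function(path) {
  do.call(et_config, yaml::read_yaml(path))
}

#' Train a color model from image/mask pairs
#'
#' Convenience wrapper: extracts color samples from every labeled pair
#' with [extract_training_colors()] and fits [train_color_model()].
#'
#' @param pairs list of `list(image, mask)` (see
#'   [generate_training_images()]) or a manifest data frame with columns
#'   `image`, `mask` of PNG paths.
#' @param config an [et_config()] (segmentation parameters, scale).
#' @param ... passed to [train_color_model()] (`cost_ratio`,
#'   `luminance_limits`, ...).
#' @return a `color_model`.
#' @export
train_from_pairs <- function(pairs, config = et_config(), ...) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      px <- png::readPNG(pairs$image[i])
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
      m <- png::readPNG(pairs$mask[i])
      if (length(dim(m)) == 3L) m <- m[, , 1]
      list(image = et_frame(px[, , 1:3], 0L, "RGB"), mask = m >= 0.5)
    })
  }
  samples <- do.call(rbind, lapply(pairs, function(p)
    extract_training_colors(p$image, p$mask, scale = config$scale,
                            spatial_bandwidth = config$spatial_bandwidth,
                            range_bandwidth = config$range_bandwidth,
                            min_segment_size = 20)))
  train_color_model(samples, ...)
}

#' Run the full detection pipeline on a sequence
#'
#' Fixed stage order: preprocess, segment, classify, trace/intersect,
#' connectivity graph, subgraph extraction, spatial merge, feature
#' extraction, validation, gap filling, and (when ground truth is given)
#' evaluation. Per-stage counts are logged in the result; with ground
#' truth, the report carries detection and false-positive rates both
#' before validation (all tracks) and after validation + gap filling.
#'
#' @param frames list of RGB [et_frame()]s.
#' @param model a trained `color_model`.
#' @param config an [et_config()].
#' @param rules optional list of `threshold_rule`s; `NULL` disables
#'   validation (every track passes).
#' @param flow optional [flow_provider] at the working scale; defaults to
#'   [flow_phasecorr()] on the preprocessed frames.
#' @param gt optional [ground_truth()] at the working scale.
#' @return an object of class `et_run`: `config`, `luv` (preprocessed
#'   frames), `seg_maps`, `candidates` (per frame), `tracking` (tracks,
#'   graph, links), `features`, `accepted` (logical per track),
#'   `tracks_final` (validated, gap-filled), `report`, `stage_log`.
#' @export
run_pipeline <- function(frames, model, config = et_config(), rules = NULL,
                         flow = NULL, gt = NULL) {
  stopifnot(length(frames) >= 1L, inherits(model, "color_model"))
  luv <- preprocess_sequence(frames, config$scale)
  seg_maps <- lapply(luv, function(f)
    mean_shift_segment(f, config$spatial_bandwidth, config$range_bandwidth,
                       config$min_segment_size))
  candidates <- lapply(seq_along(luv), function(i)
    detect_candidates(model, seg_maps[[i]], luv[[i]], config$mode,
                      config$vote_threshold))
  if (is.null(flow)) flow <- flow_phasecorr(luv)
  tracking <- track_candidates(candidates, flow, config$w, config$C)
  features <- feature_table(tracking$tracks, luv,
                            edge_threshold = config$edge_threshold,
                            duration_mode = config$duration_mode)
  accepted <- if (is.null(rules)) rep(TRUE, length(tracking$tracks))
  else validate_tracks(features, rules)
  tracks_final <- lapply(tracking$tracks[accepted], fill_gaps, flow = flow)
  report <- NULL
  if (!is.null(gt)) {
    before <- evaluate_detections(tracking$tracks, gt, config$min_overlap)
    after <- evaluate_detections(tracks_final, gt, config$min_overlap)
    report <- list(
      detection_rate = after$detection_rate,
      false_positive_rate = after$false_positive_rate,
      detection_rate_before_validation = before$detection_rate,
      false_positive_rate_before_validation = before$false_positive_rate)
  }
  stage_log <- list(
    n_frames = length(frames),
    n_segments = sum(vapply(seg_maps, function(s)
      length(s$segments), integer(1))),
    n_candidates = sum(lengths(candidates)),
    n_links = nrow(tracking$links),
    n_tracks = length(tracking$tracks),
    n_validated = sum(accepted))
  structure(list(config = config, luv = luv, seg_maps = seg_maps,
                 candidates = candidates, tracking = tracking,
                 features = features, accepted = accepted,
                 tracks_final = tracks_final, report = report,
                 stage_log = stage_log),
            class = "et_run")
}

#' @export
print.et_run <- function(x, ...) {
  s <- x$stage_log
  cat("Detection pipeline run\n")
  cat(sprintf(
    "  %d frames | %d segments | %d candidates | %d links\n",
    s$n_frames, s$n_segments, s$n_candidates, s$n_links))
  cat(sprintf("  %d tracks, %d validated\n", s$n_tracks, s$n_validated))
  if (!is.null(x$report)) {
    cat(sprintf("  detection rate: %.1f%%  false-positive rate: %.1f%%\n",
                100 * x$report$detection_rate,
                100 * x$report$false_positive_rate))
    cat(sprintf(
      "  before validation: detection %.1f%%, false positives %.1f%%\n",
      100 * x$report$detection_rate_before_validation,
      100 * x$report$false_positive_rate_before_validation))
  }
  invisible(x)
}
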