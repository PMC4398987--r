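#' Consistency features of a track
#'
#' `track_duration()` measures how long a detection can be tracked. The
#' default `"span"` reading is the full lifetime `last - first + 1`; the
#' alternative `"present"` reading counts only the frames where the track
#' was actually observed. `track_instability()` is the portion of the
#' lifetime that falls into tracking gaps, `|gaps| / lifetime` -- 0 for a
#' contiguously tracked detection. Unreliable detections (short, gappy) are
#' typically false positives.
#'
#' @param track an `st_track`.
#' @param mode lifetime reading, `"span"` (default) or `"present"`.
#' @return `track_duration()`: frames (integer); `track_instability()`:
#'   fraction in `[0, 1]`.
#' @export
track_duration <- function(track, mode = c("span", "present")) {
  mode <- match.arg(mode)
  if (mode == "span") track$lifetime else length(track$frames)
}

#' @rdname track_duration
#' @export
track_instability <- function(track) {
  length(track$gap_frames) / track$lifetime
}

#' Shape change of an area series
#'
#' Normalized range of a track's per-frame areas,
#' `f_sc = (max(a) - min(a)) / max(a)`: 0 when the area is constant over
#' time, close to 1 under abrupt changes -- which suggest an unstable
#' segmentation rather than an animal.
#'
#' @param areas per-frame areas `a_1..a_n`, all positive.
#' @return fraction in `[0, 1]`.
#' @export
shape_change <- function(areas) {
  if (length(areas) < 1L) stop("need at least one area")
  if (any(areas <= 0)) stop("areas must be positive")
  (max(areas) - min(areas)) / max(areas)
}

# The five 2x2 edge filters (horizontal, vertical, diagonal 45, diagonal
# 135, non-directional), applied to a block [a b; c d] of sub-block means.
edge_responses <- function(a, b, c, d) {
  cbind(
    horizontal = abs(a + b - c - d),
    vertical = abs(a - b + c - d),
    diag45 = sqrt(2) * abs(a - d),
    diag135 = sqrt(2) * abs(b - c),
    nondirectional = abs(2 * a - 2 * b - 2 * c + 2 * d)
  )
}

#' Five-bin edge histogram of a masked region
#'
#' A compact variant of the MPEG-7 edge-histogram descriptor with a single
#' five-bin histogram per region: the mask's bounding box is tiled into
#' non-overlapping 2x2 pixel blocks; blocks fully inside the mask are kept;
#' each kept block is scored by the five 2x2 edge filters (horizontal,
#' vertical, two diagonals, non-directional) and counts as an edge block of
#' the maximal filter iff the maximal response reaches `edge_threshold`.
#' Bin values are edge-block counts divided by the number of kept blocks,
#' so the bin sum is the fraction of blocks that represent edges.
#'
#' @param mask logical matrix or integer pixel indices (then `dim` needed).
#' @param gray grayscale image matrix on a 0--255 scale (the pipeline uses
#'   `L * 2.55`).
#' @param edge_threshold minimal filter response of an edge block.
#' @param dim frame dimensions when `mask` is an index vector.
#' @return named numeric of the 5 bins; attribute `n_blocks` carries the
#'   number of complete blocks (0 with an all-zero histogram when the mask
#'   contains no complete block).
#' @export
edge_histogram <- function(mask, gray, edge_threshold = 11, dim = NULL) {
  if (!is.matrix(mask)) {
    m <- matrix(FALSE, dim[1], dim[2]); m[mask] <- TRUE; mask <- m
  }
  if (!any(mask)) stop("mask is empty")
  bins <- c(horizontal = 0, vertical = 0, diag45 = 0, diag135 = 0,
            nondirectional = 0)
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  r0 <- rr[1]; c0 <- cr[1]
  nbr <- (rr[2] - rr[1] + 1L) %/% 2L
  nbc <- (cr[2] - cr[1] + 1L) %/% 2L
  if (nbr < 1L || nbc < 1L)
    return(structure(bins, n_blocks = 0L))
  ri <- r0 + seq_len(2L * nbr) - 1L
  ci <- c0 + seq_len(2L * nbc) - 1L
  sub_m <- mask[ri, ci, drop = FALSE]
  sub_g <- gray[ri, ci, drop = FALSE]
  odd_r <- seq(1L, 2L * nbr, by = 2L); odd_c <- seq(1L, 2L * nbc, by = 2L)
  a <- sub_g[odd_r, odd_c, drop = FALSE]       # top-left
  b <- sub_g[odd_r, odd_c + 1L, drop = FALSE]  # top-right
  cc <- sub_g[odd_r + 1L, odd_c, drop = FALSE] # bottom-left
  d <- sub_g[odd_r + 1L, odd_c + 1L, drop = FALSE]
  complete <- sub_m[odd_r, odd_c] & sub_m[odd_r, odd_c + 1L] &
    sub_m[odd_r + 1L, odd_c] & sub_m[odd_r + 1L, odd_c + 1L]
  n_blocks <- sum(complete)
  if (n_blocks == 0L)
    return(structure(bins, n_blocks = 0L))
  resp <- edge_responses(a[complete], b[complete], cc[complete], d[complete])
  best <- max.col(resp, ties.method = "first")
  is_edge <- resp[cbind(seq_len(n_blocks), best)] >= edge_threshold
  tab <- tabulate(best[is_edge], 5L)
  bins[] <- tab / n_blocks
  structure(bins, n_blocks = n_blocks)
}

as_hist_matrix <- function(histograms) {
  if (is.list(histograms)) histograms <- do.call(rbind, histograms)
  if (is.null(nrow(histograms))) histograms <- matrix(histograms, nrow = 1L)
  if (nrow(histograms) < 1L) stop("need at least one histogram")
  histograms
}

#' Edge density of a histogram series
#'
#' The mean of the summed histograms over a track,
#' `f_ed = (1/n) * sum_i sum_j e_ij`: the mean portion of edge blocks over
#' the track's lifetime. Highly textured regions (bushes, grass) score
#' high; elephant skin, being poorly textured, scores low.
#'
#' @param histograms `n x 5` matrix or list of 5-bin histograms.
#' @return fraction in `[0, 1]`.
#' @export
edge_density <- function(histograms) {
  h <- as_hist_matrix(histograms)
  mean(rowSums(h))
}

#' Texture variation of a histogram series
#'
#' The mean over the per-bin value ranges across time,
#' `f_tv = (1/5) * sum_j (max_i e_ij - min_i e_ij)`: 0 when the texture is
#' stable over the track, high when it fluctuates -- a sign of a spurious
#' detection.
#'
#' @param histograms `n x 5` matrix or list of 5-bin histograms.
#' @return fraction in `[0, 1]`.
#' @export
texture_variation <- function(histograms) {
  h <- as_hist_matrix(histograms)
  mean(apply(h, 2L, max) - apply(h, 2L, min))
}

#' Extract the five spatiotemporal features of a track
#'
#' Assembles duration, instability, shape change, edge density and texture
#' variation. Areas and edge histograms are computed on the frames where
#' the track is actually present and not interpolated; gaps contribute only
#' through duration/instability.
#'
#' @param track an `st_track`.
#' @param frames list of LUV frames covering the track.
#' @param edge_threshold see [edge_histogram()].
#' @param duration_mode see [track_duration()].
#' @return one-row data frame: `track_id`, `duration`, `instability`,
#'   `shape_change`, `edge_density`, `texture_variation`.
#' @export
extract_features <- function(track, frames, edge_threshold = 11,
                             duration_mode = "span") {
  use <- track$frames[!track$interpolated[as.character(track$frames)]]
  if (length(use) == 0L) stop("track has no observed frames")
  areas <- numeric(length(use))
  hists <- matrix(0, length(use), 5L)
  for (i in seq_along(use)) {
    f <- use[i]
    px <- track$masks[[as.character(f)]]
    areas[i] <- length(px)
    gray <- frames[[f + 1L]]$pixels[, , 1] * 2.55
    hists[i, ] <- edge_histogram(px, gray, edge_threshold, dim = track$dim)
  }
  data.frame(
    track_id = track$track_id,
    duration = track_duration(track, duration_mode),
    instability = track_instability(track),
    shape_change = shape_change(areas),
    edge_density = edge_density(hists),
    texture_variation = texture_variation(hists)
  )
}

#' Feature table for a set of tracks
#'
#' @param tracks list of `st_track`.
#' @param frames list of LUV frames.
#' @param ... passed to [extract_features()].
#' @return data frame with one row per track.
#' @export
feature_table <- function(tracks, frames, ...) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(), duration = integer(),
                      instability = numeric(), shape_change = numeric(),
                      edge_density = numeric(), texture_variation = numeric()))
  do.call(rbind, lapply(tracks, extract_features, frames = frames, ...))
}
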