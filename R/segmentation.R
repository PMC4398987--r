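#' Mean-shift color segmentation of an LUV frame
#'
#' Partitions a frame into coherent color segments: joint spatial+range
#' mean-shift filtering with a flat kernel moves every pixel to its mode in
#' (row, col, L, u, v) space, 4-connected pixels whose modes lie within the
#' range bandwidth are fused into regions, and regions smaller than
#' `min_segment_size` are merged into the 4-connected neighbor with the
#' closest mean color (ties broken by lower segment id). The representative
#' color of each surviving segment is the arithmetic mean of the LUV colors
#' of the pixels it covers in the input frame.
#'
#' `min_segment_size` trades resolution against robustness: 150 px (at the
#' working scale) suits animals at near and intermediate camera distance,
#' 20 px retains the small segments needed for far-distant animals at the
#' cost of many more segments.
#'
#' @param frame an LUV [et_frame()].
#' @param spatial_bandwidth spatial kernel radius in pixels (> 0).
#' @param range_bandwidth color kernel radius in LUV units (> 0).
#' @param min_segment_size minimum surviving segment area in pixels (>= 1).
#' @param max_iter,eps mean-shift convergence controls.
#' @return an object of class `segment_map`: `frame_index`, `labels`
#'   (H x W integer matrix of 1-based segment ids forming a total
#'   partition) and `segments`, a list of `et_segment` objects with fields
#'   `id`, `frame_index`, `pixels` (linear indices), `area`, `mean_color`
#'   and `dim`.
#' @export
mean_shift_segment <- function(frame, spatial_bandwidth = 8,
                               range_bandwidth = 8, min_segment_size = 150,
                               max_iter = 8, eps = 0.5) {
  stopifnot(inherits(frame, "et_frame"))
  if (frame$space != "LUV") stop("'frame' must be in LUV space")
  if (spatial_bandwidth <= 0 || range_bandwidth <= 0)
    stop("bandwidths must be positive")
  if (min_segment_size < 1) stop("'min_segment_size' must be >= 1")
  px <- frame$pixels
  filt <- .ms_filter(px[, , 1], px[, , 2], px[, , 3],
                     spatial_bandwidth, range_bandwidth,
                     as.integer(max_iter), eps)
  h <- frame$height; w <- frame$width
  fl <- matrix(filt[, 1], h, w)
  fu <- matrix(filt[, 2], h, w)
  fv <- matrix(filt[, 3], h, w)
  labels <- .ms_label(fl, fu, fv, range_bandwidth)
  labels <- merge_small_regions(labels, px, min_segment_size)
  build_segment_map(labels, px, frame$index)
}

# Region adjacency as a two-column matrix of distinct touching label pairs.
region_adjacency <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  a <- c(labels[-h, ], labels[, -w])
  b <- c(labels[-1, ], labels[, -1])
  keep <- a != b
  pairs <- rbind(cbind(a[keep], b[keep]), cbind(b[keep], a[keep]))
  unique(pairs)
}

# Merge every region smaller than min_size into its most similar-color
# 4-connected neighbor; repeated in rounds (a merge can create adjacency and
# change mean colors) until no undersized region with a neighbor remains.
merge_small_regions <- function(labels, luv, min_size) {
  if (min_size <= 1) return(relabel_sequential(labels))
  repeat {
    labels <- relabel_sequential(labels)
    n <- max(labels)
    if (n == 1L) break
    areas <- tabulate(labels, n)
    small <- which(areas < min_size)
    if (length(small) == 0L) break
    lv <- as.vector(labels)
    means <- cbind(
      rowsum(as.vector(luv[, , 1]), lv) / areas,
      rowsum(as.vector(luv[, , 2]), lv) / areas,
      rowsum(as.vector(luv[, , 3]), lv) / areas
    )
    adj <- region_adjacency(labels)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    merged_any <- FALSE
    for (s in small) {
      nb <- adj[adj[, 1] == s, 2]
      if (length(nb) == 0L) next
      d <- colSums((t(means[nb, , drop = FALSE]) - means[s, ])^2)
      target <- nb[order(d, nb)][1]        # nearest color; tie -> lower id
      rs <- find(s); rt <- find(target)
      if (rs != rt) { parent[rs] <- rt; merged_any <- TRUE }
    }
    if (!merged_any) break
    root <- vapply(seq_len(n), find, integer(1))
    labels <- matrix(root[labels], nrow(labels), ncol(labels))
  }
  labels
}

# Renumber labels 1..n in order of first appearance (column-major scan).
relabel_sequential <- function(labels) {
  u <- unique(as.vector(labels))
  map <- integer(max(u))
  map[u] <- seq_along(u)
  matrix(map[labels], nrow(labels), ncol(labels))
}

build_segment_map <- function(labels, luv, frame_index) {
  n <- max(labels)
  lv <- as.vector(labels)
  areas <- tabulate(lv, n)
  ml <- rowsum(as.vector(luv[, , 1]), lv) / areas
  mu <- rowsum(as.vector(luv[, , 2]), lv) / areas
  mv <- rowsum(as.vector(luv[, , 3]), lv) / areas
  pix <- split(seq_along(lv), lv)
  d <- dim(labels)
  segments <- lapply(seq_len(n), function(i) {
    structure(
      list(id = i, frame_index = frame_index, pixels = pix[[i]],
           area = areas[i], mean_color = c(L = ml[i], u = mu[i], v = mv[i]),
           dim = d),
      class = "et_segment"
    )
  })
  structure(
    list(frame_index = frame_index, labels = labels, segments = segments,
         height = d[1], width = d[2]),
    class = "segment_map"
  )
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map frame %d: %d segments over %dx%d>\n",
              x$frame_index, length(x$segments), x$height, x$width))
  invisible(x)
}

#' @export
print.et_segment <- function(x, ...) {
  cat(sprintf(
    "<segment %d @frame %d: area %d, mean LUV (%.1f, %.1f, %.1f)>\n",
    x$id, x$frame_index, x$area,
    x$mean_color[1], x$mean_color[2], x$mean_color[3]))
  invisible(x)
}

#' Binary mask of a segment
#'
#' @param segment an `et_segment`.
#' @return logical H x W matrix.
#' @export
segment_mask <- function(segment) {
  m <- matrix(FALSE, segment$dim[1], segment$dim[2])
  m[segment$pixels] <- TRUE
  m
}

#' Export a segmentation for inspection
#'
#' Writes the label image as an RGB PNG with the 16-bit segment id split
#' across the red (high byte) and green (low byte) channels -- lossless for
#' up to 65535 segments -- plus a CSV of per-segment statistics
#' `(frame, id, area, L, u, v)`.
#'
#' @param seg_map a `segment_map`.
#' @param png_path,csv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the CSV content as a data frame.
#' @export
write_segment_map <- function(seg_map, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path)) {
    id <- seg_map$labels
    img <- array(0, c(nrow(id), ncol(id), 3))
    img[, , 1] <- (id %/% 256L) / 255
    img[, , 2] <- (id %% 256L) / 255
    png::writePNG(img, png_path)
  }
  df <- data.frame(
    frame = seg_map$frame_index,
    id = vapply(seg_map$segments, `[[`, integer(1), "id"),
    area = vapply(seg_map$segments, `[[`, integer(1), "area"),
    L = vapply(seg_map$segments, function(s) s$mean_color[[1]], numeric(1)),
    u = vapply(seg_map$segments, function(s) s$mean_color[[2]], numeric(1)),
    v = vapply(seg_map$segments, function(s) s$mean_color[[3]], numeric(1))
  )
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}

#' Construct a segment from a mask
#'
#' Builds an `et_segment` directly from a binary mask -- useful for
#' injecting known segments (e.g. ground-truth regions) into the tracking
#' stage, or for tests.
#'
#' @param mask logical H x W matrix (non-empty).
#' @param frame_index 0-based frame index.
#' @param id segment id.
#' @param frame optional LUV [et_frame()] to compute `mean_color` from;
#'   otherwise the mean color is `NA`.
#' @return an `et_segment`.
#' @export
as_segment <- function(mask, frame_index, id = 1L, frame = NULL) {
  px <- which(mask)
  if (length(px) == 0L) stop("mask is empty")
  mc <- c(L = NA_real_, u = NA_real_, v = NA_real_)
  if (!is.null(frame)) {
    m <- matrix(frame$pixels, ncol = 3L)[px, , drop = FALSE]
    mc <- c(L = mean(m[, 1]), u = mean(m[, 2]), v = mean(m[, 3]))
  }
  structure(
    list(id = as.integer(id), frame_index = as.integer(frame_index),
         pixels = px, area = length(px), mean_color = mc,
         dim = dim(mask)),
    class = "et_segment"
  )
}
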