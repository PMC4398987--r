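#' Construct a video frame
#'
#' A frame is the atomic input of the detection pipeline: an `H x W x 3`
#' numeric array of pixel values together with its 0-based index in the
#' sequence and a color-space tag. RGB frames hold sRGB values in `[0, 1]`
#' (as read from PNG); LUV frames hold CIE L*u*v* values (L in 0--100).
#'
#' @param pixels numeric `H x W x 3` array, finite.
#' @param index integer frame number, 0-based.
#' @param space color space tag, `"RGB"` or `"LUV"`.
#' @return an object of class `et_frame`.
#' @export
et_frame <- function(pixels, index = 0L, space = c("RGB", "LUV")) {
  space <- match.arg(space)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("empty image")
  if (!all(is.finite(pixels)))
    stop("'pixels' must be finite")
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("'index' must be a non-negative integer")
  structure(
    list(pixels = pixels, index = index, space = space,
         height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "et_frame"
  )
}

#' @export
print.et_frame <- function(x, ...) {
  cat(sprintf("<et_frame #%d %dx%d %s>\n", x$index, x$height, x$width, x$space))
  invisible(x)
}

#' @export
dim.et_frame <- function(x) c(x$height, x$width)

# Separable area-averaging resize weights: output cell i covers the input
# interval [(i-1)/s, i/s); weight of input cell r is the overlap length * s.
resize_weights <- function(n_in, n_out, scale) {
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) / scale
    hi <- i / scale
    r0 <- floor(lo) + 1
    r1 <- min(ceiling(hi), n_in)
    for (r in r0:r1) {
      ov <- min(hi, r) - max(lo, r - 1)
      if (ov > 0) w[i, r] <- ov
    }
    w[i, ] <- w[i, ] / sum(w[i, ])
  }
  w
}

#' Downscale an image array by area averaging
#'
#' Each output pixel is the mean of the input area it covers, so mean colors
#' are preserved under decimation (no aliasing from point sampling).
#'
#' @param pixels `H x W x 3` array.
#' @param scale fraction in (0, 1]; output is `floor(scale*H) x floor(scale*W)`.
#' @return resized array.
#' @export
resize_area <- function(pixels, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("'scale' must be in (0, 1]")
  if (scale == 1) return(pixels)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  oh <- floor(scale * h); ow <- floor(scale * w)
  if (oh < 1L || ow < 1L) stop("scale too small for image size")
  wr <- resize_weights(h, oh, scale)
  wc <- resize_weights(w, ow, scale)
  out <- array(0, c(oh, ow, dim(pixels)[3]))
  for (k in seq_len(dim(pixels)[3]))
    out[, , k] <- wr %*% pixels[, , k] %*% t(wc)
  out
}

#' Convert sRGB pixel values to CIE LUV
#'
#' Assumes sRGB input with the D65 white point. `L` is in 0--100; pure black
#' maps to `L = 0`.
#'
#' @param pixels `H x W x 3` sRGB array in `[0, 1]`, or an `N x 3` matrix.
#' @return array/matrix of the same shape with LUV values.
#' @export
rgb_to_luv <- function(pixels) {
  d <- dim(pixels)
  m <- matrix(pmin(pmax(as.vector(pixels), 0), 1), ncol = 3L)
  luv <- grDevices::convertColor(m, from = "sRGB", to = "Luv")
  # convertColor leaves u, v as NaN at exact black; the limit is 0
  luv[!is.finite(luv)] <- 0
  array(luv, d)
}

#' Convert CIE LUV values to sRGB
#'
#' Inverse of [rgb_to_luv()]; out-of-gamut results are clipped to `[0, 1]`.
#'
#' @param pixels `H x W x 3` LUV array or `N x 3` matrix.
#' @return sRGB array/matrix in `[0, 1]`.
#' @export
luv_to_rgb <- function(pixels) {
  d <- dim(pixels)
  m <- matrix(as.vector(pixels), ncol = 3L)
  rgb <- grDevices::convertColor(m, from = "Luv", to = "sRGB")
  rgb[!is.finite(rgb)] <- 0
  array(pmin(pmax(rgb, 0), 1), d)
}

#' Preprocess a frame: downscale and convert to LUV
#'
#' The working representation of the pipeline: input frames (typically full
#' HD) are downscaled -- by a factor of 0.25 by default -- and transformed to
#' the perceptually uniform LUV color space, in which Euclidean distance
#' approximates perceived color difference.
#'
#' @param frame an RGB [et_frame()].
#' @param scale downscale fraction in (0, 1]; default 0.25.
#' @return an LUV `et_frame` of size `floor(scale*H) x floor(scale*W)`.
#' @export
preprocess_frame <- function(frame, scale = 0.25) {
  stopifnot(inherits(frame, "et_frame"))
  if (frame$space != "RGB") stop("'frame' must be in RGB space")
  px <- resize_area(frame$pixels, scale)
  et_frame(rgb_to_luv(px), index = frame$index, space = "LUV")
}

#' Preprocess a whole sequence
#'
#' @param frames list of RGB frames.
#' @param scale downscale fraction.
#' @return list of LUV frames.
#' @export
preprocess_sequence <- function(frames, scale = 0.25) {
  lapply(frames, preprocess_frame, scale = scale)
}

#' Read a directory of numbered PNG frames
#'
#' Files are sorted by name; zero-padded numbering therefore yields temporal
#' order. Frame indices are assigned 0-based in sorted order.
#'
#' @param path directory containing `.png` files.
#' @return list of RGB frames.
#' @export
read_frame_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG files in ", path)
  lapply(seq_along(files), function(i) {
    px <- png::readPNG(files[[i]])
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
    et_frame(px, index = i - 1L, space = "RGB")
  })
}

#' Write a sequence of RGB frames as numbered PNG files
#'
#' @param frames list of RGB frames.
#' @param path output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_frame_dir <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(frames, function(f) {
    file <- file.path(path, sprintf("frame_%05d.png", f$index))
    png::writePNG(pmin(pmax(f$pixels, 0), 1), file)
    file
  }, character(1))
  invisible(out)
}
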