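#' Flow providers
#'
#' A flow provider supplies a dense per-pixel displacement field between any
#' two *adjacent* frames of a sequence; it is the motion backend of segment
#' tracing and gap interpolation. The field for `from -> to` is an
#' `H x W x 2` array with the row displacement in `[,,1]` and the column
#' displacement in `[,,2]`, evaluated at the pixels of frame `from`.
#' Backward fields are derived by negating the corresponding forward field
#' (exact for locally constant flow).
#'
#' * `flow_zero()` -- identity motion (static camera, static scene).
#' * `flow_constant()` -- one global displacement per frame step, e.g. a
#'   steady camera pan.
#' * `flow_true()` -- wraps externally known forward fields, e.g. the exact
#'   flow emitted by [generate_sequence()].
#' * `flow_phasecorr()` -- estimates one global translation per adjacent
#'   frame pair by FFT phase correlation of the L channel; a lightweight
#'   default that models camera pan but not object-relative motion.
#'
#' @param dim frame dimensions `c(H, W)`.
#' @param v displacement per forward frame step, `c(dy, dx)`.
#' @param flows list of `n_frames - 1` forward fields; element `t + 1` maps
#'   frame `t` to `t + 1` (0-based `t`).
#' @param frames list of LUV frames.
#' @return an object of class `flow_provider`.
#' @name flow_provider
NULL

new_flow_provider <- function(get, dim) {
  structure(list(get = get, dim = dim), class = "flow_provider")
}

#' @export
print.flow_provider <- function(x, ...) {
  cat(sprintf("<flow_provider %dx%d>\n", x$dim[1], x$dim[2]))
  invisible(x)
}

#' Displacement field between two adjacent frames
#'
#' @param provider a `flow_provider`.
#' @param from,to 0-based frame indices with `|to - from| == 1`.
#' @return `H x W x 2` displacement array (`[,,1]` rows, `[,,2]` columns).
#' @export
get_flow <- function(provider, from, to) {
  stopifnot(inherits(provider, "flow_provider"))
  if (abs(to - from) != 1L)
    stop("flow is defined between adjacent frames only")
  provider$get(as.integer(from), as.integer(to))
}

constant_field <- function(dim, v) {
  f <- array(0, c(dim[1], dim[2], 2))
  f[, , 1] <- v[1]; f[, , 2] <- v[2]
  f
}

#' @rdname flow_provider
#' @export
flow_zero <- function(dim) {
  new_flow_provider(function(from, to) constant_field(dim, c(0, 0)), dim)
}

#' @rdname flow_provider
#' @export
flow_constant <- function(dim, v) {
  new_flow_provider(function(from, to) {
    constant_field(dim, if (to > from) v else -v)
  }, dim)
}

#' @rdname flow_provider
#' @export
flow_true <- function(flows, dim = NULL) {
  if (is.null(dim)) dim <- base::dim(flows[[1]])[1:2]
  new_flow_provider(function(from, to) {
    fwd <- min(from, to) + 1L          # forward field index (1-based)
    if (fwd < 1L || fwd > length(flows))
      stop("flow unavailable for frames ", from, " -> ", to)
    f <- flows[[fwd]]
    if (to > from) f else -f
  }, dim)
}

# Global integer translation from a to b by phase correlation of matrices.
phase_corr_shift <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  r <- fb * Conj(fa)
  m <- Mod(r); m[m < .Machine$double.eps] <- 1
  s <- Re(stats::fft(r / m, inverse = TRUE))
  p <- which.max(s) - 1L
  h <- nrow(a); w <- ncol(a)
  dy <- p %% h; dx <- p %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dy, dx)
}

#' @rdname flow_provider
#' @export
flow_phasecorr <- function(frames) {
  stopifnot(length(frames) >= 2L)
  d <- c(frames[[1]]$height, frames[[1]]$width)
  cache <- new.env(parent = emptyenv())
  new_flow_provider(function(from, to) {
    f0 <- min(from, to)
    key <- as.character(f0)
    if (is.null(cache[[key]])) {
      a <- frames[[f0 + 1L]]$pixels[, , 1]
      b <- frames[[f0 + 2L]]$pixels[, , 1]
      cache[[key]] <- phase_corr_shift(a, b)
    }
    v <- cache[[key]]
    constant_field(d, if (to > from) v else -v)
  }, d)
}

#' Warp a binary mask by a displacement field
#'
#' Nearest-neighbor forward splatting: every mask pixel is moved by its
#' (rounded) displacement; pixels leaving the frame are clipped. A single
#' hole-filling pass then switches on empty pixels with at least three of
#' four occupied 4-neighbors, closing the one-pixel holes that forward
#' splatting of a deforming field can leave.
#'
#' @param mask logical H x W matrix.
#' @param field `H x W x 2` displacement array.
#' @return warped logical matrix.
#' @export
warp_mask <- function(mask, field) {
  .warp_mask_cpp(mask, field[, , 1], field[, , 2])
}
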