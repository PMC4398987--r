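#' Synthetic scene specification
#'
#' Parameters of the deterministic test-sequence generator. The generator
#' emulates the statistical structure the detector assumes in wildlife
#' footage: weakly textured gray-brown foreground blobs whose colors partly
#' overlap the background's color distribution, strongly textured
#' background clutter, a steady camera pan, and scheduled occlusions that
#' create tracking gaps. Scenes are rendered at the working resolution
#' (320 x 180 by default), so the pipeline is run on them with `scale = 1`.
#'
#' Color palettes are defined in LUV. The foreground band is a low-chroma
#' gray-brown (L 38--62); the background mixes green, blue and tan bands,
#' and a fraction `overlap_fraction` of background cells is drawn from the
#' *foreground* palette ("confusable" clutter) to provoke false positives.
#' Background texture is high-amplitude luminance noise, foreground texture
#' low-amplitude, so texture features carry discriminative signal.
#'
#' @param width,height frame size in pixels.
#' @param n_frames sequence length.
#' @param n_blobs number of foreground blobs (animals).
#' @param blob_axes range of ellipse semi-axes in pixels.
#' @param blob_speed_max maximal per-axis blob speed (px/frame, integer).
#' @param pan background screen displacement per frame `c(dy, dx)`
#'   (integer; the camera pans opposite).
#' @param cell background patch size in pixels.
#' @param overlap_fraction fraction of background cells colored from the
#'   foreground palette.
#' @param dark_frac,bright_frac fraction of background cells that are
#'   near-black / near-white (luminance confusers; off by default).
#' @param fg_noise,bg_noise,clutter_noise,extreme_noise luminance texture
#'   amplitudes (Gaussian sd in L units) of foreground blobs, ordinary
#'   background, confusable clutter, and dark/bright cells.
#' @param noise_sd per-frame sensor noise (sd in sRGB units).
#' @param occlusions list of `list(blob, start, length)` schedules; during
#'   `[start, start+length-1]` the blob is hidden (background shows) while
#'   the ground truth keeps its region, flagged occluded.
#' @param fg_extreme_frac fraction of each blob's axes carved into
#'   near-black and near-white shading in *training* images (gives the
#'   foreground color list its unreliable extremes; off by default).
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(width = 320, height = 180, n_frames = 30,
                       n_blobs = 3, blob_axes = c(10, 16),
                       blob_speed_max = 1, pan = c(0, 1), cell = 24,
                       overlap_fraction = 0.3,
                       dark_frac = 0, bright_frac = 0,
                       fg_noise = 1.25, bg_noise = 9, clutter_noise = 5,
                       extreme_noise = 1, noise_sd = 0.004,
                       occlusions = list(list(blob = 1, start = 12,
                                              length = 3)),
                       fg_extreme_frac = 0) {
  spec <- list(width = width, height = height, n_frames = n_frames,
               n_blobs = n_blobs, blob_axes = blob_axes,
               blob_speed_max = blob_speed_max, pan = as.integer(pan),
               cell = cell, overlap_fraction = overlap_fraction,
               dark_frac = dark_frac, bright_frac = bright_frac,
               fg_noise = fg_noise, bg_noise = bg_noise,
               clutter_noise = clutter_noise, extreme_noise = extreme_noise,
               noise_sd = noise_sd, occlusions = occlusions,
               fg_extreme_frac = fg_extreme_frac)
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  if (spec$width < 16 || spec$height < 16) stop("frame too small")
  if (spec$n_frames < 1) stop("need at least one frame")
  if (spec$n_blobs < 0) stop("negative blob count")
  if (2 * max(spec$blob_axes) + 4 > min(spec$width, spec$height))
    stop("blob larger than frame")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 1 ||
      spec$dark_frac < 0 || spec$bright_frac < 0 ||
      spec$overlap_fraction + spec$dark_frac + spec$bright_frac > 1)
    stop("cell-type fractions must be in [0, 1] and sum to at most 1")
  for (oc in spec$occlusions) {
    if (spec$n_blobs > 0 && (oc$blob < 1 || oc$blob > spec$n_blobs))
      stop("occlusion references unknown blob")
    if (oc$start < 0 || oc$length < 1) stop("invalid occlusion schedule")
  }
  invisible(spec)
}

#' Load a scene specification from YAML
#'
#' @param path YAML file whose keys are [scene_spec()] arguments.
#' @return a `scene_spec`.
#' @export
read_scene_spec <- function(path) {
  do.call(scene_spec, yaml::read_yaml(path))
}

luv_fg <- function(n) cbind(L = runif(n, 38, 62), u = runif(n, 4, 16),
                            v = runif(n, 10, 26))
luv_dark <- function(n) cbind(L = runif(n, 2, 6), u = runif(n, -2, 2),
                              v = runif(n, -2, 2))
luv_bright <- function(n) cbind(L = runif(n, 93, 97), u = runif(n, -2, 2),
                                v = runif(n, -2, 2))
luv_bg <- function(n) {
  kind <- sample(c("green", "blue", "tan"), n, replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
  out <- matrix(0, n, 3, dimnames = list(NULL, c("L", "u", "v")))
  g <- kind == "green"; b <- kind == "blue"; tn <- kind == "tan"
  out[g, ] <- cbind(runif(sum(g), 42, 60), runif(sum(g), -32, -12),
                    runif(sum(g), 28, 48))
  out[b, ] <- cbind(runif(sum(b), 55, 72), runif(sum(b), -14, -2),
                    runif(sum(b), -28, -8))
  out[tn, ] <- cbind(runif(sum(tn), 66, 80), runif(sum(tn), 14, 26),
                     runif(sum(tn), 32, 46))
  out
}

# separable box blur with edge replication, radius r
box_blur <- function(m, r) {
  n <- 2L * r + 1L
  pad <- function(x, k) rbind(x[rep(1L, k), , drop = FALSE], x,
                              x[rep(nrow(x), k), , drop = FALSE])
  run <- function(x) {
    cs <- apply(pad(x, r), 2L, cumsum)
    (cs[seq_len(nrow(x)) + 2L * r, , drop = FALSE] -
        rbind(0, cs)[seq_len(nrow(x)), , drop = FALSE]) / n
  }
  t(run(t(run(m))))
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

# Background world model: per-cell palette colors plus static per-pixel
# luminance noise, sampled by the (panning) camera window.
make_world <- function(spec) {
  n <- spec$n_frames
  span_r <- abs(spec$pan[1]) * (n - 1)
  span_c <- abs(spec$pan[2]) * (n - 1)
  hw <- spec$height + span_r
  ww <- spec$width + span_c
  ncr <- ceiling(hw / spec$cell); ncc <- ceiling(ww / spec$cell)
  ncell <- ncr * ncc
  type <- sample(c("confusable", "dark", "bright", "bg"), ncell,
                 replace = TRUE,
                 prob = c(spec$overlap_fraction, spec$dark_frac,
                          spec$bright_frac,
                          1 - spec$overlap_fraction - spec$dark_frac -
                            spec$bright_frac))
  cols <- matrix(0, ncell, 3)
  for (k in c("confusable", "dark", "bright", "bg")) {
    ix <- which(type == k)
    if (length(ix) == 0L) next
    cols[ix, ] <- switch(k, confusable = luv_fg(length(ix)),
                         dark = luv_dark(length(ix)),
                         bright = luv_bright(length(ix)),
                         bg = luv_bg(length(ix)))
  }
  amp <- c(confusable = spec$clutter_noise, dark = spec$extreme_noise,
           bright = spec$extreme_noise, bg = spec$bg_noise)[type]
  cell_of <- function(r, c)
    (pmin(ceiling(c / spec$cell), ncc) - 1L) * ncr +
      pmin(ceiling(r / spec$cell), ncr)
  rr <- matrix(seq_len(hw), hw, ww)
  cc <- matrix(seq_len(ww), hw, ww, byrow = TRUE)
  id <- cell_of(rr, cc)
  luv <- array(0, c(hw, ww, 3))
  noise <- matrix(stats::rnorm(hw * ww), hw, ww) * matrix(amp[id], hw, ww)
  luv[, , 1] <- matrix(cols[id, 1], hw, ww) + noise
  luv[, , 2] <- matrix(cols[id, 2], hw, ww)
  luv[, , 3] <- matrix(cols[id, 3], hw, ww)
  luv[, , 1] <- pmin(pmax(luv[, , 1], 0.5), 99.5)
  # camera origin shift keeping world indices positive for all t
  s0 <- c(max(0L, spec$pan[1] * (n - 1L)), max(0L, spec$pan[2] * (n - 1L)))
  list(luv = luv, s0 = s0)
}

make_blobs <- function(spec) {
  if (spec$n_blobs == 0L) return(list())
  n <- spec$n_frames
  lapply(seq_len(spec$n_blobs), function(b) {
    axes <- sort(round(runif(2, spec$blob_axes[1], spec$blob_axes[2])))
    vel <- sample(seq(-spec$blob_speed_max, spec$blob_speed_max), 2,
                  replace = TRUE)
    lo <- c(axes[1] + 2, axes[2] + 2) + pmax(0, -vel * (n - 1))
    hi <- c(spec$height, spec$width) - c(axes[1], axes[2]) - 2 -
      pmax(0, vel * (n - 1))
    hi <- pmax(hi, lo)   # slow blobs always fit; clamp degenerate ranges
    center <- c(round(runif(1, lo[1], hi[1])), round(runif(1, lo[2], hi[2])))
    color <- luv_fg(1)
    # foreground texture is low-frequency (smoothed noise rescaled to the
    # target amplitude): skin shading varies slowly, unlike background
    # clutter, so 2x2 edge filters barely respond to it
    tex <- matrix(stats::rnorm((2 * axes[1] + 1) * (2 * axes[2] + 1)),
                  2 * axes[1] + 1, 2 * axes[2] + 1)
    tex <- box_blur(tex, 3L)
    tex <- tex * (spec$fg_noise / max(stats::sd(tex), 1e-9))
    list(id = b, axes = axes, vel = vel, center0 = center,
         color = color, tex = tex)
  })
}

blob_center <- function(blob, t) blob$center0 + blob$vel * t

blob_occluded <- function(spec, b, t) {
  for (oc in spec$occlusions)
    if (oc$blob == b && t >= oc$start && t < oc$start + oc$length)
      return(TRUE)
  FALSE
}

render_blob <- function(luv, blob, t) {
  h <- dim(luv)[1]; w <- dim(luv)[2]
  ctr <- blob_center(blob, t)
  m <- ellipse_mask(h, w, ctr, blob$axes)
  idx <- which(m)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  lr <- r - ctr[1] + blob$axes[1] + 1L
  lc <- c - ctr[2] + blob$axes[2] + 1L
  luv[, , 1][idx] <- pmin(pmax(
    blob$color[1] + blob$tex[cbind(lr, lc)], 0.5), 99.5)
  luv[, , 2][idx] <- blob$color[2]
  luv[, , 3][idx] <- blob$color[3]
  list(luv = luv, mask = m)
}

# label connected components of a binary mask (4-connected)
label_mask <- function(mask) {
  lab <- .ms_label(matrix(as.numeric(mask) * 1000, nrow(mask)),
                   matrix(0, nrow(mask), ncol(mask)),
                   matrix(0, nrow(mask), ncol(mask)), 1)
  lab[!mask] <- 0L
  if (any(mask)) {
    u <- sort(unique(lab[mask]))
    map <- integer(max(u)); map[u] <- seq_along(u)
    lab[mask] <- map[lab[mask]]
  }
  lab
}

#' Generate a synthetic image sequence with exact ground truth and flow
#'
#' Renders a panning background of textured color patches and a set of
#' moving foreground blobs, fully reproducible for a fixed seed. Returns
#' the frames, a spatiotemporal [ground_truth()] whose masks stay
#' consistent with the blobs on every frame (including occluded frames,
#' which are flagged), and the exact per-frame-pair flow fields: the
#' background moves with the pan, blob regions with their blob -- also
#' while occluded, so the flow is the true *object* flow and can be
#' injected into tracking via [flow_true()].
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @return list with `frames` (RGB [et_frame()]s), `gt`
#'   ([ground_truth()]), `flows` (list of `n_frames - 1` forward fields)
#'   and `spec`.
#' @export
generate_sequence <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  world <- make_world(spec)
  blobs <- make_blobs(spec)
  n <- spec$n_frames; h <- spec$height; w <- spec$width
  frames <- vector("list", n)
  gt_masks <- vector("list", n)
  regions <- list()
  flows <- vector("list", max(n - 1L, 0L))
  blob_masks <- vector("list", n)
  for (t in seq_len(n) - 1L) {
    orig <- world$s0 - spec$pan * t
    luv <- world$luv[orig[1] + seq_len(h), orig[2] + seq_len(w), ,
                     drop = FALSE]
    masks_t <- vector("list", length(blobs))
    occ_t <- logical(length(blobs))
    for (b in seq_along(blobs)) {
      ctr <- blob_center(blobs[[b]], t)
      occ_t[b] <- blob_occluded(spec, b, t)
      if (!occ_t[b]) {
        res <- render_blob(luv, blobs[[b]], t)
        luv <- res$luv
        masks_t[[b]] <- res$mask
      } else {
        masks_t[[b]] <- ellipse_mask(h, w, ctr, blobs[[b]]$axes)
      }
    }
    blob_masks[[t + 1L]] <- masks_t
    union <- Reduce(`|`, masks_t, matrix(FALSE, h, w))
    lab <- label_mask(union)
    gt_masks[[t + 1L]] <- lab
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    for (id in ids) {
      covering <- vapply(seq_along(blobs), function(b)
        any(lab[masks_t[[b]]] == id), logical(1))
      regions[[length(regions) + 1L]] <- data.frame(
        frame = t, id = id, occluded = all(occ_t[covering]))
    }
    rgb <- luv_to_rgb(luv)
    rgb <- pmin(pmax(rgb + stats::rnorm(length(rgb), sd = spec$noise_sd),
                     0), 1)
    frames[[t + 1L]] <- et_frame(rgb, index = t, space = "RGB")
  }
  for (t in seq_len(max(n - 1L, 0L)) - 1L) {
    field <- array(0, c(h, w, 2))
    field[, , 1] <- spec$pan[1]; field[, , 2] <- spec$pan[2]
    for (b in seq_along(blobs)) {
      m <- blob_masks[[t + 1L]][[b]]
      field[, , 1][m] <- blobs[[b]]$vel[1]
      field[, , 2][m] <- blobs[[b]]$vel[2]
    }
    flows[[t + 1L]] <- field
  }
  regions <- if (length(regions)) do.call(rbind, regions)
  else data.frame(frame = integer(), id = integer(), occluded = logical())
  list(frames = frames, gt = ground_truth(gt_masks, regions),
       flows = flows, spec = spec)
}

#' Generate labeled training images
#'
#' Stand-ins for manually labeled training material: single static frames
#' (no pan, no occlusion) with blobs from the foreground palette on the
#' textured background, plus the exact binary foreground mask. With
#' `fg_extreme_frac > 0`, each blob gets a near-black and a near-white
#' shaded patch *inside* its mask, so the extracted foreground color list
#' contains the unreliable luminance extremes that [luminance_filter()]
#' targets.
#'
#' @param spec a [scene_spec()]; `n_frames`, `pan` and `occlusions` are
#'   ignored.
#' @param n number of image/mask pairs; the default 16 sits in the
#'   10--20 regime this kind of model is trained in.
#' @param seed integer seed.
#' @return list of `list(image, mask)` pairs.
#' @export
generate_training_images <- function(spec, n = 16, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  one <- scene_spec(
    width = spec$width, height = spec$height, n_frames = 1,
    n_blobs = spec$n_blobs, blob_axes = spec$blob_axes,
    blob_speed_max = 0, pan = c(0, 0), cell = spec$cell,
    overlap_fraction = spec$overlap_fraction,
    dark_frac = spec$dark_frac, bright_frac = spec$bright_frac,
    fg_noise = spec$fg_noise, bg_noise = spec$bg_noise,
    clutter_noise = spec$clutter_noise, extreme_noise = spec$extreme_noise,
    noise_sd = spec$noise_sd, occlusions = list(),
    fg_extreme_frac = spec$fg_extreme_frac)
  lapply(seq_len(n), function(i) {
    world <- make_world(one)
    blobs <- make_blobs(one)
    h <- one$height; w <- one$width
    luv <- world$luv[seq_len(h), seq_len(w), , drop = FALSE]
    mask <- matrix(FALSE, h, w)
    for (b in seq_along(blobs)) {
      res <- render_blob(luv, blobs[[b]], 0L)
      luv <- res$luv
      mask <- mask | res$mask
      if (one$fg_extreme_frac > 0) {
        ctr <- blob_center(blobs[[b]], 0L)
        ax <- pmax(round(blobs[[b]]$axes * one$fg_extreme_frac), 2)
        off <- round(blobs[[b]]$axes / 2)
        dark <- ellipse_mask(h, w, ctr - off, ax) & res$mask
        bright <- ellipse_mask(h, w, ctr + off, ax) & res$mask
        luv[, , 1][dark] <- runif(1, 2, 5)
        luv[, , 1][bright] <- runif(1, 94, 97)
        luv[, , 2][dark | bright] <- 0
        luv[, , 3][dark | bright] <- 0
      }
    }
    rgb <- pmin(pmax(luv_to_rgb(luv) +
                       stats::rnorm(h * w * 3, sd = one$noise_sd), 0), 1)
    list(image = et_frame(rgb, index = 0L, space = "RGB"), mask = mask)
  })
}
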