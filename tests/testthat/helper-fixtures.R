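# Shared in-code fixtures: tiny frames, segments, candidate sets and
# independent brute-force oracles used across the suite.

# constant-color RGB frame
const_frame <- function(h, w, rgb = c(0.5, 0.4, 0.3), index = 0L) {
  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  et_frame(px, index = index, space = "RGB")
}

# LUV frame from a matrix per channel (defaults: flat gray)
luv_frame <- function(L, u = NULL, v = NULL, index = 0L) {
  h <- nrow(L); w <- ncol(L)
  if (is.null(u)) u <- matrix(0, h, w)
  if (is.null(v)) v <- matrix(0, h, w)
  et_frame(array(c(L, u, v), c(h, w, 3)), index = index, space = "LUV")
}

rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# color model accepting exactly the colors for which `rule(L, u, v)` is TRUE
rule_model <- function(rule) {
  backend <- list(
    name = "rule",
    fit = function(x, y) rule,
    predict = function(fit, x) {
      factor(ifelse(fit(x[, 1], x[, 2], x[, 3]), "foreground", "background"),
             levels = c("background", "foreground"))
    }
  )
  structure(list(fit = rule, gamma = NA_real_, cost_ratio = 1,
                 luminance_limits = c(0, 100), cv_accuracy = NA_real_,
                 n_sv = NA_integer_, backend = backend),
            class = "color_model")
}

accept_all_model <- function() rule_model(function(L, u, v) rep(TRUE, length(L)))
reject_all_model <- function() rule_model(function(L, u, v) rep(FALSE, length(L)))

# candidate segments per frame from the ground truth of a generated scene
# (occluded regions yield no candidate -- the detector cannot see them)
gt_candidates <- function(seqd) {
  lapply(seq_len(seqd$spec$n_frames), function(i) {
    t <- i - 1L
    regs <- seqd$gt$regions[seqd$gt$regions$frame == t, ]
    lab <- seqd$gt$masks[[i]]
    segs <- list()
    for (k in seq_len(nrow(regs))) {
      if (regs$occluded[k]) next
      segs[[length(segs) + 1L]] <- as_segment(lab == regs$id[k], t, regs$id[k])
    }
    segs
  })
}

# ---- independent brute-force oracles -------------------------------------

bf_jaccard <- function(t, s) {
  length(intersect(t, s)) / length(union(t, s))
}

bf_shape_change <- function(a) (max(a) - min(a)) / max(a)

bf_edge_density <- function(h) {
  tot <- 0
  for (i in seq_len(nrow(h))) for (j in seq_len(ncol(h))) tot <- tot + h[i, j]
  tot / nrow(h)
}

bf_texture_variation <- function(h) {
  s <- 0
  for (j in seq_len(ncol(h))) s <- s + (max(h[, j]) - min(h[, j]))
  s / ncol(h)
}

bf_duration <- function(frames) max(frames) - min(frames) + 1L

bf_instability <- function(frames) {
  lt <- bf_duration(frames)
  sum(!(seq(min(frames), max(frames)) %in% frames)) / lt
}

# union-find connected components over node keys
bf_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(match(edges$a[k], nodes)); rb <- find(match(edges$b[k], nodes))
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  unname(split(nodes, roots))
}

# normalize a component list for comparison: sort within, sort by first key
canon_components <- function(comps) {
  comps <- unname(lapply(comps, function(x) sort(unname(x))))
  comps[order(vapply(comps, `[`, character(1), 1))]
}

empty_links_df <- function() {
  data.frame(a = character(), b = character(),
             confidence = numeric(), span = integer())
}
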