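test_that("Jaccard confidence matches set arithmetic and rejects empty input", {
  m <- rect_mask(6, 6, 2, 3, 2, 3)
  expect_equal(jaccard_confidence(m, m), 1)
  expect_equal(jaccard_confidence(rect_mask(6, 6, 1, 1, 1, 2),
                                  rect_mask(6, 6, 5, 5, 5, 6)), 0)
  # |T| = 4, |S| = 4, overlap 2 -> 2/6
  t4 <- rect_mask(6, 6, 1, 1, 1, 4)
  s4 <- rect_mask(6, 6, 1, 1, 3, 6)
  expect_equal(jaccard_confidence(t4, s4), 2 / 6)
  expect_error(jaccard_confidence(integer(), integer()), "empty")
})

test_that("trace intersection links by strict confidence and bridges gaps", {
  h <- 20; w <- 30
  blob <- rect_mask(h, w, 6, 11, 8, 15)   # 6x8 = 48 px
  seg_at <- function(t, mask, id = 1L) as_segment(mask, t, id)
  src <- seg_at(2L, blob)
  # frame 3: u overlaps the trace heavily, sliver v barely
  u <- rect_mask(h, w, 6, 11, 8, 13)      # 6x6 inside the blob
  v <- rect_mask(h, w, 6, 6, 15, 16)      # 2-px sliver
  # frame 1 empty; frame 0 has k = the blob again (span-2 link over the gap)
  cands <- list(list(seg_at(0L, blob, 3L)), list(), list(src),
                list(seg_at(3L, u, 1L), seg_at(3L, v, 2L)), list())
  tr <- trace_segment(src, flow_zero(c(h, w)), w = 2, n_frames = 5)
  links <- intersect_trace(tr, cands, C = 0.5)
  keys <- paste(links$a, links$b)
  expect_true("f2_s1 f3_s1" %in% keys)       # u linked
  expect_false("f2_s1 f3_s2" %in% keys)      # sliver below C
  expect_true("f2_s1 f0_s3" %in% keys)       # gap bridged, span 2
  expect_equal(links$span[links$b == "f0_s3"], 2)
  expect_true(all(links$confidence > 0.5))
  # candidate identical to the traced mask -> confidence 1 at any C < 1
  links99 <- intersect_trace(tr, cands, C = 0.99)
  expect_equal(links99$confidence[links99$b == "f0_s3"], 1)
})

test_that("raising C yields a nested subset of links", {
  set.seed(61)
  h <- 24; w <- 24
  cands <- lapply(0:5, function(t) {
    lapply(1:3, function(i) {
      r <- sample(3:(h - 8), 1); c <- sample(3:(w - 8), 1)
      as_segment(rect_mask(h, w, r, r + 5, c, c + 5), t, i)
    })
  })
  src <- cands[[3]][[1]]
  tr <- trace_segment(src, flow_zero(c(h, w)), w = 3, n_frames = 6)
  key <- function(l) paste(l$a, l$b, l$span)
  prev <- NULL
  for (C in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cur <- key(intersect_trace(tr, cands, C = C))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the connectivity graph is undirected with collapsed duplicates", {
  s <- as_segment(rect_mask(6, 6, 2, 4, 2, 4), 0L, 1L)
  u <- as_segment(rect_mask(6, 6, 2, 4, 2, 4), 1L, 1L)
  links <- data.frame(a = c("f0_s1", "f1_s1"), b = c("f1_s1", "f0_s1"),
                      confidence = c(0.8, 0.9), span = c(1L, 1L))
  cg <- build_connectivity_graph(list(s, u), links)
  expect_equal(igraph::ecount(cg$graph), 1)
  expect_equal(igraph::E(cg$graph)$confidence, 0.9)  # max kept
  # dangling endpoints and same-frame links error
  bad <- data.frame(a = "f0_s1", b = "f9_s9", confidence = 0.7, span = 1L)
  expect_error(build_connectivity_graph(list(s, u), bad), "endpoint")
  same <- as_segment(rect_mask(6, 6, 1, 2, 1, 2), 0L, 2L)
  sf <- data.frame(a = "f0_s1", b = "f0_s2", confidence = 0.7, span = 0L)
  expect_error(build_connectivity_graph(list(s, same), sf), "same frame")
  # isolated candidates stay as degree-0 nodes
  cg2 <- build_connectivity_graph(list(s, u), empty_links_df())
  expect_equal(igraph::vcount(cg2$graph), 2)
  expect_equal(igraph::ecount(cg2$graph), 0)
})

test_that("subgraph extraction equals union-find on random graphs", {
  set.seed(62)
  for (rep in 1:100) {
    n_frames <- sample(3:6, 1)
    segs <- list()
    for (t in seq_len(n_frames) - 1L) {
      for (i in seq_len(sample(1:4, 1))) {
        segs[[length(segs) + 1L]] <-
          as_segment(rect_mask(8, 8, 2, 4, 2, 4), t, i)
      }
    }
    keys <- vapply(segs, function(s) sprintf("f%d_s%d", s$frame_index, s$id),
                   character(1))
    frames <- vapply(segs, `[[`, integer(1), "frame_index")
    # random inter-frame links (cycles arise naturally)
    pairs <- which(outer(frames, frames, "!=") & upper.tri(diag(length(segs))),
                   arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      take <- pairs[stats::runif(nrow(pairs)) < 0.25, , drop = FALSE]
      links <- data.frame(a = keys[take[, 1]], b = keys[take[, 2]],
                          confidence = stats::runif(nrow(take), 0.6, 1),
                          span = abs(frames[take[, 1]] - frames[take[, 2]]))
    } else links <- empty_links_df()
    cg <- build_connectivity_graph(segs, links)
    got <- canon_components(extract_subgraphs(cg))
    want <- canon_components(bf_components(keys, links))
    expect_equal(got, want)
  }
})

test_that("merging a subgraph unions masks per frame and derives gaps", {
  h <- 10; w <- 10
  a <- as_segment(rect_mask(h, w, 1, 3, 1, 3), 3L, 1L)
  b <- as_segment(rect_mask(h, w, 1, 3, 6, 8), 3L, 2L)   # same frame, disjoint
  c3 <- as_segment(rect_mask(h, w, 2, 4, 2, 4), 4L, 1L)
  d <- as_segment(rect_mask(h, w, 3, 5, 3, 5), 6L, 1L)
  links <- data.frame(a = c("f3_s1", "f3_s2", "f4_s1"),
                      b = c("f4_s1", "f4_s1", "f6_s1"),
                      confidence = 0.9, span = c(1L, 1L, 2L))
  cg <- build_connectivity_graph(list(a, b, c3, d), links)
  comps <- extract_subgraphs(cg)
  expect_length(comps, 1)
  tr <- merge_subgraph(comps[[1]], cg)
  expect_equal(tr$frames, c(3L, 4L, 6L))
  expect_equal(tr$lifetime, 4L)
  expect_equal(tr$gap_frames, 5L)
  # disjoint same-frame members merge additively
  expect_equal(length(tr$masks[["3"]]), a$area + b$area)
  # single-frame component: lifetime 1, no gaps
  e <- as_segment(rect_mask(h, w, 1, 2, 1, 2), 0L, 9L)
  cg2 <- build_connectivity_graph(list(e), empty_links_df())
  tr2 <- merge_subgraph(extract_subgraphs(cg2)[[1]], cg2)
  expect_equal(tr2$lifetime, 1L)
  expect_length(tr2$gap_frames, 0)
})

test_that("tracked links respect the confidence threshold and window", {
  spec <- scene_spec(width = 120, height = 72, n_frames = 10, n_blobs = 2,
                     blob_axes = c(6, 9), pan = c(0, 1), occlusions = list())
  sq <- generate_sequence(spec, seed = 8)
  res <- track_candidates(gt_candidates(sq), flow_true(sq$flows),
                          w = 4L, C = 0.4)
  expect_true(all(res$links$confidence > 0.4))
  expect_true(all(res$links$span <= 4))
  # per-frame union of track masks is within the union of candidate masks
  cand_px <- lapply(gt_candidates(sq), function(cs)
    sort(unique(unlist(lapply(cs, `[[`, "pixels")))))
  for (tr in res$tracks) for (f in tr$frames) {
    expect_true(all(tr$masks[[as.character(f)]] %in% cand_px[[f + 1L]]))
  }
})

test_that("track JSON and GraphML exports are readable", {
  spec <- scene_spec(width = 96, height = 64, n_frames = 6, n_blobs = 1,
                     blob_axes = c(6, 8), pan = c(0, 0), occlusions = list())
  sq <- generate_sequence(spec, seed = 9)
  res <- track_candidates(gt_candidates(sq), flow_true(sq$flows))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_tracks_json(res$tracks, res$links, jpath)
  doc <- jsonlite::read_json(jpath)
  expect_equal(doc$format, "elephtrack-tracks")
  expect_length(doc$tracks, length(res$tracks))
  rle1 <- doc$tracks[[1]]$frames[[1]]$rle
  expect_equal(sum(unlist(rle1$lengths)),
               length(res$tracks[[1]]$masks[[1]]))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(res$graph, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), igraph::vcount(res$graph$graph))
})
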