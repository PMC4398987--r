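#' Jaccard overlap confidence between two pixel sets
#'
#' The confidence of a temporal link: `|T intersect S| / |T union S|`, the
#' portion of overlap between a traced segment and a candidate segment.
#'
#' @param t,s pixel sets on the same frame grid: logical matrices or
#'   integer vectors of linear pixel indices.
#' @return fraction in `[0, 1]`.
#' @export
jaccard_confidence <- function(t, s) {
  if (is.matrix(t)) t <- which(t)
  if (is.matrix(s)) s <- which(s)
  u <- length(union(t, s))
  if (u == 0L) stop("both pixel sets are empty")
  length(intersect(t, s)) / u
}

segment_key <- function(frame_index, id) sprintf("f%d_s%d", frame_index, id)

#' Trace a segment through the temporal window
#'
#' Propagates the segment's mask frame-to-frame by the optical flow, `+w`
#' frames forward and `-w` frames backward (clipped at the sequence ends).
#' Each step warps the current estimate by the flow between the adjacent
#' frames and re-binarizes; propagation stops early in a direction if the
#' estimate empties. The set of all estimates is the segment's *trace*.
#'
#' @param segment an `et_segment`.
#' @param flow a [flow_provider].
#' @param w temporal window half-size in frames (>= 1).
#' @param n_frames number of frames in the sequence.
#' @return an object of class `et_trace`: `source`, `w` and `masks`, a list
#'   of logical matrices named by signed offset (`"-2"`, `"1"`, ...).
#' @export
trace_segment <- function(segment, flow, w = 5L, n_frames) {
  stopifnot(inherits(segment, "et_segment"), w >= 1L)
  t0 <- segment$frame_index
  if (t0 < 0L || t0 > n_frames - 1L) stop("segment frame outside sequence")
  masks <- list()
  for (dir in c(1L, -1L)) {
    m <- segment_mask(segment)
    for (k in seq_len(w)) {
      from <- t0 + dir * (k - 1L)
      to <- t0 + dir * k
      if (to < 0L || to > n_frames - 1L) break
      m <- warp_mask(m, get_flow(flow, from, to))
      if (!any(m)) break
      masks[[as.character(dir * k)]] <- m
    }
  }
  structure(list(source = segment, w = as.integer(w), masks = masks),
            class = "et_trace")
}

#' Intersect a trace with candidate detections
#'
#' For every frame of the temporal window, the traced mask is intersected
#' with the candidate segments detected in that frame; a temporal link is
#' established whenever the Jaccard confidence is strictly above the
#' threshold `C`. Because the window spans up to `w` frames in each
#' direction, links can skip frames where a candidate is missing, bridging
#' short gaps. Splits and merges are handled implicitly: several candidates
#' can link to one trace and vice versa.
#'
#' @param trace an `et_trace`.
#' @param candidates_by_frame list of length `n_frames`; element `t + 1`
#'   holds the candidate segments of frame `t`.
#' @param C confidence threshold in `[0, 1)`.
#' @return data frame of links: `a`, `b` (segment keys), `confidence`,
#'   `span`.
#' @export
intersect_trace <- function(trace, candidates_by_frame, C = 0.5) {
  if (C < 0 || C >= 1) stop("'C' must be in [0, 1)")
  src <- trace$source
  a_key <- segment_key(src$frame_index, src$id)
  bs <- character(); confs <- numeric(); spans <- integer()
  for (off_chr in names(trace$masks)) {
    off <- as.integer(off_chr)
    f <- src$frame_index + off
    cands <- if (f + 1L <= length(candidates_by_frame))
      candidates_by_frame[[f + 1L]] else NULL
    if (length(cands) == 0L) next
    tr <- trace$masks[[off_chr]]
    n_tr <- sum(tr)
    for (cand in cands) {
      inter <- sum(tr[cand$pixels])
      cc <- inter / (n_tr + cand$area - inter)
      if (cc > C) {
        bs <- c(bs, segment_key(cand$frame_index, cand$id))
        confs <- c(confs, cc)
        spans <- c(spans, abs(off))
      }
    }
  }
  data.frame(a = rep(a_key, length(bs)), b = bs,
             confidence = confs, span = spans)
}

#' Build the connectivity graph of candidate segments
#'
#' Nodes are candidate segments (bound to their frames); edges are the
#' temporal links from trace intersection, with orientation dropped.
#' Duplicate links between the same pair collapse to the maximum
#' confidence. Candidates without links remain as isolated nodes -- in
#' practice short-lived spurious detections.
#'
#' @param candidates flat list of candidate `et_segment`s.
#' @param links link data frame (rows as from [intersect_trace()]).
#' @return an object of class `connectivity_graph`: an igraph `graph` plus
#'   the `segments` keyed by node name.
#' @export
build_connectivity_graph <- function(candidates, links) {
  keys <- vapply(candidates, function(s)
    segment_key(s$frame_index, s$id), character(1))
  if (anyDuplicated(keys)) stop("duplicate candidate segments")
  segments <- stats::setNames(candidates, keys)
  if (nrow(links) > 0) {
    if (!all(c(links$a, links$b) %in% keys))
      stop("link endpoint not among candidates")
    if (any(links$a == links$b)) stop("self-link")
    frames <- vapply(segments, `[[`, integer(1), "frame_index")
    if (any(frames[links$a] == frames[links$b]))
      stop("link between segments of the same frame")
    # undirected: collapse a-b and b-a, keep max confidence
    lo <- pmin(links$a, links$b); hi <- pmax(links$a, links$b)
    conf <- tapply(links$confidence, paste(lo, hi, sep = "|"), max)
    pair <- strsplit(names(conf), "|", fixed = TRUE)
    edf <- data.frame(from = vapply(pair, `[[`, character(1), 1),
                      to = vapply(pair, `[[`, character(1), 2),
                      confidence = as.numeric(conf))
  } else {
    edf <- data.frame(from = character(), to = character(),
                      confidence = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(
      name = keys,
      frame = vapply(segments, `[[`, integer(1), "frame_index"),
      segment_id = vapply(segments, `[[`, integer(1), "id")))
  structure(list(graph = g, segments = segments),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph: %d segments, %d links>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Extract the disjoint subgraphs (tracks) of a connectivity graph
#'
#' The connected components of the graph; each component is the set of
#' segments assumed to represent one object over time. Components are
#' ordered by (first frame, lowest segment id), and nodes within a
#' component by (frame, segment id), so the result is deterministic.
#'
#' @param cg a `connectivity_graph`.
#' @return list of character vectors of segment keys.
#' @export
extract_subgraphs <- function(cg) {
  comp <- igraph::components(cg$graph)
  frames <- igraph::V(cg$graph)$frame
  ids <- igraph::V(cg$graph)$segment_id
  names <- igraph::V(cg$graph)$name
  groups <- split(seq_along(names), comp$membership)
  groups <- lapply(groups, function(ix) ix[order(frames[ix], ids[ix])])
  ord <- order(vapply(groups, function(ix) frames[ix[1]], numeric(1)),
               vapply(groups, function(ix) ids[ix[1]], numeric(1)))
  lapply(groups[ord], function(ix) names[ix])
}

#' Merge a subgraph into one spatiotemporal segment
#'
#' Member segments that share a frame are spatially merged (mask union) --
#' the implicit spatial coherence of the subgraph -- and the per-frame
#' merged masks over the component's lifetime form one track. Frames inside
#' the lifetime without any member are the track's gaps.
#'
#' @param component character vector of segment keys (one connected
#'   component).
#' @param cg the `connectivity_graph` the component came from.
#' @param track_id integer id for the new track.
#' @return an object of class `st_track`: `track_id`, `frames`
#'   (sorted frames present), `masks` (list of integer pixel-index vectors
#'   named by frame), `first`, `last`, `lifetime`, `gap_frames`,
#'   `interpolated` (per present frame), `members`, `dim`.
#' @export
merge_subgraph <- function(component, cg, track_id = 1L) {
  stopifnot(length(component) >= 1L)
  segs <- cg$segments[component]
  frames <- vapply(segs, `[[`, integer(1), "frame_index")
  d <- segs[[1]]$dim
  masks <- lapply(split(segs, frames), function(members)
    sort(unique(unlist(lapply(members, `[[`, "pixels")))))
  present <- sort(unique(frames))
  new_st_track(track_id, present, masks, d, members = component)
}

new_st_track <- function(track_id, frames, masks, dim, members = character(),
                         interpolated = NULL) {
  first <- min(frames); last <- max(frames)
  if (is.null(interpolated))
    interpolated <- stats::setNames(rep(FALSE, length(frames)),
                                    as.character(frames))
  structure(
    list(track_id = as.integer(track_id), frames = frames,
         masks = masks[as.character(frames)],
         first = first, last = last, lifetime = last - first + 1L,
         gap_frames = setdiff(seq(first, last), frames),
         interpolated = interpolated, members = members, dim = dim),
    class = "st_track"
  )
}

#' @export
print.st_track <- function(x, ...) {
  cat(sprintf(
    "<st_track %d: frames %d-%d (%d present, %d gaps), %d member segments>\n",
    x$track_id, x$first, x$last, length(x$frames), length(x$gap_frames),
    length(x$members)))
  invisible(x)
}

#' Mask of a track at one frame
#'
#' @param track an `st_track`.
#' @param frame 0-based frame index.
#' @return logical matrix (all-`FALSE` outside `frames`).
#' @export
track_mask <- function(track, frame) {
  m <- matrix(FALSE, track$dim[1], track$dim[2])
  px <- track$masks[[as.character(frame)]]
  if (!is.null(px)) m[px] <- TRUE
  m
}

#' Track candidate segments across a sequence
#'
#' The full tracking stage: every candidate is traced through the `+/-w`
#' frame window, traces are intersected with the candidates of neighboring
#' frames (links require Jaccard confidence `> C`), the undirected
#' connectivity graph is built, and its connected components are spatially
#' merged into spatiotemporal segments.
#'
#' @param candidates_by_frame list (length `n_frames`) of candidate lists.
#' @param flow a [flow_provider].
#' @param w temporal window half-size (frames).
#' @param C link confidence threshold.
#' @return list with `tracks` (list of `st_track`), `graph`
#'   (`connectivity_graph`) and `links` (data frame).
#' @export
track_candidates <- function(candidates_by_frame, flow, w = 5L, C = 0.5) {
  n_frames <- length(candidates_by_frame)
  all_cands <- unlist(candidates_by_frame, recursive = FALSE)
  if (length(all_cands) == 0L)
    return(list(tracks = list(),
                graph = build_connectivity_graph(list(), empty_links()),
                links = empty_links()))
  links <- lapply(all_cands, function(s) {
    tr <- trace_segment(s, flow, w, n_frames)
    intersect_trace(tr, candidates_by_frame, C)
  })
  links <- do.call(rbind, links)
  cg <- build_connectivity_graph(all_cands, links)
  comps <- extract_subgraphs(cg)
  tracks <- lapply(seq_along(comps), function(i)
    merge_subgraph(comps[[i]], cg, track_id = i))
  list(tracks = tracks, graph = cg, links = links)
}

empty_links <- function() {
  data.frame(a = character(), b = character(),
             confidence = numeric(), span = integer())
}

# run-length encoding of a pixel-index mask over the column-major scan
rle_encode <- function(pixels, npix) {
  v <- logical(npix); v[pixels] <- TRUE
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(starts = starts[r$values], lengths = r$lengths[r$values])
}

#' Export tracks as JSON
#'
#' One JSON document per sequence: for every track its id, per-frame
#' run-length-encoded masks (column-major pixel scan), the interpolation
#' flags, and the link list with confidences.
#'
#' @param tracks list of `st_track`.
#' @param links link data frame.
#' @param path output file.
#' @export
write_tracks_json <- function(tracks, links, path) {
  npix <- if (length(tracks)) prod(tracks[[1]]$dim) else 0L
  doc <- list(
    format = "elephtrack-tracks", version = 1L,
    dim = if (length(tracks)) tracks[[1]]$dim else integer(),
    tracks = lapply(tracks, function(tr) list(
      track_id = tr$track_id, first = tr$first, last = tr$last,
      frames = lapply(tr$frames, function(f) list(
        frame = f,
        interpolated = isTRUE(tr$interpolated[[as.character(f)]]),
        rle = rle_encode(tr$masks[[as.character(f)]], npix))))),
    links = links
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a connectivity graph as GraphML
#'
#' @param cg a `connectivity_graph`.
#' @param path output file.
#' @export
write_graphml <- function(cg, path) {
  igraph::write_graph(cg$graph, path, format = "graphml")
  invisible(path)
}
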