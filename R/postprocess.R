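#' Fill tracking gaps by optical-flow interpolation
#'
#' Tracking links can span up to `w` frames, so a validated track may
#' contain short gaps -- frames inside its lifetime where no segment was
#' detected (occlusion, noise, a missed classification). For every gap
#' frame, a mask is interpolated by propagating the temporally nearer
#' flanking mask step-by-step with the cached optical flow (ties go to the
#' earlier flank). Interpolated frames are flagged as synthetic and
#' excluded from any later feature computation; the output track covers
#' the contiguous interval `[first, last]` and has instability 0. The
#' operation is idempotent.
#'
#' @param track an `st_track`.
#' @param flow the [flow_provider] used during tracking.
#' @return the gap-free `st_track`.
#' @export
fill_gaps <- function(track, flow) {
  gaps <- track$gap_frames
  if (length(gaps) == 0L) return(track)
  masks <- track$masks
  interp <- track$interpolated
  for (g in gaps) {
    prev <- max(track$frames[track$frames < g])
    nxt <- min(track$frames[track$frames > g])
    src <- if ((g - prev) <= (nxt - g)) prev else nxt
    m <- track_mask(track, src)
    step <- if (src < g) 1L else -1L
    for (t in seq(src, g - step, by = step))
      m <- warp_mask(m, get_flow(flow, t, t + step))
    masks[[as.character(g)]] <- which(m)
    interp[[as.character(g)]] <- TRUE
  }
  frames <- sort(c(track$frames, gaps))
  new_st_track(track$track_id, frames, masks, track$dim,
               members = track$members,
               interpolated = interp[as.character(frames)])
}
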