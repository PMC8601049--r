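# Local maxima with a topographic-prominence criterion. Boundary frames
# count as candidate maxima when they exceed their inward neighbor: a
# trace that starts exactly at maximum gape still marks a closing onset.
find_gape_maxima <- function(g, prominence_frac = 0.2) {
  n <- length(g)
  if (n < 3L) return(integer(0))
  interior <- which(diff(sign(diff(g))) < 0) + 1L
  # keep only strict peaks (plateau-safe: take first frame of a plateau)
  interior <- interior[g[interior] > g[pmin(interior + 1L, n)] &
                       g[interior] >= g[pmax(interior - 1L, 1L)]]
  # the first frame may start a cycle if it is already a falling maximum;
  # a rising cut at the trailing edge is never a boundary (that cycle is
  # truncated and cannot be closed)
  cand <- interior
  if (g[1] > g[2]) cand <- c(1L, cand)
  cand <- sort(unique(cand[cand < n]))
  if (!length(cand)) return(integer(0))
  # topographic prominence: drop from the peak to the key saddle, the
  # lowest point passed before reaching higher ground; a side that never
  # reaches higher ground (including series edges) contributes no saddle
  prom <- vapply(cand, function(p) {
    lh <- if (p > 1L) which(g[seq_len(p - 1L)] > g[p]) else integer(0)
    lb <- if (length(lh)) min(g[max(lh):p]) else NA_real_
    rh <- if (p < n) which(g[(p + 1L):n] > g[p]) else integer(0)
    rb <- if (length(rh)) min(g[p:(p + min(rh))]) else NA_real_
    if (is.na(lb) && is.na(rb)) return(g[p] - min(g))
    g[p] - max(lb, rb, na.rm = TRUE)
  }, numeric(1))
  iqr_range <- stats::IQR(g, na.rm = TRUE)
  thresh <- prominence_frac * iqr_range
  cand[prom > thresh & prom > 0]
}

#' Segment a jaw-pitch series into gape cycles
#'
#' A gape cycle runs from one gape maximum (initiation of jaw closing)
#' to the next, as a half-open frame interval `[start, end)`; the end
#' frame belongs to the following cycle. Each cycle contains exactly one
#' minimum-gape frame, the opening/closing transition. Maxima are
#' detected by local-extremum search with a prominence threshold (a
#' configurable fraction of the interquartile gape range), which rejects
#' noise wiggles without hard-coding amplitudes. Cycles shorter than
#' `min_cycle_duration_s`, containing missing/flagged frames, or
#' containing externally supplied swallow frames are flagged and
#' excluded from statistics.
#'
#' @param pitch a `jaw_pitch` (filtered series recommended).
#' @param config an `analysis_config`.
#' @param swallow_frames integer frame indices annotated as swallows
#'   (cycles containing them are dropped; no automatic detection).
#' @param missing_frames integer frame indices with missing marker data.
#' @return object of class `gape_cycles`: data.frame with columns
#'   `cycle`, `behavior`, `start`, `end`, `min_gape_frame`,
#'   `duration_s`, `flag_short`, `flag_missing`, `flag_swallow`,
#'   `excluded`. Empty with a `diagnostic` attribute when no cycles are
#'   found.
#' @export
segment_gape_cycles <- function(pitch, config = default_analysis_config(),
                                swallow_frames = integer(0),
                                missing_frames = integer(0)) {
  g <- pitch$gape
  empty <- function(msg) {
    out <- data.frame(cycle = integer(0), behavior = character(0),
                      start = integer(0), end = integer(0),
                      min_gape_frame = integer(0), duration_s = numeric(0),
                      flag_short = logical(0), flag_missing = logical(0),
                      flag_swallow = logical(0), excluded = logical(0))
    attr(out, "diagnostic") <- msg
    class(out) <- c("gape_cycles", "data.frame")
    out
  }
  if (all(!is.finite(g)) || length(g) < 5L) return(empty("no usable samples"))
  if (max(g, na.rm = TRUE) - min(g, na.rm = TRUE) < .Machine$double.eps^0.5)
    return(empty("no cycles: constant gape trace"))
  peaks <- find_gape_maxima(g, config$peak_prominence_frac)
  if (length(peaks) < 2L) return(empty("no cycles: fewer than two gape maxima"))
  starts <- peaks[-length(peaks)]
  ends <- peaks[-1]
  mg <- mapply(function(s, e) {
    idx <- s:(e - 1L)
    idx[which.min(g[idx])]
  }, starts, ends)
  dur <- (ends - starts) / pitch$frame_rate
  flagged_frames <- sort(unique(c(missing_frames, which(pitch$flagged))))
  in_cycle <- function(frames, s, e) any(frames >= s & frames < e)
  flag_missing <- mapply(in_cycle, list(flagged_frames), starts, ends)
  flag_swallow <- mapply(in_cycle, list(as.integer(swallow_frames)),
                         starts, ends)
  flag_short <- dur < config$min_cycle_duration_s
  # degenerate: the minimum must lie strictly inside the cycle
  ok_min <- mg > starts & mg < ends
  out <- data.frame(cycle = seq_along(starts), behavior = config$behavior,
                    start = as.integer(starts), end = as.integer(ends),
                    min_gape_frame = as.integer(mg), duration_s = dur,
                    flag_short = flag_short, flag_missing = flag_missing,
                    flag_swallow = flag_swallow,
                    excluded = flag_short | flag_missing | flag_swallow | !ok_min)
  class(out) <- c("gape_cycles", "data.frame")
  out
}

#' @export
print.gape_cycles <- function(x, ...) {
  analyzed <- if (!is.null(x$excluded)) sum(!x$excluded) else NA_integer_
  cat("gape_cycles:", nrow(x), "detected,", analyzed, "analyzed\n")
  if (!is.null(attr(x, "diagnostic")))
    cat("  diagnostic:", attr(x, "diagnostic"), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# velocity/acceleration by central differences (units per frame);
# one-sided at the ends
central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

# boundary between a fast and slow sub-phase inside `window` (frame
# indices): the acceleration extremum; falls back to the frame where
# speed first crosses 50% of the window's peak speed when the extremum
# sits within `edge_fraction` of the window edge (near-sinusoidal case).
phase_boundary <- function(acc, vel, window, edge_fraction, rising) {
  if (length(window) < 3L)
    return(list(frame = window[ceiling(length(window) / 2)], fallback = TRUE))
  a <- acc[window]
  k <- which.max(a)
  edge <- max(1, ceiling(edge_fraction * length(window)))
  if (k <= edge || k > length(window) - edge) {
    sp <- abs(vel[window])
    half <- 0.5 * max(sp)
    k <- if (rising) which(sp >= half)[1] else rev(which(sp >= half))[1]
    if (is.na(k)) k <- ceiling(length(window) / 2)
    return(list(frame = window[k], fallback = TRUE))
  }
  list(frame = window[k], fallback = FALSE)
}

#' Classify the phases of one gape cycle
#'
#' Splits a cycle into its fast/slow phases from the direction and
#' acceleration of jaw pitch. Chewing cycles have four phases (fast
#' close FC, slow close SC, slow open SO, fast open FO); drinking cycles
#' have three (closing C, open 1 O1, open 2 O2). Closing phases precede
#' the minimum-gape frame, opening phases follow it, and the phase
#' intervals partition `[start, end)` exactly.
#'
#' The FC/SC boundary is the frame of extreme deceleration (acceleration
#' maximum) between peak closing speed and minimum gape; the SO/FO (and
#' O1/O2) boundary is the frame of extreme acceleration between minimum
#' gape and peak opening speed. When the acceleration extremum lies
#' within `edge_fraction` of the search-window edge (near-sinusoidal
#' cycles have no interior extremum), the boundary falls back to the
#' frame where speed first crosses 50% of the window's peak speed, and
#' the cycle is flagged.
#'
#' @param cycle one row of a `gape_cycles` data.frame.
#' @param pitch the `jaw_pitch` the cycles were segmented from.
#' @param behavior `"chew"` or `"drink"` (default: the cycle's).
#' @param config an `analysis_config`.
#' @return object of class `phase_set`: data.frame with columns `phase`,
#'   `start`, `end` (half-open frame intervals, in order), plus a
#'   `fallback` attribute marking degenerate-acceleration cycles.
#' @export
classify_phases <- function(cycle, pitch, behavior = NULL,
                            config = default_analysis_config()) {
  behavior <- behavior %||% cycle$behavior
  s <- cycle$start; e <- cycle$end; mg <- cycle$min_gape_frame
  stopifnot(s < mg, mg < e)
  vel <- central_diff(pitch$gape)
  acc <- central_diff(vel)
  fallback <- FALSE
  closing <- s:(mg - 1L)
  opening <- mg:(e - 1L)
  # opening boundary (both behaviors): between min gape and peak opening speed
  pk_open <- opening[which.max(vel[opening])]
  w_open <- mg:pk_open
  bo <- phase_boundary(acc, vel, w_open, config$edge_fraction, rising = TRUE)
  b_open <- min(max(bo$frame, mg + 1L), e - 1L)
  fallback <- fallback || bo$fallback
  if (behavior == "chew") {
    pk_close <- closing[which.min(vel[closing])]
    w_close <- pk_close:(mg - 1L)
    bc <- phase_boundary(acc, vel, w_close, config$edge_fraction,
                         rising = FALSE)
    b_close <- min(max(bc$frame, s + 1L), mg - 1L)
    fallback <- fallback || bc$fallback
    ph <- data.frame(phase = c("FC", "SC", "SO", "FO"),
                     start = c(s, b_close, mg, b_open),
                     end = c(b_close, mg, b_open, e))
  } else {
    ph <- data.frame(phase = c("C", "O1", "O2"),
                     start = c(s, mg, b_open),
                     end = c(mg, b_open, e))
  }
  attr(ph, "fallback") <- fallback
  attr(ph, "cycle") <- cycle$cycle
  class(ph) <- c("phase_set", "data.frame")
  ph
}

#' Standardized cycle time of a frame
#'
#' Maps a frame inside a cycle to a percentage of cycle duration on
#' `[0, 100)`: 0 at the cycle start (initiation of jaw closing), wrapping
#' modulo 100. Being a fraction of the closed cycle, the quantity is
#' inherently circular.
#'
#' @param frame frame index (vectorized), `cycle.start <= frame < cycle.end`.
#' @param cycle one row of a `gape_cycles` data.frame.
#' @return percent of cycle duration in `[0, 100)`.
#' @export
standardized_time <- function(frame, cycle) {
  if (any(frame < cycle$start | frame >= cycle$end))
    stop("range error: frame outside the cycle [", cycle$start, ", ",
         cycle$end, ")")
  100 * (frame - cycle$start) / (cycle$end - cycle$start)
}
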