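#' Region map from tongue markers
#'
#' Resolves the 10 tongue markers into the regional layout: the anterior
#' midline marker, four left/right pairs, and the posterior midline
#' marker. Five anteroposterior regions R1..R5 run between consecutive
#' "midpoints" (the pair midpoints, with the anterior and posterior
#' midline markers standing in at the ends); four mediolateral widths
#' W1..W4 are the pair distances.
#'
#' @param ms a `marker_set` satisfying [validate_tongue_layout()].
#' @return list with `anterior`, `posterior` (marker names) and `pairs`
#'   (list of 4 `c(left, right)` name pairs).
#' @export
region_map <- function(ms) {
  validate_tongue_layout(ms)
  tg <- ms$markers[ms$markers$role == "tongue", ]
  pairs <- lapply(1:4, function(i) {
    c(left = tg$name[tg$ap_index == i & tg$side == "left"],
      right = tg$name[tg$ap_index == i & tg$side == "right"])
  })
  list(anterior = tg$name[tg$ap_index == 0L],
       posterior = tg$name[tg$ap_index == 5L],
       pairs = pairs)
}

# n x 3 matrices of the six AP "midpoints" per frame
ap_midpoints <- function(positions, map) {
  mids <- vector("list", 6)
  mids[[1]] <- positions[[map$anterior]]
  for (i in 1:4) {
    mids[[i + 1]] <- (positions[[map$pairs[[i]]["left"]]] +
                      positions[[map$pairs[[i]]["right"]]]) / 2
  }
  mids[[6]] <- positions[[map$posterior]]
  mids
}

row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

#' Regional lengths, widths and total length (mm)
#'
#' `regional_lengths()` returns the 3D distances between consecutive
#' midpoints of the left/right marker pairs (with the single midline
#' markers at the anterior and posterior ends); `regional_widths()` the
#' 3D distances between the right and left markers of each pair;
#' `total_length()` the exact sum of the five regional lengths (which,
#' by the triangle inequality, is at least the straight anterior to
#' posterior distance, capturing off-axis shape change).
#'
#' @param positions named list of `n x 3` marker position matrices (mm).
#' @param map a [region_map()].
#' @return `n x 5` matrix (`R1..R5`) / `n x 4` matrix (`W1..W4`) /
#'   numeric vector, respectively. Frames with missing markers yield
#'   `NA`.
#' @export
regional_lengths <- function(positions, map) {
  mids <- ap_midpoints(positions, map)
  out <- vapply(1:5, function(i) row_dist(mids[[i]], mids[[i + 1]]),
                numeric(nrow(mids[[1]])))
  out <- matrix(out, ncol = 5, dimnames = list(NULL, paste0("R", 1:5)))
  out
}

#' @rdname regional_lengths
#' @export
regional_widths <- function(positions, map) {
  out <- vapply(1:4, function(i) {
    row_dist(positions[[map$pairs[[i]]["left"]]],
             positions[[map$pairs[[i]]["right"]]])
  }, numeric(nrow(positions[[1]])))
  matrix(out, ncol = 4, dimnames = list(NULL, paste0("W", 1:4)))
}

#' @rdname regional_lengths
#' @param lengths `n x 5` matrix of regional lengths.
#' @export
total_length <- function(lengths) {
  unname(rowSums(lengths))
}

#' Per-frame deformation series
#'
#' Computes raw regional lengths R1..R5, widths W1..W4 and total length
#' (mm) per frame and, when a rest configuration is supplied, their
#' normalized counterparts (raw / rest; 1.0 = rest). The normalized
#' total is `sum(raw regions) / sum(rest regions)`, so the
#' sum-of-regional-deformations identity holds in normalized space with
#' region weights proportional to the rest lengths. Frames with any
#' missing tongue marker are flagged.
#'
#' @param ms a `marker_set` (typically already expressed in the skull
#'   frame); alternatively a named list of position matrices via
#'   `positions`.
#' @param rest a `rest_config`, or `NULL` for raw distances only.
#' @param positions optional named list of `n x 3` matrices overriding
#'   `ms$positions` (e.g. skull-frame coordinates).
#' @return object of class `deformation_series`: data.frame with
#'   `frame`, raw columns `R1..R5`, `W1..W4`, `total`, normalized
#'   columns `*_norm` when `rest` is given, and a logical `flagged`
#'   column.
#' @export
deformation_series <- function(ms, rest = NULL, positions = NULL) {
  map <- region_map(ms)
  pos <- positions %||% ms$positions
  lens <- regional_lengths(pos, map)
  wids <- regional_widths(pos, map)
  tot <- total_length(lens)
  out <- data.frame(frame = seq_len(nrow(lens)), lens, wids, total = tot)
  out$flagged <- !stats::complete.cases(cbind(lens, wids))
  if (!is.null(rest)) {
    rl <- rest$rest_regional_lengths
    rw <- rest$rest_widths
    norm <- cbind(sweep(lens, 2, rl, "/"), sweep(wids, 2, rw, "/"),
                  total = tot / sum(rl))
    colnames(norm) <- paste0(c(paste0("R", 1:5), paste0("W", 1:4), "total"),
                             "_norm")
    out <- cbind(out, norm)
  }
  class(out) <- c("deformation_series", "data.frame")
  out
}

#' @export
print.deformation_series <- function(x, ...) {
  cat("deformation_series:", nrow(x), "frames,",
      sum(x$flagged), "flagged;",
      if (any(grepl("_norm$", names(x)))) "normalized" else "raw only", "\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# extremum index under a tie rule
which_extreme <- function(v, fn, tie_rule) {
  target <- fn(v)
  idx <- which(v == target)
  if (tie_rule == "last") idx[length(idx)] else idx[1]
}

#' Per-cycle deformation magnitudes and timings
#'
#' For every unflagged cycle and every normalized measure (total,
#' R1..R5, W1..W4), finds the maximum and minimum over the half-open
#' cycle `[start, end)`, their difference (the per-cycle deformation
#' magnitude, delta = max - min >= 0), and the timings of the extrema as
#' standardized cycle time. Ties are broken by `tie_rule` (default first
#' occurrence). Cycles containing any flagged frame are suppressed.
#'
#' @param ds a `deformation_series` with normalized columns.
#' @param cycles a `gape_cycles` data.frame.
#' @param tie_rule `"first"` or `"last"`.
#' @return data.frame of class `cycle_summary`: columns `cycle`,
#'   `behavior`, `measure`, `max_norm`, `min_norm`, `delta`, `t_max`,
#'   `t_min`, `f_max`, `f_min`.
#' @export
cycle_deformation_summary <- function(ds, cycles, tie_rule = "first") {
  normcols <- grep("_norm$", names(ds), value = TRUE)
  if (!length(normcols))
    stop("deformation series has no normalized columns; supply a rest config")
  measures <- sub("_norm$", "", normcols)
  rows <- list()
  for (k in seq_len(nrow(cycles))) {
    cy <- cycles[k, ]
    if (cy$excluded) next
    idx <- cy$start:(cy$end - 1L)
    if (any(ds$flagged[idx])) next  # summary suppressed for this cycle
    for (m in seq_along(measures)) {
      v <- ds[[normcols[m]]][idx]
      imax <- which_extreme(v, max, tie_rule)
      imin <- which_extreme(v, min, tie_rule)
      f_max <- idx[imax]; f_min <- idx[imin]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = cy$cycle, behavior = cy$behavior, measure = measures[m],
        max_norm = v[imax], min_norm = v[imin], delta = v[imax] - v[imin],
        t_max = standardized_time(f_max, cy),
        t_min = standardized_time(f_min, cy),
        f_max = f_max, f_min = f_min)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cycle = integer(0), behavior = character(0),
               measure = character(0), max_norm = numeric(0),
               min_norm = numeric(0), delta = numeric(0), t_max = numeric(0),
               t_min = numeric(0), f_max = integer(0), f_min = integer(0))
  class(out) <- c("cycle_summary", "data.frame")
  out
}

#' Length-width trade-off records
#'
#' For each region that has a width (R1..R4) and each summarized cycle,
#' emits two records pairing the cycle's extreme normalized length with
#' the same region's normalized width at the same frame: one at the
#' length maximum, one at the length minimum. Under the muscular
#' hydrostat expectation, maximum-length records should show narrower
#' widths than minimum-length records. R5 has no corresponding width and
#' is excluded by construction.
#'
#' @param summary a `cycle_summary`.
#' @param ds the `deformation_series` the summary came from.
#' @return data.frame with columns `cycle`, `behavior`, `region`,
#'   `extreme` (`"max"`/`"min"`), `length_norm`, `width_norm`, `frame`.
#' @export
length_width_pairs <- function(summary, ds) {
  regs <- paste0("R", 1:4)
  sub <- summary[summary$measure %in% regs, ]
  if (!nrow(sub))
    return(data.frame(cycle = integer(0), behavior = character(0),
                      region = character(0), extreme = character(0),
                      length_norm = numeric(0), width_norm = numeric(0),
                      frame = integer(0)))
  wcol <- function(region) paste0("W", substring(region, 2), "_norm")
  recs <- lapply(seq_len(nrow(sub)), function(i) {
    r <- sub[i, ]
    data.frame(cycle = r$cycle, behavior = r$behavior, region = r$measure,
               extreme = c("max", "min"),
               length_norm = c(r$max_norm, r$min_norm),
               width_norm = ds[[wcol(r$measure)]][c(r$f_max, r$f_min)],
               frame = c(r$f_max, r$f_min))
  })
  do.call(rbind, recs)
}
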