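#' Construct a marker trajectory set
#'
#' Bundles per-marker 3D trajectories (mm) with marker metadata and the
#' sampling rate. Markers carry a role (`skull`, `jaw`, `tongue`), a side
#' (`left`, `right`, `midline`) and, for tongue markers, an
#' anteroposterior index `ap_index` (0 = anterior midline, 1..4 =
#' left/right pairs, 5 = posterior midline).
#'
#' @param positions named list, one `n_frames x 3` numeric matrix per
#'   marker (columns x, y, z in mm). `NA` entries mark missing samples.
#' @param info data.frame with columns `name`, `role`, `side`,
#'   `ap_index` (one row per marker, names matching `positions`).
#' @param frame_rate sampling rate in frames per second.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(positions, info, frame_rate) {
  if (!is.list(positions) || is.null(names(positions)))
    stop("`positions` must be a named list of n x 3 matrices")
  if (!all(c("name", "role", "side", "ap_index") %in% names(info)))
    stop("`info` must have columns name, role, side, ap_index")
  info$name <- as.character(info$name)
  if (!setequal(names(positions), info$name))
    stop("marker names in `positions` and `info` disagree")
  positions <- positions[info$name]
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("all markers must share the same number of frames; found ",
         paste(unique(nf), collapse = ", "))
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("`frame_rate` must be a positive number")
  bad <- vapply(positions, function(p) any(!is.finite(p) & !is.na(p)), logical(1))
  if (any(bad))
    stop("non-finite coordinates (not NA) in markers: ",
         paste(info$name[bad], collapse = ", "))
  x <- list(positions = positions, markers = info,
            frame_rate = frame_rate, n_frames = unname(nf[1]))
  class(x) <- "marker_set"
  x
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", nrow(x$markers), "markers x", x$n_frames,
      "frames @", x$frame_rate, "fps\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$markers$role)),
                                table(x$markers$role)), collapse = ", "), "\n")
  miss <- sum(vapply(x$positions, function(p) sum(!stats::complete.cases(p)),
                     integer(1)))
  if (miss > 0) cat("  missing marker-frames:", miss, "\n")
  invisible(x)
}

#' Validate tongue-marker layout for regional analysis
#'
#' Checks that the tongue markers form the layout the regional
#' length/width metrics require: one anterior midline marker
#' (`ap_index` 0), four left/right pairs (`ap_index` 1..4), and one
#' posterior midline marker (`ap_index` 5).
#'
#' @param ms a `marker_set`.
#' @return invisibly `TRUE`; errors describe the violation.
#' @export
validate_tongue_layout <- function(ms) {
  tg <- ms$markers[ms$markers$role == "tongue", ]
  for (ap in c(0L, 5L)) {
    m <- tg[tg$ap_index == ap, ]
    if (nrow(m) != 1L || m$side != "midline")
      stop("tongue layout: ap_index ", ap, " must be a single midline marker")
  }
  for (ap in 1:4) {
    m <- tg[tg$ap_index == ap, ]
    if (nrow(m) != 2L || !setequal(m$side, c("left", "right")))
      stop("tongue layout: ap_index ", ap,
           " must be a left/right pair; found sides {",
           paste(m$side, collapse = ","), "}")
  }
  if (nrow(tg) != 10L)
    stop("regional analysis needs exactly 10 tongue markers, found ", nrow(tg))
  invisible(TRUE)
}

#' Write marker trajectories to the self-describing CSV dialect
#'
#' The file starts with `#`-prefixed header lines declaring the format
#' version, frame rate, units, and one `# marker:` line per marker
#' (`name role side ap_index`), followed by a wide numeric body
#' `frame,<name>_x,<name>_y,<name>_z,...`. Missing samples are written as
#' empty cells. Coordinates are serialized with 17 significant digits so
#' a write/read round trip reproduces doubles exactly.
#'
#' @param ms a `marker_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_trajectories <- function(ms, path) {
  info <- ms$markers
  hdr <- c("# linguakin-markers v1",
           sprintf("# frame_rate: %.17g", ms$frame_rate),
           "# units: mm",
           sprintf("# marker: %s %s %s %d",
                   info$name, info$role, info$side, info$ap_index))
  cols <- lapply(info$name, function(nm) {
    p <- ms$positions[[nm]]
    vals <- lapply(1:3, function(j) {
      v <- sprintf("%.17g", p[, j])
      v[is.na(p[, j])] <- ""
      v
    })
    names(vals) <- paste0(nm, "_", c("x", "y", "z"))
    vals
  })
  body <- c(list(frame = as.character(seq_len(ms$n_frames))),
            unlist(cols, recursive = FALSE))
  lines <- c(hdr, paste(names(body), collapse = ","),
             do.call(paste, c(body, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read marker trajectories from the linguakin CSV dialect
#'
#' Parses the header block written by [write_marker_trajectories()] and
#' the wide numeric body. Missing samples (empty cells) are carried as
#' `NA` and flagged, never interpolated.
#'
#' @param path input file path.
#' @param regional if `TRUE`, additionally validate the 10-marker tongue
#'   layout required for regional analysis.
#' @return a `marker_set`.
#' @export
read_marker_trajectories <- function(path, regional = FALSE) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("^# linguakin-markers", hdr[1]))
    stop("format error: missing '# linguakin-markers' header line")
  fr_line <- grep("^# frame_rate:", hdr, value = TRUE)
  if (length(fr_line) != 1L)
    stop("format error: header must declare 'frame_rate' exactly once")
  frame_rate <- as.numeric(sub("^# frame_rate:\\s*", "", fr_line))
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("format error: invalid frame_rate in header")
  units_line <- grep("^# units:", hdr, value = TRUE)
  if (length(units_line) == 1L && trimws(sub("^# units:", "", units_line)) != "mm")
    stop("format error: units must be mm, found ",
         trimws(sub("^# units:", "", units_line)))
  mk <- sub("^# marker:\\s*", "", grep("^# marker:", hdr, value = TRUE))
  if (!length(mk)) stop("format error: no '# marker:' declarations in header")
  parts <- strsplit(trimws(mk), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("format error: malformed marker declaration: '", mk[bad[1]], "'")
  info <- data.frame(name = vapply(parts, `[`, "", 1),
                     role = vapply(parts, `[`, "", 2),
                     side = vapply(parts, `[`, "", 3),
                     ap_index = as.integer(vapply(parts, `[`, "", 4)),
                     stringsAsFactors = FALSE)
  if (!all(info$role %in% c("skull", "jaw", "tongue")))
    stop("format error: marker roles must be skull/jaw/tongue")
  if (!all(info$side %in% c("left", "right", "midline")))
    stop("format error: marker sides must be left/right/midline")

  body <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          check.names = FALSE)
  if (!"frame" %in% names(body))
    stop("format error: body must have a 'frame' column")
  expected <- as.vector(t(outer(info$name, c("_x", "_y", "_z"), paste0)))
  missing_cols <- setdiff(expected, names(body))
  if (length(missing_cols))
    stop("format error: missing column '", missing_cols[1], "'")
  positions <- lapply(info$name, function(nm) {
    m <- as.matrix(body[, paste0(nm, c("_x", "_y", "_z"))])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    storage.mode(m) <- "double"
    m
  })
  names(positions) <- info$name
  ms <- marker_set(positions, info, frame_rate)
  if (regional) validate_tongue_layout(ms)
  ms
}

#' Frames with any missing tongue-marker sample
#'
#' @param ms a `marker_set`.
#' @param role marker role to inspect (default `"tongue"`).
#' @return integer vector of frame indices with incomplete data.
#' @export
missing_frames <- function(ms, role = "tongue") {
  nms <- ms$markers$name[ms$markers$role == role]
  if (!length(nms)) return(integer(0))
  bad <- Reduce(`|`, lapply(ms$positions[nms],
                            function(p) !stats::complete.cases(p)))
  which(bad)
}

#' Read a rest configuration (resting inter-marker distances)
#'
#' The rest configuration holds the resting regional lengths R1..R5 and
#' widths W1..W4 (mm), typically measured from an in vivo CT scan with
#' the tongue in a relaxed neutral posture; all instantaneous lengths and
#' widths are normalized to these values (1.0 = rest).
#'
#' @param path YAML file with keys `rest_regional_lengths` (5 values),
#'   `rest_widths` (4 values), optional `provenance`.
#' @return object of class `rest_config`: list with fields
#'   `rest_regional_lengths`, `rest_widths`, `provenance`.
#' @export
read_rest_config <- function(path) {
  if (!file.exists(path)) stop("rest config not found: ", path)
  y <- yaml::read_yaml(path)
  rest_config(y$rest_regional_lengths, y$rest_widths,
              y$provenance %||% "unspecified")
}

#' @rdname read_rest_config
#' @param rest_regional_lengths numeric(5), mm.
#' @param rest_widths numeric(4), mm.
#' @param provenance free-text origin of the measurements.
#' @export
rest_config <- function(rest_regional_lengths, rest_widths,
                        provenance = "unspecified") {
  lens <- as.numeric(rest_regional_lengths)
  wids <- as.numeric(rest_widths)
  if (length(lens) != 5L)
    stop("rest config validation: need 5 regional lengths (R1..R5), found ",
         length(lens))
  if (length(wids) != 4L)
    stop("rest config validation: need 4 widths (W1..W4), found ",
         length(wids))
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("rest config validation: regional lengths must all be positive")
  if (any(!is.finite(wids)) || any(wids <= 0))
    stop("rest config validation: widths must all be positive")
  structure(list(rest_regional_lengths = lens, rest_widths = wids,
                 provenance = provenance),
            class = "rest_config")
}

#' @rdname read_rest_config
#' @param rc a `rest_config`.
#' @export
write_rest_config <- function(rc, path) {
  yaml::write_yaml(list(rest_regional_lengths = rc$rest_regional_lengths,
                        rest_widths = rc$rest_widths,
                        provenance = rc$provenance), path)
  invisible(path)
}

#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one list. Defaults follow
#' common motion-capture practice: order-2 Butterworth applied
#' forward-backward (zero phase) with a 25 Hz cutoff, filtering applied
#' to marker coordinates before pose fitting.
#'
#' @param ... overrides of the defaults, by name.
#' @return object of class `analysis_config`.
#' @export
default_analysis_config <- function(...) {
  cfg <- list(
    butterworth_cutoff_hz = 25,
    butterworth_order = 2L,
    filter_target = "coordinates",  # coordinates | pitch | both | none
    opening_sign = 1,
    behavior = "chew",
    min_cycle_duration_s = 0.1,
    extremum_tie_rule = "first",
    peak_prominence_frac = 0.2,
    edge_fraction = 0.05,
    permutation_count = 999L,
    random_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_analysis_config(structure(cfg, class = "analysis_config"))
}

validate_analysis_config <- function(cfg) {
  if (!cfg$filter_target %in% c("coordinates", "pitch", "both", "none"))
    stop("filter_target must be coordinates/pitch/both/none")
  if (!cfg$opening_sign %in% c(-1, 1)) stop("opening_sign must be +1 or -1")
  if (!cfg$behavior %in% c("chew", "drink"))
    stop("behavior must be 'chew' or 'drink'")
  if (!cfg$extremum_tie_rule %in% c("first", "last"))
    stop("extremum_tie_rule must be 'first' or 'last'")
  if (cfg$permutation_count < 1) stop("permutation_count must be >= 1")
  if (cfg$butterworth_cutoff_hz <= 0) stop("cutoff must be positive")
  cfg
}

#' @rdname default_analysis_config
#' @param path YAML file of config overrides.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("analysis config not found: ", path)
  do.call(default_analysis_config, yaml::read_yaml(path))
}

#' @rdname default_analysis_config
#' @param cfg an `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write magnitude summary tables
#'
#' Writes one CSV row per measure x behavior with n, mean and SD of the
#' per-cycle delta, maximum and minimum (the shape of a published
#' chew-vs-drink magnitude table). SD is reported as `NA` when n < 2.
#' Column and row order are deterministic.
#'
#' @param summaries per-cycle deformation summary (from
#'   [cycle_deformation_summary()]), with a `behavior` column.
#' @param path output CSV path.
#' @return the written table, invisibly.
#' @export
write_summary_tables <- function(summaries, path) {
  tab <- summarize_magnitudes(summaries)
  if (nrow(summaries) == 0L)
    warning("empty summaries: writing header-only table")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

measure_levels <- function() c("total", paste0("R", 1:5), paste0("W", 1:4))
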