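#' Run the full analysis pipeline on one recording
#'
#' Orchestrates the chain: read markers and rest configuration, low-pass
#' filter (per config), fit skull and jaw rigid poses, express tongue
#' markers in the skull frame, extract jaw pitch, segment gape cycles,
#' classify phases, compute normalized deformations, summarize per-cycle
#' magnitudes and timings, and write all tabular outputs plus a JSON run
#' manifest. Outputs are a pure function of (inputs, config), so reruns
#' are byte-identical.
#'
#' @param markers_file marker trajectory CSV (see
#'   [read_marker_trajectories()]).
#' @param rest_file rest configuration YAML.
#' @param config an `analysis_config` (or path to one).
#' @param out_dir output directory (created if needed).
#' @param swallow_frames integer frames annotated as swallows; cycles
#'   containing them are excluded.
#' @return invisibly, a list with all intermediate objects (`markers`,
#'   `pitch`, `cycles`, `phases`, `deformation`, `summary`, `pairs`,
#'   `magnitude_table`, `timing_table`, `manifest`, `out_dir`).
#' @export
run_analysis <- function(markers_file, rest_file,
                         config = default_analysis_config(),
                         out_dir, swallow_frames = integer(0)) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- validate_analysis_config(config)
  stage <- "io"
  res <- tryCatch({
    ms <- read_marker_trajectories(markers_file, regional = TRUE)
    rest <- read_rest_config(rest_file)
    if (config$filter_target != "none" &&
        config$butterworth_cutoff_hz >= ms$frame_rate / 2)
      stop("butterworth cutoff must be below Nyquist (",
           ms$frame_rate / 2, " Hz)")

    stage <- "filtering"
    if (config$filter_target %in% c("coordinates", "both")) {
      ms$positions <- lapply(ms$positions, function(p) {
        if (anyNA(p)) return(p)  # missing data: left raw, frames flagged
        lowpass_filter(p, config$butterworth_cutoff_hz,
                       config$butterworth_order, ms$frame_rate)
      })
    }

    stage <- "pose"
    skull_poses <- fit_pose_series(ms, "skull")
    jaw_poses <- fit_pose_series(ms, "jaw")
    pitch <- jaw_pitch_series(skull_poses, jaw_poses,
                              opening_sign = config$opening_sign)
    if (config$filter_target %in% c("pitch", "both")) {
      rz_f <- lowpass_filter(pitch$rz, config$butterworth_cutoff_hz,
                             config$butterworth_order, ms$frame_rate)
      pitch <- jaw_pitch(rz_f, ms$frame_rate, config$opening_sign,
                         gimbal_flag = pitch$gimbal_flag,
                         flagged = pitch$flagged)
    }
    tongue_names <- ms$markers$name[ms$markers$role == "tongue"]
    tongue_skull <- to_skull_frame(ms$positions[tongue_names], skull_poses)

    stage <- "segmentation"
    miss <- sort(unique(c(missing_frames(ms, "tongue"), which(pitch$flagged))))
    cycles <- segment_gape_cycles(pitch, config, swallow_frames, miss)
    phases <- if (nrow(cycles)) do.call(rbind, lapply(
      which(!cycles$excluded), function(k) {
        ph <- classify_phases(cycles[k, ], pitch, config = config)
        data.frame(cycle = cycles$cycle[k], as.data.frame(ph),
                   fallback = attr(ph, "fallback"))
      })) else data.frame(cycle = integer(0), phase = character(0),
                          start = integer(0), end = integer(0),
                          fallback = logical(0))

    stage <- "deformation"
    ds <- deformation_series(ms, rest, positions = tongue_skull)
    summ <- cycle_deformation_summary(ds, cycles, config$extremum_tie_rule)
    pairs <- length_width_pairs(summ, ds)
    mag <- summarize_magnitudes(summ)
    timing <- timing_summary(summ)

    stage <- "output"
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(x), p, row.names = FALSE, quote = FALSE)
      p
    }
    outputs <- c(
      deformation = wcsv(ds, "deformation.csv"),
      cycles = wcsv(cycles, "cycles.csv"),
      phases = wcsv(phases, "phases.csv"),
      cycle_summary = wcsv(summ, "cycle_summary.csv"),
      magnitude_table = wcsv(mag, "magnitude_table.csv"),
      timing_summary = wcsv(timing, "timing_summary.csv"),
      length_width_pairs = wcsv(pairs, "length_width_pairs.csv"),
      config = file.path(out_dir, "config.yaml"))
    write_analysis_config(config, outputs[["config"]])
    manifest <- list(
      tool = "linguakin",
      config = unclass(config),
      inputs = list(
        markers = unname(tools::md5sum(markers_file)),
        rest = unname(tools::md5sum(rest_file))),
      seed = config$random_seed,
      frames = ms$n_frames,
      frame_rate = ms$frame_rate,
      cycles_detected = nrow(cycles),
      cycles_flagged = sum(cycles$excluded),
      cycles_analyzed = sum(!cycles$excluded),
      outputs = basename(outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(markers = ms, pitch = pitch, cycles = cycles, phases = phases,
         deformation = ds, summary = summ, pairs = pairs,
         magnitude_table = mag, timing_table = timing,
         manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# circular timing summary per measure x extremum
timing_summary <- function(summ) {
  if (!nrow(summ))
    return(data.frame(measure = character(0), behavior = character(0),
                      event = character(0), circ_mean = numeric(0),
                      R = numeric(0), variance = numeric(0),
                      circ_sd = numeric(0), n = integer(0)))
  grid <- expand.grid(measure = unique(summ$measure),
                      behavior = unique(summ$behavior),
                      event = c("t_max", "t_min"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    v <- summ[[g$event]][summ$measure == g$measure &
                         summ$behavior == g$behavior]
    if (!length(v)) return(NULL)
    d <- suppressWarnings(circ_dispersion(v))
    data.frame(measure = g$measure, behavior = g$behavior, event = g$event,
               circ_mean = d$circ_mean, R = d$R, variance = d$variance,
               circ_sd = d$circ_sd, n = d$n)
  })
  out <- do.call(rbind, rows)
  out[order(match(out$measure, measure_levels()), out$behavior, out$event), ]
}

#' Compare two analyzed recordings (behaviors)
#'
#' Reads the per-cycle summaries of two completed [run_analysis()]
#' output directories (e.g. chewing and drinking) and compares them:
#' per-measure magnitude differences (stratified permutation test on
#' the per-cycle deltas) and circular timing differences of the extrema
#' (stratified permutation test on the circular means of t_max/t_min).
#' One magnitude row per measure (total, R1..R5, W1..W4) and two timing
#' rows per measure (t_max, t_min).
#'
#' @param dir_a,dir_b output directories of two completed analyses.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param out_dir optional directory for the comparison CSVs.
#' @return list with data.frames `magnitude` and `timing`.
#' @export
run_comparison <- function(dir_a, dir_b, n_perm = 999, seed = 1,
                           out_dir = NULL) {
  read_summ <- function(d) {
    p <- file.path(d, "cycle_summary.csv")
    if (!file.exists(p)) stop("no cycle_summary.csv in ", d,
                              "; run run_analysis() first")
    utils::read.csv(p)
  }
  sa <- read_summ(dir_a); sb <- read_summ(dir_b)
  if (!setequal(unique(sa$measure), unique(sb$measure)))
    stop("config error: the two analyses use different region maps")
  measures <- intersect(measure_levels(), unique(sa$measure))
  mag <- do.call(rbind, lapply(seq_along(measures), function(i) {
    m <- measures[i]
    a <- sa$delta[sa$measure == m]; b <- sb$delta[sb$measure == m]
    r <- compare_magnitudes(a, b, n_perm = n_perm, seed = seed + i)
    data.frame(measure = m, n_a = r$n_a, n_b = r$n_b,
               mean_a = mean(a), mean_b = mean(b),
               observed_diff = r$observed, p_value = r$p_value,
               n_perm = r$n_perm, seed = r$seed)
  }))
  timing <- do.call(rbind, lapply(seq_along(measures), function(i) {
    m <- measures[i]
    do.call(rbind, lapply(c("t_max", "t_min"), function(ev) {
      a <- sa[[ev]][sa$measure == m]; b <- sb[[ev]][sb$measure == m]
      r <- circ_permutation_test(a, b, n_perm = n_perm,
                                 seed = seed + 100 + 2 * i +
                                   (ev == "t_min"))
      data.frame(measure = m, event = ev,
                 circ_mean_a = suppressWarnings(circ_mean(a)),
                 circ_mean_b = suppressWarnings(circ_mean(b)),
                 observed_dist = r$observed, p_value = r$p_value,
                 n_perm = r$n_perm, seed = r$seed)
    }))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(mag, file.path(out_dir, "comparison_magnitude.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(timing, file.path(out_dir, "comparison_timing.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(magnitude = mag, timing = timing)
}
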