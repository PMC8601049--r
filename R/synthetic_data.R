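# Gaussian smoothing with odd-reflection edge padding; used to round the
# corners of piecewise-linear gape traces and to blend per-cycle
# amplitude steps into continuous waveforms.
gauss_smooth <- function(x, sd_frames) {
  if (sd_frames <= 0) return(x)
  half <- max(2L, ceiling(5 * sd_frames))
  k <- stats::dnorm(seq(-half, half), sd = sd_frames)
  k <- k / sum(k)
  n <- length(x)
  npad <- min(n - 1, half)
  ext <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- stats::filter(ext, k, sides = 2)
  as.numeric(y[(npad + 1):(npad + n)])
}

#' Gape-cycle specification for the synthetic generator
#'
#' Defines the rhythmic jaw trace the generator emits: per-phase
#' durations (chew: FC, SC, SO, FO; drink: C, O1, O2), gape amplitude,
#' frame rate, cycle-to-cycle duration jitter and additive gape noise.
#' Fast phases traverse `fast_fraction` of the gape amplitude, so their
#' mean angular speed exceeds the slow phases' by construction; the
#' specification is rejected if it does not.
#'
#' @param behavior `"chew"` or `"drink"`.
#' @param phase_durations_s named durations in seconds: chew
#'   `c(FC=, SC=, SO=, FO=)`, drink `c(C=, O1=, O2=)`.
#' @param gape_amplitude_deg peak-to-peak gape amplitude in degrees.
#' @param frame_rate frames per second (default 250).
#' @param duration_jitter fractional cycle-to-cycle duration jitter
#'   (uniform, default 0.03).
#' @param noise_sd_deg additive Gaussian noise on the gape trace
#'   (degrees, default 0).
#' @param fast_fraction fraction of the gape amplitude traversed during
#'   the fast sub-phase of closing/opening (default 0.75).
#' @param smooth_sd_s Gaussian corner-smoothing SD in seconds (default
#'   0.008, i.e. 2 frames at 250 fps).
#' @return object of class `cycle_spec`.
#' @export
cycle_spec <- function(behavior,
                       phase_durations_s = NULL,
                       gape_amplitude_deg = NULL,
                       frame_rate = 250,
                       duration_jitter = 0.03,
                       noise_sd_deg = 0,
                       fast_fraction = 0.75,
                       smooth_sd_s = 0.008) {
  if (!behavior %in% c("chew", "drink"))
    stop("behavior must be 'chew' or 'drink'")
  if (is.null(phase_durations_s))
    phase_durations_s <- if (behavior == "chew")
      c(FC = 0.08, SC = 0.12, SO = 0.12, FO = 0.08)
    else c(C = 0.12, O1 = 0.10, O2 = 0.08)
  if (is.null(gape_amplitude_deg))
    gape_amplitude_deg <- if (behavior == "chew") 15 else 6
  want <- if (behavior == "chew") c("FC", "SC", "SO", "FO")
          else c("C", "O1", "O2")
  if (!identical(names(phase_durations_s), want))
    stop("phase_durations_s must be named ", paste(want, collapse = ", "))
  if (any(phase_durations_s <= 0)) stop("phase durations must be positive")
  if (gape_amplitude_deg <= 0) stop("gape amplitude must be positive")
  if (fast_fraction <= 0.5 || fast_fraction >= 1)
    stop("fast_fraction must lie in (0.5, 1)")
  d <- phase_durations_s; A <- gape_amplitude_deg; ff <- fast_fraction
  if (behavior == "chew") {
    speeds <- c(fast_close = ff * A / d[["FC"]],
                slow_close = (1 - ff) * A / d[["SC"]],
                slow_open = (1 - ff) * A / d[["SO"]],
                fast_open = ff * A / d[["FO"]])
    if (speeds[["fast_close"]] <= speeds[["slow_close"]] ||
        speeds[["fast_open"]] <= speeds[["slow_open"]])
      stop("spec error: fast phases must be faster than slow phases")
  } else {
    speeds <- c(close = A / d[["C"]], slow_open = (1 - ff) * A / d[["O1"]],
                fast_open = ff * A / d[["O2"]])
    if (speeds[["fast_open"]] <= speeds[["slow_open"]])
      stop("spec error: O2 must be faster than O1")
  }
  structure(list(behavior = behavior, phase_durations_s = phase_durations_s,
                 gape_amplitude_deg = gape_amplitude_deg,
                 frame_rate = frame_rate, duration_jitter = duration_jitter,
                 noise_sd_deg = noise_sd_deg, fast_fraction = fast_fraction,
                 smooth_sd_s = smooth_sd_s, mean_speeds = speeds),
            class = "cycle_spec")
}

#' Generate a synthetic jaw-pitch trace with known ground truth
#'
#' Builds a gape trace from per-phase constant-speed segments joined at
#' knots (cycle start = maximum gape, phase transitions, minimum gape),
#' smooths the corners with a Gaussian kernel so value and slope are
#' continuous, records the ground truth (cycle boundaries, minimum-gape
#' frames, phase-transition frames) from the noise-free trace, and adds
#' Gaussian noise last. Acceleration extrema of the smoothed trace fall
#' at the original corner frames, which is what the phase classifier
#' detects.
#'
#' @param spec a [cycle_spec()].
#' @param n_cycles number of complete cycles to emit.
#' @param seed integer seed (same seed, same trace).
#' @return object of class `jaw_sim`: list with `pitch` (a
#'   [jaw_pitch()] built from the noisy trace), `gape_clean` (noise-free
#'   gape), `truth` (data.frame: `cycle`, `start`, `end`,
#'   `min_gape_frame`, `boundary_close`, `boundary_open`), `spec`.
#' @export
generate_jaw_trace <- function(spec, n_cycles, seed = 1) {
  fs <- spec$frame_rate
  nominal <- round(spec$phase_durations_s * fs)
  if (any(nominal < 3))
    stop("spec error: each phase needs >= 3 frames at this frame rate")
  ff <- spec$fast_fraction; A <- spec$gape_amplitude_deg
  knot_vals <- if (spec$behavior == "chew")
    c(A, A * (1 - ff), 0, A * (1 - ff), A)
  else c(A, 0, A * (1 - ff), A)
  out <- with_seed(seed, {
    phase_frames <- lapply(seq_len(n_cycles), function(k) {
      scl <- 1 + spec$duration_jitter * stats::runif(1, -1, 1)
      pmax(3L, as.integer(round(nominal * scl)))
    })
    cyc_len <- vapply(phase_frames, sum, integer(1))
    starts <- 1L + c(0L, cumsum(cyc_len))[seq_len(n_cycles)]
    N <- 1L + sum(cyc_len)
    knotf <- unique(unlist(lapply(seq_len(n_cycles), function(k) {
      starts[k] + c(0L, cumsum(phase_frames[[k]]))
    })))
    knotv <- rep(knot_vals[-length(knot_vals)], n_cycles)
    knotv <- c(knotv, A)  # final knot closes the last cycle at max gape
    gape_pl <- stats::approx(knotf, knotv, xout = seq_len(N))$y
    # lead-out: descend into a phantom next cycle so the final maximum is
    # an interior peak (a trailing rising cut is never a cycle boundary)
    lead <- as.integer(max(5, nominal[1]))
    slope <- (knot_vals[2] - knot_vals[1]) / nominal[1]
    gape_pl <- c(gape_pl, knot_vals[1] + slope * seq_len(lead))
    final_knot <- N
    N <- N + lead
    sd_frames <- max(1, round(spec$smooth_sd_s * fs))
    clean <- gauss_smooth(gape_pl, sd_frames)
    # ground truth from the emitted noise-free trace: cycle boundaries
    # refined to the local maximum near each nominal corner
    refine <- function(f) {
      w <- max(2L, 3L * sd_frames)
      idx <- max(1L, f - w):min(N, f + w)
      idx[which.max(clean[idx])]
    }
    bounds <- vapply(c(starts, final_knot), refine, integer(1))
    truth <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
      s <- bounds[k]; e <- bounds[k + 1L]
      interior <- starts[k] + cumsum(phase_frames[[k]])
      if (spec$behavior == "chew") {
        b_close <- interior[1]; mg_nom <- interior[2]; b_open <- interior[3]
      } else {
        b_close <- NA_integer_; mg_nom <- interior[1]; b_open <- interior[2]
      }
      idx <- s:(e - 1L)
      mg <- idx[which.min(clean[idx])]
      data.frame(cycle = k, start = s, end = e, min_gape_frame = mg,
                 boundary_close = b_close, boundary_open = b_open)
    }))
    noisy <- clean + stats::rnorm(N, 0, spec$noise_sd_deg)
    list(clean = clean, noisy = noisy, truth = truth)
  })
  structure(list(
    pitch = jaw_pitch(rz = -out$noisy, frame_rate = fs, opening_sign = 1),
    gape_clean = out$clean, truth = out$truth, spec = spec, seed = seed),
    class = "jaw_sim")
}

#' Deformation specification for the synthetic tongue
#'
#' Each normalized measure follows a single-harmonic waveform
#' `baseline + amplitude * cos(2*pi*(t% - phase)/100)` of standardized
#' cycle time (an optional second harmonic produces bimodal waveforms).
#' Widths couple to their region's length via `kappa`: at `kappa = 1`
#' the width is strictly antiphase to the length (idealized muscular
#' hydrostat trade-off), at `kappa = 0` it follows its own independent
#' phase; amplitudes are realized exactly at `|kappa|` of 0 or 1.
#' Per-cycle multiplicative amplitude jitter emulates biological
#' cycle-to-cycle variation. The tongue spine has zero curvature by
#' default so realized midpoint distances equal the specified lengths
#' exactly; `curvature_mm` arches the spine to demonstrate the
#' chord-versus-arc caveat (no exactness guarantee).
#'
#' @param rest_lengths numeric(5), resting regional lengths in mm.
#' @param rest_widths numeric(4), resting widths in mm.
#' @param length_baseline,length_amp,length_phase numeric(5): normalized
#'   baseline, amplitude, and peak timing (% cycle) per region.
#' @param width_baseline,width_amp,width_phase numeric(4): same for
#'   widths.
#' @param kappa width-length coupling in `[-1, 1]`.
#' @param amp_jitter SD of the per-cycle multiplicative amplitude jitter
#'   (default 0.2, the scale of published cycle-to-cycle SD/mean ratios).
#' @param transport_amp_mm amplitude of rigid anteroposterior transport
#'   of the whole tongue (mm).
#' @param transport_rot_deg amplitude of the rigid transport rotation
#'   about z (degrees).
#' @param marker_noise_sd iid Gaussian noise per coordinate per frame
#'   (mm); default 0.5, the scale of published XROMM marker-tracking
#'   precision (mean SDs roughly 0.44-0.85).
#' @param curvature_mm static dorsoventral arch of the spine (mm).
#' @param length_amp2,length_phase2 optional second-harmonic amplitude
#'   and phase per region (default 0: single harmonic).
#' @return object of class `deformation_spec` with derived fields
#'   `total_baseline`, `total_amp`, `total_phase` (the total length is a
#'   single harmonic of the regional cosines, with resultant amplitude
#'   and phase).
#' @export
deformation_spec <- function(rest_lengths = rep(18, 5),
                             rest_widths = c(14, 18, 18, 14),
                             length_baseline = rep(1, 5),
                             length_amp = rep(0.1, 5),
                             length_phase = rep(45, 5),
                             width_baseline = rep(1, 4),
                             width_amp = rep(0.1, 4),
                             width_phase = rep(80, 4),
                             kappa = 0,
                             amp_jitter = 0.2,
                             transport_amp_mm = 0,
                             transport_rot_deg = 0,
                             marker_noise_sd = 0,
                             curvature_mm = 0,
                             length_amp2 = rep(0, 5),
                             length_phase2 = rep(0, 5)) {
  stopifnot(length(rest_lengths) == 5, length(rest_widths) == 4,
            length(length_baseline) == 5, length(length_amp) == 5,
            length(length_phase) == 5, length(width_baseline) == 4,
            length(width_amp) == 4, length(width_phase) == 4)
  if (any(rest_lengths <= 0) || any(rest_widths <= 0))
    stop("rest lengths and widths must be positive")
  if (abs(kappa) > 1) stop("kappa must lie in [-1, 1]")
  lo <- length_baseline - length_amp - length_amp2
  hi <- length_baseline + length_amp + length_amp2
  if (any(lo <= 0) || any(hi >= 2))
    stop("spec error: normalized lengths must stay within (0, 2)")
  if (any(width_baseline - width_amp <= 0) ||
      any(width_baseline + width_amp >= 2))
    stop("spec error: normalized widths must stay within (0, 2)")
  w <- rest_lengths / sum(rest_lengths)
  z <- sum(w * length_amp * exp(1i * 2 * pi * length_phase / 100))
  structure(list(rest_lengths = rest_lengths, rest_widths = rest_widths,
                 length_baseline = length_baseline, length_amp = length_amp,
                 length_phase = length_phase %% 100,
                 width_baseline = width_baseline, width_amp = width_amp,
                 width_phase = width_phase %% 100, kappa = kappa,
                 amp_jitter = amp_jitter,
                 transport_amp_mm = transport_amp_mm,
                 transport_rot_deg = transport_rot_deg,
                 marker_noise_sd = marker_noise_sd,
                 curvature_mm = curvature_mm,
                 length_amp2 = length_amp2,
                 length_phase2 = length_phase2 %% 100,
                 total_baseline = sum(w * length_baseline),
                 total_amp = Mod(z),
                 total_phase = (Arg(z) * 100 / (2 * pi)) %% 100),
            class = "deformation_spec")
}

# standardized cycle time per frame, from the ground-truth cycle table;
# frames outside the covered span extrapolate the nearest cycle's map
frame_cycle_time <- function(truth, n_frames) {
  tpct <- numeric(n_frames)
  cyc <- integer(n_frames)
  for (k in seq_len(nrow(truth))) {
    s <- truth$start[k]; e <- truth$end[k]
    idx <- s:(e - 1L)
    tpct[idx] <- 100 * (idx - s) / (e - s)
    cyc[idx] <- k
  }
  before <- seq_len(n_frames) < truth$start[1]
  if (any(before)) {
    s <- truth$start[1]; e <- truth$end[1]
    tpct[before] <- (100 * (which(before) - s) / (e - s)) %% 100
    cyc[before] <- 1L
  }
  after <- seq_len(n_frames) >= truth$end[nrow(truth)]
  if (any(after)) {
    k <- nrow(truth); s <- truth$start[k]; e <- truth$end[k]
    tpct[after] <- (100 * (which(after) - s) / (e - s)) %% 100
    cyc[after] <- k
  }
  list(tpct = tpct, cycle = cyc)
}

#' Generate synthetic tongue, skull and jaw marker trajectories
#'
#' Builds a 10-marker tongue (anterior midline, four left/right pairs,
#' posterior midline) whose regional lengths and widths follow the
#' waveforms in `dspec`, driven by the standardized cycle time of a
#' synthetic jaw trace; emits consistent static skull markers and jaw
#' markers hinged about the z axis at the jaw pitch angle; applies
#' optional rigid transport to the whole tongue; adds marker noise last.
#' Ground-truth per-cycle extrema are recorded from the noise-free
#' discretized waveforms, so they are exactly consistent with what a
#' perfect analysis of the emitted frames would measure.
#'
#' @param dspec a [deformation_spec()].
#' @param jaw a `jaw_sim` from [generate_jaw_trace()].
#' @param seed integer seed for amplitude jitter and marker noise.
#' @return list with `markers` (a [marker_set()]), `rest` (a
#'   [rest_config()]), `rest_positions` (10 x 3 matrix: the tongue
#'   markers in the rest configuration, all measures exactly at rest),
#'   `truth` (list: `cycles`, `deformation` -- per cycle x measure
#'   max/min/delta/t_max/t_min from the noise-free channel -- and
#'   `spec`), and `clean_norm` (noise-free normalized series,
#'   frames x measures).
#' @export
generate_tongue_markers <- function(dspec, jaw, seed = 1) {
  N <- length(jaw$gape_clean)
  fs <- jaw$spec$frame_rate
  ct <- frame_cycle_time(jaw$truth, N)
  tpct <- ct$tpct
  n_cycles <- nrow(jaw$truth)
  measures <- c(paste0("R", 1:5), paste0("W", 1:4))
  sd_frames <- max(1, round(jaw$spec$smooth_sd_s * fs))
  sim <- with_seed(seed, {
    # per-cycle multiplicative amplitude jitter, blended smoothly in time
    mult <- matrix(pmax(0.2, 1 + dspec$amp_jitter *
                          stats::rnorm(n_cycles * 9)), n_cycles, 9)
    ampf <- apply(mult[ct$cycle, , drop = FALSE], 2, gauss_smooth,
                  sd_frames = sd_frames)
    norm_len <- matrix(0, N, 5)
    for (i in 1:5) {
      norm_len[, i] <- dspec$length_baseline[i] +
        ampf[, i] * dspec$length_amp[i] *
          cos(2 * pi * (tpct - dspec$length_phase[i]) / 100) +
        dspec$length_amp2[i] *
          cos(4 * pi * (tpct - dspec$length_phase2[i]) / 100)
    }
    norm_wid <- matrix(0, N, 4)
    k <- dspec$kappa
    for (i in 1:4) {
      shape <- -k * cos(2 * pi * (tpct - dspec$length_phase[i]) / 100) +
        (1 - abs(k)) * cos(2 * pi * (tpct - dspec$width_phase[i]) / 100)
      norm_wid[, i] <- dspec$width_baseline[i] +
        ampf[, 5 + i] * dspec$width_amp[i] * shape
    }
    if (any(norm_len <= 0) || any(norm_wid <= 0))
      stop("spec error: instantaneous normalized length/width <= 0")
    len_mm <- sweep(norm_len, 2, dspec$rest_lengths, "*")
    wid_mm <- sweep(norm_wid, 2, dspec$rest_widths, "*")
    # zero-curvature spine along x: midpoint distances equal the
    # specified lengths exactly
    xm <- cbind(0, t(apply(len_mm, 1, cumsum)))  # N x 6 midpoint x
    zarch <- dspec$curvature_mm * sin(pi * (0:5) / 5)
    tongue <- list(T0 = cbind(xm[, 1], 0, zarch[1]))
    for (i in 1:4) {
      tongue[[paste0("L", i)]] <- cbind(xm[, i + 1], wid_mm[, i] / 2, zarch[i + 1])
      tongue[[paste0("R", i)]] <- cbind(xm[, i + 1], -wid_mm[, i] / 2, zarch[i + 1])
    }
    tongue$T5 <- cbind(xm[, 6], 0, zarch[6])
    # rigid transport of the whole tongue: AP translation + small
    # rotation about z, both cycle-locked
    if (dspec$transport_amp_mm != 0 || dspec$transport_rot_deg != 0) {
      s <- sin(2 * pi * tpct / 100)
      tx <- dspec$transport_amp_mm * s
      psi <- dspec$transport_rot_deg * pi / 180 * s
      ctr <- c(sum(dspec$rest_lengths) / 2, 0, 0)
      cp <- cos(psi); sp <- sin(psi)
      tongue <- lapply(tongue, function(p) {
        dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
        cbind(ctr[1] + cp * dx - sp * dy + tx,
              ctr[2] + sp * dx + cp * dy,
              p[, 3])
      })
    }
    # static skull; jaw hinged about z at the pitch angle. Marker clouds
    # span tens of mm, as implanted bone markers do in a pig skull, so
    # tracking noise maps to realistically small angular noise.
    skull_base <- matrix(c(-40, 40, 0,   60, 45, 15,   -20, 75, -20,
                           -35, 30, 25,   30, 80, 10), ncol = 3, byrow = TRUE)
    jaw_base <- matrix(c(-25, 12, 0,   20, 8, 18,   70, 16, -18,
                         -10, 28, 10,   45, 20, -8), ncol = 3, byrow = TRUE)
    pivot <- c(-40, 25, 0)
    rz <- -jaw$gape_clean * pi / 180
    crz <- cos(rz); srz <- sin(rz)
    markers <- tongue
    for (j in 1:5) {
      markers[[paste0("S", j)]] <-
        matrix(skull_base[j, ], N, 3, byrow = TRUE)
      dxy <- jaw_base[j, 1:2] - pivot[1:2]
      markers[[paste0("J", j)]] <- cbind(
        pivot[1] + crz * dxy[1] - srz * dxy[2],
        pivot[2] + srz * dxy[1] + crz * dxy[2],
        jaw_base[j, 3])
    }
    if (dspec$marker_noise_sd > 0) {
      markers <- lapply(markers, function(p)
        p + matrix(stats::rnorm(length(p), 0, dspec$marker_noise_sd),
                   nrow(p), 3))
    }
    list(markers = markers, norm_len = norm_len, norm_wid = norm_wid)
  })
  tg_names <- c("T0", paste0(rep(c("L", "R"), 4), rep(1:4, each = 2)), "T5")
  info <- rbind(
    data.frame(name = tg_names, role = "tongue",
               side = c("midline", rep(c("left", "right"), 4), "midline"),
               ap_index = c(0L, rep(1:4, each = 2), 5L)),
    data.frame(name = paste0("S", 1:5), role = "skull", side = "midline",
               ap_index = 0L),
    data.frame(name = paste0("J", 1:5), role = "jaw", side = "midline",
               ap_index = 0L))
  ms <- marker_set(sim$markers[info$name], info, fs)
  rest <- rest_config(dspec$rest_lengths, dspec$rest_widths,
                      "synthetic generator rest frame")
  # the rest frame itself: zero-curvature spine with all measures at rest
  xr <- cumsum(c(0, dspec$rest_lengths))
  rest_positions <- rbind(
    T0 = c(xr[1], 0, 0),
    do.call(rbind, lapply(1:4, function(i) {
      rbind(c(xr[i + 1], dspec$rest_widths[i] / 2, 0),
            c(xr[i + 1], -dspec$rest_widths[i] / 2, 0))
    })),
    T5 = c(xr[6], 0, 0))
  rownames(rest_positions) <- tg_names
  clean_norm <- cbind(sim$norm_len, sim$norm_wid,
                      total = as.numeric(sim$norm_len %*% dspec$rest_lengths) /
                        sum(dspec$rest_lengths))
  colnames(clean_norm) <- c(measures, "total")
  truth_def <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
    cy <- jaw$truth[k, ]
    idx <- cy$start:(cy$end - 1L)
    do.call(rbind, lapply(c("total", measures), function(m) {
      v <- clean_norm[idx, m]
      imax <- which.max(v); imin <- which.min(v)
      data.frame(cycle = k, measure = m,
                 max_norm = v[imax], min_norm = v[imin],
                 delta = v[imax] - v[imin],
                 t_max = 100 * (idx[imax] - cy$start) / (cy$end - cy$start),
                 t_min = 100 * (idx[imin] - cy$start) / (cy$end - cy$start),
                 f_max = idx[imax], f_min = idx[imin])
    }))
  }))
  list(markers = ms, rest = rest, rest_positions = rest_positions,
       truth = list(cycles = jaw$truth, deformation = truth_def,
                    spec = dspec),
       clean_norm = clean_norm)
}

#' Behavior presets parameterized from published magnitudes
#'
#' Returns a (`cycle_spec`, `deformation_spec`) pair whose noise-free
#' ground-truth per-cycle deltas equal published chew/drink means:
#' regional length amplitudes are half the reported regional
#' delta-L means and baselines sit midway between the reported maximum
#' and minimum normalized lengths (likewise for widths, Table-style
#' values); the anterior-to-posterior stagger of the regional peak
#' timings is solved at construction time so the resultant amplitude of
#' the (single-harmonic) total length matches the reported total delta
#' exactly — 0.16 for chewing, 0.07 for drinking — which also keeps the
#' instantaneous normalized total below 1.1x rest, the published
#' envelope. Width-length coupling is `kappa = 1` so width deltas are
#' realized exactly.
#'
#' @param name `"chew_default"` or `"drink_default"`.
#' @return list with elements `cycle` (a `cycle_spec`), `deformation`
#'   (a `deformation_spec`), `name`, and `nominal_deltas` (named list of
#'   the analytic noise-free deltas: total, R1..R5, W1..W4).
#' @export
preset <- function(name = c("chew_default", "drink_default")) {
  name <- match.arg(name)
  if (name == "chew_default") {
    cyc <- cycle_spec("chew")
    ldelta <- c(0.37, 0.28, 0.40, 0.48, 0.34)
    lbase <- c((0.95 + 0.58), (0.85 + 0.57), (1.08 + 0.68),
               (1.36 + 0.88), (1.15 + 0.81)) / 2
    wdelta <- c(0.32, 0.39, 0.37, 0.22)
    wbase <- c((1.04 + 0.73), (1.09 + 0.70), (1.17 + 0.80),
               (0.97 + 0.75)) / 2
    total_delta <- 0.16
    phi1 <- 40
  } else {
    cyc <- cycle_spec("drink")
    ldelta <- c(0.14, 0.12, 0.12, 0.20, 0.19)
    lbase <- c((0.84 + 0.71), (0.86 + 0.73), (1.03 + 0.91),
               (1.31 + 1.11), (1.12 + 0.94)) / 2
    wdelta <- c(0.28, 0.37, 0.25, 0.18)
    wbase <- c((1.17 + 0.89), (1.34 + 0.96), (1.32 + 1.07),
               (0.96 + 0.79)) / 2
    total_delta <- 0.07
    phi1 <- 45
  }
  rest_lengths <- rep(18, 5)
  w <- rest_lengths / sum(rest_lengths)
  amp <- ldelta / 2
  resultant <- function(delta_pct) {
    Mod(sum(w * amp * exp(1i * 2 * pi * (0:4) * delta_pct / 100)))
  }
  stagger <- stats::uniroot(function(d) resultant(d) - total_delta / 2,
                            c(1e-9, 16), tol = 1e-12)$root
  lphase <- (phi1 + (0:4) * stagger) %% 100
  dspec <- deformation_spec(
    rest_lengths = rest_lengths, rest_widths = c(14, 18, 18, 14),
    length_baseline = lbase, length_amp = amp, length_phase = lphase,
    width_baseline = wbase, width_amp = wdelta / 2,
    width_phase = (lphase[1:4] + 50) %% 100, kappa = 1,
    amp_jitter = 0.2, transport_amp_mm = 8, transport_rot_deg = 2,
    marker_noise_sd = 0.5)
  deltas <- as.list(c(total = 2 * dspec$total_amp,
                      stats::setNames(ldelta, paste0("R", 1:5)),
                      stats::setNames(wdelta, paste0("W", 1:4))))
  list(cycle = cyc, deformation = dspec, name = name,
       nominal_deltas = deltas)
}

#' Simulate a full synthetic recording
#'
#' Convenience wrapper: jaw trace + tongue/skull/jaw markers from a
#' preset (or explicit specs), optionally written to disk in the
#' package's file formats (markers CSV, rest config YAML, ground-truth
#' manifest JSON).
#'
#' @param preset_name `"chew_default"` or `"drink_default"`; ignored if
#'   `specs` is given.
#' @param n_cycles number of gape cycles.
#' @param seed integer seed; the jaw trace uses `seed`, the markers
#'   `seed + 1`.
#' @param dir output directory, or `NULL` to keep everything in memory.
#' @param specs optional list with elements `cycle` and `deformation`
#'   overriding the preset.
#' @return list with `jaw`, `markers`, `rest`, `truth`, `clean_norm`,
#'   and (when `dir` is given) `files` (named paths).
#' @export
simulate_recording <- function(preset_name = "chew_default", n_cycles = 20,
                               seed = 1, dir = NULL, specs = NULL) {
  sp <- specs %||% preset(preset_name)
  jaw <- generate_jaw_trace(sp$cycle, n_cycles, seed)
  tm <- generate_tongue_markers(sp$deformation, jaw, seed + 1)
  out <- c(list(jaw = jaw), tm)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(markers = file.path(dir, "markers.csv"),
               rest = file.path(dir, "rest.yaml"),
               truth = file.path(dir, "truth.json"))
    write_marker_trajectories(tm$markers, files["markers"])
    write_rest_config(tm$rest, files["rest"])
    manifest <- list(
      generator = "linguakin synthetic recording",
      seed = seed, n_cycles = n_cycles,
      behavior = sp$cycle$behavior,
      cycle_spec = unclass(sp$cycle),
      deformation_spec = unclass(sp$deformation),
      truth_cycles = jaw$truth,
      truth_deformation = tm$truth$deformation)
    jsonlite::write_json(manifest, files["truth"], auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    out$files <- files
  }
  out
}
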