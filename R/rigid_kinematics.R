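#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero
#' phase: extrema of symmetric inputs are not shifted in time). The
#' effective magnitude response is the squared single-pass response, so
#' a sinusoid at exactly the cutoff frequency is attenuated to 1/2
#' amplitude. Edges are handled by odd-reflection padding with
#' steady-state initial conditions, so a constant trace is reproduced
#' exactly.
#'
#' @param x numeric vector, or matrix whose columns are filtered
#'   independently (e.g. x/y/z of one marker).
#' @param cutoff cutoff frequency in Hz; must be below `frame_rate / 2`.
#' @param order filter order of a single pass (default 2).
#' @param frame_rate sampling rate in Hz.
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff, order = 2, frame_rate) {
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive frequency")
  if (cutoff >= frame_rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         frame_rate / 2, " Hz")
  if (is.matrix(x))
    return(apply(x, 2, lowpass_filter, cutoff = cutoff, order = order,
                 frame_rate = frame_rate))
  n <- length(x)
  if (n <= 3 * order)
    stop("series too short to filter: length ", n, " <= 3 x order")
  if (anyNA(x))
    stop("cannot filter a series containing missing samples")
  bf <- signal::butter(order, 2 * cutoff / frame_rate, type = "low")
  npad <- min(n - 1, max(3 * (order + 1), ceiling(3 * frame_rate / cutoff)))
  ext <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  onepass <- function(v) {
    signal::filter(bf$b, bf$a, v,
                   init.x = rep(v[1], order), init.y = rep(v[1], order))
  }
  y <- rev(onepass(rev(onepass(ext))))
  unname(y[(npad + 1):(npad + n)])
}

#' Least-squares rigid pose from marker correspondences
#'
#' Finds the proper rotation `R` (3x3, det +1) and translation `t`
#' minimizing the sum of squared distances between `R %*% ref + t` and
#' the observed coordinates (Kabsch/SVD solution; a reflection-optimal
#' SVD is corrected to a proper rotation). Requires at least 3
#' non-collinear markers.
#'
#' @param reference_coords n x 3 matrix of reference-configuration
#'   coordinates (mm), rows in correspondence with `observed_coords`.
#' @param observed_coords n x 3 matrix of observed coordinates (mm).
#' @return list with `rotation` (3x3), `translation` (length 3) and
#'   `residual` (RMSD in mm at the minimum).
#' @export
fit_rigid_pose <- function(reference_coords, observed_coords) {
  ref <- as.matrix(reference_coords)
  obs <- as.matrix(observed_coords)
  if (!is.numeric(ref) || ncol(ref) != 3L || !is.numeric(obs) ||
      ncol(obs) != 3L || nrow(ref) != nrow(obs))
    stop("reference and observed coordinates must be matching n x 3 matrices")
  n <- nrow(ref)
  if (n < 3L) stop("geometry error: need at least 3 markers, found ", n)
  if (anyNA(ref) || anyNA(obs))
    stop("geometry error: missing coordinates in pose fit")
  cr <- colMeans(ref); co <- colMeans(obs)
  rc <- sweep(ref, 2, cr); oc <- sweep(obs, 2, co)
  sv_ref <- svd(rc)$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1))
    stop("geometry error: markers are collinear; pose is not identifiable")
  H <- crossprod(rc, oc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(co - R %*% cr)
  resid2 <- sum((oc - rc %*% t(R))^2)
  list(rotation = R, translation = tr,
       residual = sqrt(resid2 / n))
}

#' Fit a rigid pose series for one body from its markers
#'
#' Fits [fit_rigid_pose()] frame by frame for the markers of one role
#' (skull or jaw), against a reference configuration (by default the
#' body's marker coordinates at the first frame with complete data).
#' Frames with missing markers get an `NA` pose and are flagged.
#'
#' @param ms a `marker_set`.
#' @param role `"skull"` or `"jaw"`.
#' @param reference_frame frame index supplying the reference
#'   configuration; default the first complete frame.
#' @return object of class `pose_series`: list with `rotation`
#'   (3 x 3 x n array), `translation` (n x 3), `residual` (n),
#'   `flagged` (logical n), `frame_rate`, `role`.
#' @export
fit_pose_series <- function(ms, role, reference_frame = NULL) {
  nms <- ms$markers$name[ms$markers$role == role]
  if (length(nms) < 3L)
    stop("geometry error: role '", role, "' has ", length(nms),
         " markers; need >= 3")
  pos <- ms$positions[nms]
  n <- ms$n_frames
  complete <- !Reduce(`|`, lapply(pos, function(p) !stats::complete.cases(p)))
  if (is.null(reference_frame)) {
    reference_frame <- which(complete)[1]
    if (is.na(reference_frame))
      stop("no frame with complete ", role, " markers")
  }
  ref <- t(vapply(pos, function(p) p[reference_frame, ], numeric(3)))
  rot <- array(NA_real_, c(3, 3, n))
  tra <- matrix(NA_real_, n, 3)
  res <- rep(NA_real_, n)
  obs <- array(unlist(pos), c(n, 3, length(nms)))
  for (f in which(complete)) {
    fit <- fit_rigid_pose(ref, t(obs[f, , ]))
    rot[, , f] <- fit$rotation
    tra[f, ] <- fit$translation
    res[f] <- fit$residual
  }
  structure(list(rotation = rot, translation = tra, residual = res,
                 flagged = !complete, frame_rate = ms$frame_rate,
                 role = role, reference_frame = reference_frame),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat("pose_series (", x$role, "): ", dim(x$rotation)[3], " frames, ",
      sum(x$flagged), " flagged; mean residual ",
      signif(mean(x$residual, na.rm = TRUE), 3), " mm\n", sep = "")
  invisible(x)
}

#' Express marker positions in the skull frame
#'
#' Applies the inverse skull pose per frame, removing skull motion so
#' tongue and jaw kinematics are reported relative to the skull. Being a
#' rigid transform per frame, all simultaneous inter-marker distances
#' are preserved.
#'
#' @param positions named list of `n x 3` matrices (world coordinates).
#' @param skull_poses a `pose_series` for the skull covering the same
#'   frames.
#' @return named list of `n x 3` matrices in the skull frame; frames with
#'   a flagged skull pose become `NA`.
#' @export
to_skull_frame <- function(positions, skull_poses) {
  n <- nrow(positions[[1]])
  if (dim(skull_poses$rotation)[3] != n)
    stop("structural error: pose series covers ", dim(skull_poses$rotation)[3],
         " frames but positions have ", n)
  out <- lapply(positions, function(p) {
    q <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (f in seq_len(n)) {
      if (skull_poses$flagged[f] || anyNA(p[f, ])) next
      q[f, ] <- crossprod(skull_poses$rotation[, , f],
                          p[f, ] - skull_poses$translation[f, ])
    }
    q
  })
  out
}

#' Jaw-pitch (Rz) series from skull and jaw poses
#'
#' Computes the rotation of the jaw relative to the skull per frame and
#' extracts the pitch angle about the z axis as the first angle of an
#' intrinsic z-y-x Euler sequence. The caller is responsible for the
#' reference frames' z axis being aligned with the mediolateral
#' anatomical axis; only Rz is consumed downstream. Gape is derived as
#' `opening_sign * (rz_reference - rz)` so that jaw opening increases
#' gape; by default `rz_reference` is chosen so the minimum gape over
#' the series is 0.
#'
#' @param skull_poses,jaw_poses `pose_series` of equal length.
#' @param opening_sign +1 or -1, mapping Rz to gape.
#' @param rz_reference reference pitch (degrees) at which gape = 0;
#'   default makes `min(gape) == 0`.
#' @return object of class `jaw_pitch`: list with `rz` (degrees),
#'   `gape` (degrees), `frame_rate`, `gimbal_flag` (logical, second Euler
#'   angle beyond 85 degrees), `flagged` (missing pose frames).
#' @export
jaw_pitch_series <- function(skull_poses, jaw_poses, opening_sign = 1,
                             rz_reference = NULL) {
  n <- dim(skull_poses$rotation)[3]
  if (dim(jaw_poses$rotation)[3] != n)
    stop("structural error: skull and jaw pose series differ in length")
  rz <- rep(NA_real_, n)
  gimbal <- rep(FALSE, n)
  for (f in seq_len(n)) {
    if (skull_poses$flagged[f] || jaw_poses$flagged[f]) next
    Rrel <- crossprod(skull_poses$rotation[, , f], jaw_poses$rotation[, , f])
    rz[f] <- atan2(Rrel[2, 1], Rrel[1, 1]) * 180 / pi
    ry <- asin(max(-1, min(1, -Rrel[3, 1]))) * 180 / pi
    if (abs(ry) > 85) gimbal[f] <- TRUE
  }
  if (any(gimbal))
    warning(sum(gimbal), " frames near gimbal lock (|second angle| > 85 deg)")
  jaw_pitch(rz, skull_poses$frame_rate, opening_sign, rz_reference,
            gimbal_flag = gimbal,
            flagged = skull_poses$flagged | jaw_poses$flagged)
}

#' @rdname jaw_pitch_series
#' @param rz numeric vector of jaw pitch angles (degrees).
#' @param frame_rate sampling rate in Hz.
#' @param gimbal_flag,flagged optional per-frame quality flags.
#' @export
jaw_pitch <- function(rz, frame_rate, opening_sign = 1, rz_reference = NULL,
                      gimbal_flag = NULL, flagged = NULL) {
  if (!opening_sign %in% c(-1, 1)) stop("opening_sign must be +1 or -1")
  if (is.null(rz_reference)) {
    rz_reference <- if (opening_sign > 0) max(rz, na.rm = TRUE)
                    else min(rz, na.rm = TRUE)
  }
  gape <- opening_sign * (rz_reference - rz)
  structure(list(rz = rz, gape = gape, frame_rate = frame_rate,
                 opening_sign = opening_sign, rz_reference = rz_reference,
                 gimbal_flag = gimbal_flag %||% rep(FALSE, length(rz)),
                 flagged = flagged %||% !is.finite(rz)),
            class = "jaw_pitch")
}

#' @export
print.jaw_pitch <- function(x, ...) {
  cat("jaw_pitch:", length(x$rz), "frames @", x$frame_rate, "fps; gape range [",
      signif(min(x$gape, na.rm = TRUE), 3), ",",
      signif(max(x$gape, na.rm = TRUE), 3), "] deg\n")
  invisible(x)
}
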