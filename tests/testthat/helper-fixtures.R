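# shared fixtures, built in code

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# constant-pose series wrapping a fixed rotation/translation
const_pose_series <- function(R, tr, n, frame_rate = 250, role = "skull") {
  structure(list(
    rotation = array(R, c(3, 3, n)),
    translation = matrix(tr, n, 3, byrow = TRUE),
    residual = numeric(n), flagged = rep(FALSE, n),
    frame_rate = frame_rate, role = role, reference_frame = 1L),
    class = "pose_series")
}

# brute-force rigid-pose oracle: numeric minimization of the same
# objective over axis-angle rotation + translation, multi-start
rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  u <- v / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

brute_pose_residual <- function(ref, obs) {
  obj <- function(p) {
    R <- rodrigues(p[1:3])
    d <- obs - (ref %*% t(R) + matrix(p[4:6], nrow(ref), 3, byrow = TRUE))
    sum(d^2)
  }
  starts <- list(rep(0, 6),
                 c(0.5, -0.4, 0.3, 0, 0, 0),
                 c(-1, 1, -1, colMeans(obs) - colMeans(ref)),
                 c(2, 0.1, -0.5, colMeans(obs) - colMeans(ref)))
  best <- Inf
  for (s in starts) {
    r1 <- stats::optim(s, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    r2 <- stats::optim(r1$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r1$value, r2$value)
  }
  sqrt(best / nrow(ref))
}

# a tiny valid 10-marker tongue + skull + jaw set with simple geometry
simple_marker_set <- function(n_frames = 5, frame_rate = 250) {
  tg_names <- c("T0", paste0(rep(c("L", "R"), 4), rep(1:4, each = 2)), "T5")
  info <- rbind(
    data.frame(name = tg_names, role = "tongue",
               side = c("midline", rep(c("left", "right"), 4), "midline"),
               ap_index = c(0L, rep(1:4, each = 2), 5L)),
    data.frame(name = paste0("S", 1:4), role = "skull", side = "midline",
               ap_index = 0L),
    data.frame(name = paste0("J", 1:4), role = "jaw", side = "midline",
               ap_index = 0L))
  base <- list(
    T0 = c(0, 0, 0),
    L1 = c(10, 4, 0), R1 = c(10, -4, 0),
    L2 = c(20, 4, 0), R2 = c(20, -4, 0),
    L3 = c(30, 4, 0), R3 = c(30, -4, 0),
    L4 = c(40, 4, 0), R4 = c(40, -4, 0),
    T5 = c(50, 0, 0),
    S1 = c(0, 30, 0), S2 = c(40, 30, 10), S3 = c(0, 60, -10),
    S4 = c(30, 55, 20),
    J1 = c(0, 15, 0), J2 = c(40, 15, 10), J3 = c(20, 25, -10),
    J4 = c(35, 10, 5))
  positions <- lapply(base, function(p) matrix(p, n_frames, 3, byrow = TRUE))
  marker_set(positions, info, frame_rate)
}

# cached expensive simulations shared across acceptance blocks
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

noise_free_preset <- function(name) {
  p <- preset(name)
  p$deformation$marker_noise_sd <- 0
  p$deformation$amp_jitter <- 0
  p
}

# full pipeline run on a simulated recording; returns sim + analysis
run_sim_pipeline <- function(preset_name, n_cycles, seed, specs = NULL,
                             config = NULL) {
  behavior <- if (grepl("chew", preset_name)) "chew" else "drink"
  sim_dir <- tempfile("linguakin_")
  sim <- simulate_recording(preset_name, n_cycles = n_cycles, seed = seed,
                            dir = file.path(sim_dir, "sim"), specs = specs)
  cfg <- config %||% default_analysis_config(behavior = behavior)
  res <- run_analysis(sim$files["markers"], sim$files["rest"], cfg,
                      file.path(sim_dir, "out"))
  list(sim = sim, res = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
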