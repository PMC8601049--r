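make_positions <- function(coords) {
  lapply(coords, function(p) matrix(p, 1, 3, byrow = TRUE))
}

straight_map <- function() region_map(simple_marker_set())

test_that("regional lengths are consecutive-midpoint distances, insensitive to pair width", {
  ms <- simple_marker_set(n_frames = 1)
  map <- region_map(ms)
  lens <- regional_lengths(ms$positions, map)
  expect_equal(as.numeric(lens), rep(10, 5))
  # widen pair 2: midpoint unchanged, R2 and R3 unchanged
  ms$positions[["L2"]][1, 2] <- 9
  ms$positions[["R2"]][1, 2] <- -9
  lens2 <- regional_lengths(ms$positions, map)
  expect_equal(as.numeric(lens2), rep(10, 5))
})

test_that("semicircular midpoint arrangements give the analytic chord lengths", {
  r <- 30
  theta <- seq(0, pi, length.out = 6)  # six midpoints on a semicircle
  ms <- simple_marker_set(n_frames = 1)
  pts <- cbind(r * cos(theta), 0, r * sin(theta))
  ms$positions[["T0"]][1, ] <- pts[1, ]
  for (i in 1:4) {
    off <- c(0, 4, 0)
    ms$positions[[paste0("L", i)]][1, ] <- pts[i + 1, ] + off
    ms$positions[[paste0("R", i)]][1, ] <- pts[i + 1, ] - off
  }
  ms$positions[["T5"]][1, ] <- pts[6, ]
  lens <- regional_lengths(ms$positions, region_map(ms))
  chord <- 2 * r * sin((pi / 5) / 2)
  expect_equal(as.numeric(lens), rep(chord, 5), tolerance = 1e-12)
  # chord sum strictly exceeds the endpoint distance for an arched spine
  tot <- total_length(lens)
  endpoint <- sqrt(sum((pts[6, ] - pts[1, ])^2))
  expect_gt(tot, endpoint)
})

test_that("widths are plain pair distances, including degenerate and oblique pairs", {
  ms <- simple_marker_set(n_frames = 1)
  map <- region_map(ms)
  expect_equal(as.numeric(regional_widths(ms$positions, map)), rep(8, 4))
  ms$positions[["L1"]][1, ] <- c(10, 3, 0)
  ms$positions[["R1"]][1, ] <- c(10, 3, 0)  # coincident
  ms$positions[["L2"]][1, ] <- c(0, 3, 0)
  ms$positions[["R2"]][1, ] <- c(0, -1, 2)
  w <- regional_widths(ms$positions, map)
  expect_equal(unname(w[1, "W1"]), 0)
  expect_equal(unname(w[1, "W2"]), sqrt(20))
})

test_that("total length is the exact regional sum and equals endpoint distance when straight", {
  lens <- matrix(rep(10, 5), 1)
  expect_equal(total_length(lens), 50)
  ms <- simple_marker_set(n_frames = 1)
  lens2 <- regional_lengths(ms$positions, region_map(ms))
  expect_equal(total_length(lens2),
               sqrt(sum((ms$positions$T5[1, ] - ms$positions$T0[1, ])^2)),
               tolerance = 1e-9)
})

test_that("normalization divides by rest and is exactly 1 at the rest configuration", {
  ms <- simple_marker_set(n_frames = 2)
  rest <- rest_config(rep(10, 5), rep(8, 4))
  ds <- deformation_series(ms, rest)
  norm_cols <- grep("_norm$", names(ds), value = TRUE)
  expect_true(all(abs(as.matrix(ds[norm_cols]) - 1) < 1e-12))
  # doubling all coordinates doubles all normalized values
  ms2 <- ms
  ms2$positions <- lapply(ms$positions, function(p) 2 * p)
  ds2 <- deformation_series(ms2, rest)
  expect_true(all(abs(as.matrix(ds2[norm_cols]) - 2) < 1e-12))
})

test_that("normalized measures are scale invariant when coordinates and rest scale together", {
  ms <- simple_marker_set(n_frames = 1)
  ms$positions <- lapply(ms$positions, function(p) p * 1.37)
  rest <- rest_config(rep(10 * 1.37, 5), rep(8 * 1.37, 4))
  ds <- deformation_series(ms, rest)
  norm_cols <- grep("_norm$", names(ds), value = TRUE)
  expect_true(all(abs(as.matrix(ds[norm_cols]) - 1) < 1e-12))
})

test_that("lengths and widths are invariant under random rigid motions of all markers", {
  set.seed(9)
  jaw <- generate_jaw_trace(cycle_spec("chew"), 2, seed = 1)
  tm <- generate_tongue_markers(preset("chew_default")$deformation, jaw,
                                seed = 2)
  ms <- tm$markers
  map <- region_map(ms)
  tongue <- ms$positions[ms$markers$name[ms$markers$role == "tongue"]]
  l0 <- regional_lengths(tongue, map)
  w0 <- regional_widths(tongue, map)
  for (i in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 50)
    moved <- lapply(tongue, function(p)
      p %*% t(R) + matrix(tr, nrow(p), 3, byrow = TRUE))
    expect_equal(regional_lengths(moved, map), l0, tolerance = 1e-9)
    expect_equal(regional_widths(moved, map), w0, tolerance = 1e-9)
  }
})

test_that("cycle summaries recover analytic sinusoid extrema and honor tie rules", {
  n <- 401
  cycles <- data.frame(cycle = 1L, behavior = "chew", start = 1L,
                       end = as.integer(n), min_gape_frame = 200L,
                       excluded = FALSE)
  tpct <- 100 * (seq_len(n) - 1) / (n - 1)
  ds <- data.frame(frame = seq_len(n), flagged = FALSE,
                   R1_norm = 1 + 0.2 * sin(2 * pi * tpct / 100))
  s <- cycle_deformation_summary(ds, cycles)
  expect_equal(s$max_norm, 1.2, tolerance = 1e-6)
  expect_equal(s$min_norm, 0.8, tolerance = 1e-6)
  expect_equal(s$delta, 0.4, tolerance = 1e-6)
  expect_equal(s$t_max, 25, tolerance = 100 / n)
  expect_equal(s$t_min, 75, tolerance = 100 / n)
  # constant series: delta 0 and first-occurrence ties at 0%
  ds$R1_norm <- 1
  s0 <- cycle_deformation_summary(ds, cycles)
  expect_equal(s0$delta, 0)
  expect_equal(s0$t_max, 0)
  expect_equal(s0$t_min, 0)
  slast <- cycle_deformation_summary(ds, cycles, tie_rule = "last")
  expect_equal(slast$f_max, n - 1L)  # last frame of the half-open cycle
})

test_that("cycles containing flagged frames are suppressed from summaries", {
  n <- 101
  cycles <- data.frame(cycle = 1:2, behavior = "chew",
                       start = c(1L, 51L), end = c(51L, 101L),
                       min_gape_frame = c(25L, 75L), excluded = FALSE)
  ds <- data.frame(frame = seq_len(n), flagged = FALSE, R1_norm = 1)
  ds$flagged[60] <- TRUE
  s <- cycle_deformation_summary(ds, cycles)
  expect_equal(unique(s$cycle), 1L)
})

test_that("delta equals max minus min for every cycle and measure", {
  out <- run_sim_pipeline("chew_default", 6, seed = 31)
  s <- out$res$summary
  expect_true(nrow(s) > 0)
  expect_equal(s$delta, s$max_norm - s$min_norm, tolerance = 1e-12)
  expect_true(all(s$delta >= 0))
  expect_true(all(s$t_max >= 0 & s$t_max < 100))
  expect_true(all(s$t_min >= 0 & s$t_min < 100))
})

test_that("strict inverse width-length coupling orders the trade-off clouds in every cycle", {
  p <- noise_free_preset("chew_default")
  p$deformation$kappa <- 1
  out <- run_sim_pipeline("chew_default", 10, seed = 33, specs = p,
                          config = default_analysis_config(
                            behavior = "chew", filter_target = "none"))
  pr <- out$res$pairs
  byrec <- split(pr, list(pr$cycle, pr$region), drop = TRUE)
  cmp <- vapply(byrec, function(d) {
    d$width_norm[d$extreme == "max"] < d$width_norm[d$extreme == "min"]
  }, logical(1))
  expect_true(all(cmp))
  expect_false(any(pr$region == "R5"))  # no width exists for R5
})

test_that("without coupling, quadrature widths show no systematic trade-off ordering", {
  p <- noise_free_preset("chew_default")
  p$deformation$kappa <- 0
  p$deformation$width_phase <- (p$deformation$length_phase[1:4] + 25) %% 100
  p$deformation$marker_noise_sd <- 0.3
  out <- run_sim_pipeline("chew_default", 50, seed = 35, specs = p)
  pr <- out$res$pairs
  byrec <- split(pr, list(pr$cycle, pr$region), drop = TRUE)
  lower <- vapply(byrec, function(d) {
    d$width_norm[d$extreme == "max"] < d$width_norm[d$extreme == "min"]
  }, logical(1))
  bt <- stats::binom.test(sum(lower), length(lower))
  expect_gt(bt$p.value, 0.05)
})

test_that("a single constant cycle yields identical max and min trade-off records", {
  n <- 101
  cycles <- data.frame(cycle = 1L, behavior = "chew", start = 1L,
                       end = as.integer(n), min_gape_frame = 50L,
                       excluded = FALSE)
  ds <- data.frame(frame = seq_len(n), flagged = FALSE,
                   R1_norm = 1.1, W1_norm = 0.9)
  s <- cycle_deformation_summary(ds, cycles)
  pr <- length_width_pairs(s, ds)
  pr1 <- pr[pr$region == "R1", ]
  expect_equal(pr1$length_norm[1], pr1$length_norm[2])
  expect_equal(pr1$width_norm[1], pr1$width_norm[2])
})
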