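test_that("the generator is deterministic given a seed", {
  j1 <- generate_jaw_trace(cycle_spec("chew", noise_sd_deg = 0.3), 5, seed = 4)
  j2 <- generate_jaw_trace(cycle_spec("chew", noise_sd_deg = 0.3), 5, seed = 4)
  expect_identical(j1$pitch$rz, j2$pitch$rz)
  expect_identical(j1$truth, j2$truth)
  t1 <- generate_tongue_markers(preset("chew_default")$deformation, j1, seed = 9)
  t2 <- generate_tongue_markers(preset("chew_default")$deformation, j2, seed = 9)
  expect_identical(t1$markers$positions, t2$markers$positions)
})

test_that("without jitter, frames per cycle equal phase durations times frame rate", {
  spec <- cycle_spec("chew", duration_jitter = 0)
  jaw <- generate_jaw_trace(spec, 6, seed = 1)
  frames_per_cycle <- sum(round(spec$phase_durations_s * spec$frame_rate))
  # nominal cycle boundaries are evenly spaced by the cycle duration
  expect_equal(unique(diff(jaw$truth$start)), frames_per_cycle)
  expect_equal(jaw$truth$end - jaw$truth$start, rep(frames_per_cycle, 6))
})

test_that("incompatible phase durations are rejected", {
  expect_error(generate_jaw_trace(
    cycle_spec("chew", phase_durations_s = c(FC = 0.004, SC = 0.12,
                                             SO = 0.12, FO = 0.08)),
    3), ">= 3 frames")
  expect_error(cycle_spec("chew", fast_fraction = 0.4), "fast_fraction")
  # slow phase faster than fast phase is structurally impossible
  expect_error(cycle_spec("chew",
                          phase_durations_s = c(FC = 0.3, SC = 0.01,
                                                SO = 0.12, FO = 0.08)),
               "faster")
})

test_that("fast phases have higher mean speed than slow phases by construction", {
  for (beh in c("chew", "drink")) {
    sp <- cycle_spec(beh)
    if (beh == "chew") {
      expect_gt(sp$mean_speeds[["fast_close"]], sp$mean_speeds[["slow_close"]])
      expect_gt(sp$mean_speeds[["fast_open"]], sp$mean_speeds[["slow_open"]])
    } else {
      expect_gt(sp$mean_speeds[["fast_open"]], sp$mean_speeds[["slow_open"]])
    }
  }
})

test_that("a rigidly transported, non-deforming tongue shows zero deformation", {
  jaw <- generate_jaw_trace(cycle_spec("chew"), 5, seed = 6)
  dspec <- deformation_spec(length_amp = rep(0, 5), width_amp = rep(0, 4),
                            amp_jitter = 0, transport_amp_mm = 10,
                            transport_rot_deg = 5, marker_noise_sd = 0)
  tm <- generate_tongue_markers(dspec, jaw, seed = 7)
  ds <- deformation_series(tm$markers, tm$rest)
  s <- cycle_deformation_summary(ds, cbind(jaw$truth, behavior = "chew",
                                           excluded = FALSE))
  expect_true(all(abs(s$delta) < 1e-9))
  expect_true(all(abs(tm$truth$deformation$delta) < 1e-9))
})

test_that("impossible waveforms are rejected", {
  expect_error(deformation_spec(length_amp = rep(1.2, 5)), "\\(0, 2\\)")
  expect_error(deformation_spec(rest_lengths = c(-1, 1, 1, 1, 1) * 18),
               "positive")
  expect_error(deformation_spec(kappa = 1.5), "kappa")
})

test_that("presets reproduce the published per-cycle deformation magnitudes", {
  chew <- preset("chew_default")
  expect_equal(chew$nominal_deltas$total, 0.16, tolerance = 1e-9)
  expect_equal(unlist(chew$nominal_deltas[paste0("R", 1:5)], use.names = FALSE),
               c(0.37, 0.28, 0.40, 0.48, 0.34))
  expect_equal(unlist(chew$nominal_deltas[paste0("W", 1:4)], use.names = FALSE),
               c(0.32, 0.39, 0.37, 0.22))
  drink <- preset("drink_default")
  expect_equal(drink$nominal_deltas$total, 0.07, tolerance = 1e-9)
  expect_equal(unlist(drink$nominal_deltas[paste0("R", 1:5)], use.names = FALSE),
               c(0.14, 0.12, 0.12, 0.20, 0.19))
  expect_error(preset("nonsense"))
})

test_that("preset waveforms respect the published deformation envelopes", {
  for (nm in c("chew_default", "drink_default")) {
    p <- preset(nm)
    jaw <- generate_jaw_trace(p$cycle, 10, seed = 15)
    tm <- generate_tongue_markers(p$deformation, jaw, seed = 16)
    # total never lengthens beyond 1.1 x rest; all measures within 0.5-1.5
    expect_lte(max(tm$clean_norm[, "total"]), 1.1)
    expect_true(all(tm$clean_norm > 0.5 & tm$clean_norm < 1.5))
  }
})

test_that("noise-free generator plus pipeline is the identity on ground truth", {
  p <- noise_free_preset("chew_default")
  out <- run_sim_pipeline("chew_default", 8, seed = 25, specs = p,
                          config = default_analysis_config(
                            behavior = "chew", filter_target = "none"))
  cyc <- out$res$cycles
  tr <- out$sim$truth$cycles
  expect_equal(nrow(cyc), nrow(tr))
  expect_true(all(abs(cyc$start - tr$start) <= 1))
  expect_true(all(abs(cyc$min_gape_frame - tr$min_gape_frame) <= 1))
  m <- merge(out$res$summary, out$sim$truth$deformation,
             by = c("cycle", "measure"), suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(out$sim$truth$deformation))
  expect_lt(max(abs(m$delta - m$delta.t)), 1e-6)
  expect_lt(max(abs(m$max_norm - m$max_norm.t)), 1e-6)
  # extremum timings within one frame-quantum of standardized time
  quantum <- max(100 / (tr$end - tr$start))
  expect_lte(max(abs(m$t_max - m$t_max.t)), quantum)
  expect_lte(max(abs(m$t_min - m$t_min.t)), quantum)
})

test_that("group means of delta-L recover configured truth within 2 SEM under noise", {
  out <- cached("chew50_lownoise", {
    p <- preset("chew_default")
    p$deformation$marker_noise_sd <- 0.2  # tracking-noise scale of the check
    run_sim_pipeline("chew_default", 50, seed = 21, specs = p)
  })
  s <- out$res$summary
  td <- out$sim$truth$deformation
  for (m in c("total", paste0("R", 1:5))) {
    sv <- s$delta[s$measure == m]
    tv <- td$delta[td$measure == m]
    sem <- stats::sd(sv) / sqrt(length(sv))
    expect_lt(abs(mean(sv) - mean(tv)), 2 * sem, label = m)
  }
})
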