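# amplitude of a sinusoid at frequency f in a series, by least squares
# on a sine/cosine basis (immune to sample-phase artifacts)
fit_amplitude <- function(x, f, fs) {
  t <- seq_along(x) / fs
  b <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(b)[2:3]^2))
}

test_that("zero-phase filter has unit DC gain and the analytic cutoff attenuation", {
  expect_equal(lowpass_filter(rep(3.7, 200), 25, 2, 250), rep(3.7, 200),
               tolerance = 1e-9)
  t <- seq(0, 20, by = 1 / 250)
  mid <- 1000:4000
  # at the cutoff, forward-backward order 2: |H|^2 = 1/2
  s <- sin(2 * pi * 25 * t)
  y <- lowpass_filter(s, 25, 2, 250)
  expect_equal(fit_amplitude(y[mid], 25, 250), 0.5, tolerance = 0.02)
  # deep in the stopband
  s2 <- sin(2 * pi * 100 * t)
  y2 <- lowpass_filter(s2, 100 / 4, 2, 250)
  expect_lt(max(abs(y2[mid])), 0.05)
  # passband idempotence: 0.5 Hz changes by < 0.1%
  s3 <- sin(2 * pi * 0.5 * t)
  y3 <- lowpass_filter(s3, 25, 2, 250)
  expect_equal(fit_amplitude(y3[mid], 0.5, 250), 1, tolerance = 1e-3)
})

test_that("filter rejects invalid parameters and NA series", {
  expect_error(lowpass_filter(rnorm(100), 125, 2, 250), "Nyquist")
  expect_error(lowpass_filter(rnorm(5), 25, 2, 250), "too short")
  expect_error(lowpass_filter(c(rnorm(50), NA, rnorm(50)), 25, 2, 250),
               "missing")
})

test_that("pose fit recovers exact constructed transforms", {
  set.seed(1)
  ref <- matrix(rnorm(15, sd = 10), 5, 3)
  fit0 <- fit_rigid_pose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit0$residual, 0, tolerance = 1e-12)
  R <- rot_z(90); tr <- c(1, 2, 3)
  obs <- ref %*% t(R) + matrix(tr, 5, 3, byrow = TRUE)
  fit <- fit_rigid_pose(ref, obs)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tr, tolerance = 1e-9)
  expect_equal(fit$residual, 0, tolerance = 1e-9)
})

test_that("pose fit matches a brute-force minimization on noisy instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    ref <- matrix(rnorm(3 * n, sd = 15), n, 3)
    R <- random_rotation()
    obs <- ref %*% t(R) + matrix(rnorm(3, sd = 10), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = 0.1), n, 3)
    fit <- fit_rigid_pose(ref, obs)
    expect_equal(fit$residual, brute_pose_residual(ref, obs),
                 tolerance = 1e-6)
  }
})

test_that("pose fit yields proper rotations even for reflection-prone planar sets", {
  set.seed(3)
  for (i in 1:10) {
    ref <- cbind(matrix(rnorm(8, sd = 10), 4, 2), 0)  # planar
    obs <- ref %*% t(random_rotation()) + matrix(rnorm(12, sd = 0.5), 4, 3)
    fit <- fit_rigid_pose(ref, obs)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  }
})

test_that("degenerate marker sets are rejected", {
  expect_error(fit_rigid_pose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid_pose(line, line), "collinear")
})

test_that("skull-frame transform is the identity for a stationary skull and removes rigid scene motion", {
  set.seed(4)
  n <- 20
  tongue <- list(a = matrix(rnorm(3 * n, sd = 5), n, 3),
                 b = matrix(rnorm(3 * n, sd = 5), n, 3))
  id <- const_pose_series(diag(3), c(0, 0, 0), n)
  expect_equal(to_skull_frame(tongue, id), lapply(tongue, function(p) {
    dimnames(p) <- list(NULL, c("x", "y", "z")); p
  }), tolerance = 1e-12)

  # whole scene translated by (5,0,0) each frame: skull-frame tongue unchanged
  shift <- c(5, 0, 0)
  moved <- lapply(tongue, function(p) sweep(p, 2, shift, "+"))
  tr_pose <- const_pose_series(diag(3), shift, n)
  out <- to_skull_frame(moved, tr_pose)
  expect_equal(unname(out$a), unname(tongue$a), tolerance = 1e-9)

  # time-varying rigid rotation of the scene: pairwise distances preserved
  poses <- const_pose_series(diag(3), c(0, 0, 0), n)
  rotated <- tongue
  for (f in seq_len(n)) {
    R <- rot_z(10 * f) %*% rot_y(3 * f)
    poses$rotation[, , f] <- R
    for (nm in names(tongue))
      rotated[[nm]][f, ] <- R %*% tongue[[nm]][f, ]
  }
  out <- to_skull_frame(rotated, poses)
  d_world <- sqrt(rowSums((tongue$a - tongue$b)^2))
  d_skull <- sqrt(rowSums((out$a - out$b)^2))
  expect_equal(d_skull, d_world, tolerance = 1e-9)
  # and with this scene rotation the skull-frame coordinates equal the originals
  expect_equal(unname(out$a), unname(tongue$a), tolerance = 1e-9)
})

test_that("skull-frame transform rejects mismatched frame counts", {
  tongue <- list(a = matrix(0, 10, 3))
  expect_error(to_skull_frame(tongue, const_pose_series(diag(3), 0, 5)),
               "structural error")
})

test_that("jaw pitch extracts the z rotation and ignores pure y rotation", {
  n <- 4
  sk <- const_pose_series(diag(3), c(0, 0, 0), n)
  expect_equal(jaw_pitch_series(sk, sk)$rz, rep(0, n), tolerance = 1e-12)
  jz <- const_pose_series(rot_z(10), c(0, 0, 0), n, role = "jaw")
  expect_equal(jaw_pitch_series(sk, jz)$rz, rep(10, n), tolerance = 1e-9)
  jy <- const_pose_series(rot_y(10), c(0, 0, 0), n, role = "jaw")
  expect_equal(jaw_pitch_series(sk, jy)$rz, rep(0, n), tolerance = 1e-6)
  # identical pose series give identically zero pitch whatever the pose
  g <- const_pose_series(rot_z(33) %*% rot_y(21), c(1, 2, 3), n)
  expect_equal(jaw_pitch_series(g, g)$rz, rep(0, n), tolerance = 1e-9)
})

test_that("gape sign convention makes opening positive under either opening_sign", {
  rz <- c(0, -5, -10, -5, 0)  # jaw depresses: rz decreases as mouth opens
  jp <- jaw_pitch(rz, 250, opening_sign = 1)
  expect_equal(jp$gape, c(0, 5, 10, 5, 0))
  jp2 <- jaw_pitch(-rz, 250, opening_sign = -1)
  expect_equal(jp2$gape, c(0, 5, 10, 5, 0))
})
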