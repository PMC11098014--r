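rotate_y <- function(pos, phi) {
  out <- pos
  out[, , 1] <- pos[, , 1] * cos(phi) + pos[, , 3] * sin(phi)
  out[, , 3] <- -pos[, , 1] * sin(phi) + pos[, , 3] * cos(phi)
  out
}

# angular-momentum trace with a single prescribed y-axis series (fake but
# structurally valid; used to exercise the peak counting in isolation)
trace_from_series <- function(y_series, fps = 60) {
  n <- length(y_series)
  L <- array(0, c(n, 1, 3))
  L[, 1, 2] <- y_series
  structure(list(L = L, R = array(0, c(n, 1, 3)), fps = fps),
            class = "angmom_trace")
}

test_that("the default registry has 17 features in the 5/4/6/2 category shape", {
  reg <- feature_registry()
  expect_identical(nrow(reg$specs), 17L)
  expect_identical(anyDuplicated(reg$specs$name), 0L)
  counts <- table(reg$specs$category)
  expect_identical(as.integer(counts[c("sacrum", "extremities",
                                       "angular_momentum", "expandedness")]),
                   c(5L, 4L, 6L, 2L))
  aug <- feature_registry(augmented = TRUE)
  expect_identical(nrow(aug$specs), 20L)
  expect_identical(setdiff(aug$specs$name, reg$specs$name),
                   c("autocorr_peak_rate_x", "autocorr_peak_rate_y",
                     "autocorr_peak_rate_z"))
})

test_that("sacrum jerkiness matches cubic and sinusoid closed forms", {
  fps <- 60
  # static
  st <- differentiate(matrix(0.9, 40, 3), fps, no_smooth)
  expect_equal(sacrum_jerkiness(st), 0)
  # x(t) = a t^3 with a = 0.5 -> |jerk| = 6a = 3 exactly (raw differences)
  t <- (0:239) / fps
  cub <- differentiate(cbind(0.5 * t^3, 0, 0), fps, no_smooth)
  expect_equal(sacrum_jerkiness(cub), 3.0, tolerance = 1e-6)
  # y(t) = A sin(2 pi f t): mean |jerk| = A (2 pi f)^3 * 2/pi
  A <- 0.05; f <- 2
  t20 <- (0:(20 * fps - 1)) / fps
  sine <- differentiate(cbind(0, A * sin(2 * pi * f * t20), 0), fps, no_smooth)
  expect_equal(sacrum_jerkiness(sine), A * (2 * pi * f)^3 * 2 / pi,
               tolerance = 0.02)
})

test_that("ankle height uses the either-ankle floor and the two-ankle mean", {
  # constant ankles: floor equals the constant, heights all zero
  pose <- make_pose(n = 30)
  pos <- pose$positions
  pos[, 16, 2] <- 0.07; pos[, 17, 2] <- 0.07
  got <- ankle_height_stats(pose_sequence(pos, 60))
  expect_equal(got$mean, 0); expect_equal(got$sd, 0)
  # fixed asymmetric ankles
  pos[, 16, 2] <- 0; pos[, 17, 2] <- 0.2
  got <- ankle_height_stats(pose_sequence(pos, 60))
  expect_equal(got$mean, 0.1, tolerance = 1e-12)
  expect_equal(got$sd, 0, tolerance = 1e-12)
  # oscillating right ankle against the brute-force per-frame oracle
  t <- (0:299) / 60
  pos <- make_pose(n = 300)$positions
  pos[, 16, 2] <- 0
  pos[, 17, 2] <- 0.1 * (1 + sin(2 * pi * t))
  got <- ankle_height_stats(pose_sequence(pos, 60))
  la <- pos[, 16, 2]; ra <- pos[, 17, 2]
  floor_y <- min(pmin(la, ra))
  h <- (la + ra) / 2 - floor_y
  expect_equal(got$mean, mean(h), tolerance = 1e-12)
  expect_equal(got$sd, sqrt(mean((h - mean(h))^2)), tolerance = 1e-12)
})

test_that("extremity acceleration matches constant and centripetal closed forms", {
  fps <- 60
  n <- 120
  t <- (seq_len(n) - 1) / fps
  # static -> 0
  stack0 <- differentiate(make_pose(n = n)$positions, fps, no_smooth)
  expect_equal(extremity_acceleration(stack0, coco, "wrists"), 0)
  # both wrists x(t) = a t^2 / 2, a = 1 -> exactly 1 m/s^2
  par <- make_pose(n = n, offsets = only_joints(c(10, 11),
                   function(t) cbind(0.5 * t^2, 0, 0)))
  stack1 <- differentiate(par$positions, fps, no_smooth)
  expect_equal(extremity_acceleration(stack1, coco, "wrists"), 1.0,
               tolerance = 1e-6)
  # one wrist on a circle (r = 0.4, omega = 2 pi), the other static:
  # centripetal r omega^2 averaged over the two joints
  r <- 0.4; omega <- 2 * pi
  circ <- make_pose(n = 600, offsets = only_joints(10,
                    function(t) cbind(r * (cos(omega * t) - 1),
                                      r * sin(omega * t), 0)))
  stack2 <- differentiate(circ$positions, fps, no_smooth)
  expect_equal(extremity_acceleration(stack2, coco, "wrists"),
               r * omega^2 / 2, tolerance = 0.02)
})

test_that("angular momentum follows R x V with the circular-motion closed form", {
  fps <- 60
  # static pose: all L zero
  pose0 <- make_pose(n = 40)
  sac0 <- estimate_sacrum(pose0)
  tr0 <- angular_momentum_trace(pose0, sac0,
                                differentiate(pose0$positions, fps, no_smooth))
  expect_equal(max(abs(tr0$L)), 0)
  # one joint circling the sacrum in the X-Z plane: L = (0, r^2 omega, 0)
  r <- 0.5; omega <- pi
  n <- 600
  t <- (seq_len(n) - 1) / fps
  pos <- make_pose(n = n)$positions
  sacrum0 <- c(0, 0.95, 0)
  pos[, 10, 1] <- sacrum0[1] + r * cos(omega * t)
  pos[, 10, 2] <- sacrum0[2]
  pos[, 10, 3] <- sacrum0[3] - r * sin(omega * t)
  pose <- pose_sequence(pos, fps)
  sac <- estimate_sacrum(pose)
  tr <- angular_momentum_trace(pose, sac,
                               differentiate(pos, fps, no_smooth))
  expect_equal(mean(tr$L[, 10, 2]), r^2 * omega, tolerance = 0.02)
  expect_lt(max(abs(tr$L[, 10, 1])), 0.02 * r^2 * omega)
  expect_lt(max(abs(tr$L[, 10, 3])), 0.02 * r^2 * omega)
  # cross-product orthogonality on arbitrary motion: L . R = 0
  posr <- withr::with_seed(3, array(rnorm(30 * 17 * 3), c(30, 17, 3)))
  poser <- pose_sequence(posr, fps)
  sacr <- estimate_sacrum(poser)
  trr <- angular_momentum_trace(poser, sacr,
                                differentiate(posr, fps, no_smooth))
  dots <- rowSums(trr$L * trr$R, dims = 2)
  expect_lt(max(abs(dots)), 1e-9)
})

test_that("rotation statistics resolve the axis of rigid rotation", {
  fps <- 60; n <- 300
  t <- (seq_len(n) - 1) / fps
  omega <- 1.2
  # flatten the skeleton into the sacrum's horizontal plane, then spin about
  # the vertical axis: every joint has h = 0, so |L_j| = omega r_j^2
  base <- default_base_pose()
  base[, 2] <- 0.95
  spin <- generate_motion(motion_spec(duration = n / fps, fps = fps,
                                      base_pose = base, spin_rate = omega))
  sacs <- estimate_sacrum(spin)
  trs <- angular_momentum_trace(spin, sacs,
                                differentiate(spin$positions, fps, no_smooth))
  st <- angular_momentum_stats(trs)
  sacrum0 <- c(0, 0.95, 0)
  r2 <- rowSums(sweep(base, 2, sacrum0)[, c(1, 3)]^2)
  expect_equal(st$mean_mag, omega * mean(r2), tolerance = 0.01)
  expect_equal(st$horizontal_rotation, st$mean_mag, tolerance = 0.01)
  # cartwheel-like rotation about the X axis through the sacrum: joints are
  # placed on the axis plane (no lateral offset) so L is purely axial --
  # the vertical-component variant sees ~nothing, the literal X-Z variant
  # sees the full magnitude
  posc <- array(0, c(n, 17, 3))
  offs <- sweep(default_base_pose(), 2, sacrum0)
  offs[, 1] <- 0
  for (j in 1:17) {
    oy <- offs[j, 2]; oz <- offs[j, 3]
    posc[, j, 1] <- sacrum0[1]
    posc[, j, 2] <- sacrum0[2] + oy * cos(omega * t) - oz * sin(omega * t)
    posc[, j, 3] <- sacrum0[3] + oy * sin(omega * t) + oz * cos(omega * t)
  }
  posec <- pose_sequence(posc, fps)
  sacc <- estimate_sacrum(posec)
  trc <- angular_momentum_trace(posec, sacc,
                                differentiate(posc, fps, no_smooth))
  stc_default <- angular_momentum_stats(trc, "vertical")
  stc_literal <- angular_momentum_stats(trc, "xz")
  expect_gt(stc_default$mean_mag, 0.01)
  expect_lt(stc_default$horizontal_rotation, 0.05 * stc_default$mean_mag)
  expect_equal(stc_literal$horizontal_rotation, stc_literal$mean_mag,
               tolerance = 0.01)
})

test_that("sharp-movement rates count constructed peaks per second", {
  fps <- 60; n <- 600  # 10 s
  # constant series: no peaks on any axis
  expect_equal(unname(sharp_movement_counts(trace_from_series(rep(3, n)))),
               c(0, 0, 0))
  # 7 injected bumps, amplitude 10x the SD of a smooth slow background
  # oscillation -> exactly 0.7 peaks/s on y (count known by construction)
  t <- (seq_len(n) - 1) / fps
  background <- 0.1 * sin(2 * pi * 0.25 * t)
  series <- background
  centers <- seq(0.7, 9.3, length.out = 7)
  amp <- 10 * sd(background)
  for (ct in centers) {
    series <- series + amp * exp(-(t - ct)^2 / (2 * 0.05^2))
  }
  rates <- sharp_movement_counts(trace_from_series(series))
  expect_equal(unname(rates["rate_y"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(rates["rate_x"]), 0)
  # |sin| peaks twice per period: 1 Hz over 10 whole periods -> 2 peaks/s
  rates_sin <- sharp_movement_counts(trace_from_series(sin(2 * pi * t)))
  expect_equal(unname(rates_sin["rate_y"]), 2.0, tolerance = 0.05)
})

test_that("expandedness is the pooled joint-to-sacrum distance", {
  fps <- 60
  # all joints collapsed onto the sacrum
  pos <- array(0.5, c(10, 17, 3))
  pose <- pose_sequence(pos, fps)
  got <- expandedness_stats(pose, estimate_sacrum(pose))
  expect_equal(got$mean, 0); expect_equal(got$sd, 0)
  # all joints at distance exactly 1 from the sacrum
  pos1 <- array(0, c(10, 17, 3))
  dirs <- cbind(cos(seq_len(17)), 0, sin(seq_len(17)))
  dirs[12, ] <- c(1, 0, 0); dirs[13, ] <- c(-1, 0, 0)  # hips symmetric
  for (j in 1:17) pos1[, j, ] <- matrix(dirs[j, ], 10, 3, byrow = TRUE)
  pose1 <- pose_sequence(pos1, fps)
  got1 <- expandedness_stats(pose1, estimate_sacrum(pose1))
  expect_equal(got1$mean, 1, tolerance = 1e-12)
  expect_equal(got1$sd, 0, tolerance = 1e-9)
  # homogeneity: scaling all coordinates scales mean and sd by c
  posr <- withr::with_seed(5, array(rnorm(20 * 17 * 3), c(20, 17, 3)))
  poser <- pose_sequence(posr, fps)
  g1 <- expandedness_stats(poser, estimate_sacrum(poser))
  poses <- pose_sequence(posr * 3, fps)
  g3 <- expandedness_stats(poses, estimate_sacrum(poses))
  expect_equal(g3$mean, 3 * g1$mean, tolerance = 1e-12)
  expect_equal(g3$sd, 3 * g1$sd, tolerance = 1e-12)
})

test_that("sacrum translation statistics match glide and sinusoid closed forms", {
  fps <- 60; n <- 600
  t <- (seq_len(n) - 1) / fps
  # static
  pose0 <- make_pose(n = 60)
  sac0 <- estimate_sacrum(pose0)
  st0 <- sacrum_translation_stats(sac0, differentiate(array(sac0, c(60, 1, 3)),
                                                      fps, no_smooth))
  expect_equal(st0$xz_speed_mean, 0); expect_equal(st0$height_sd, 0)
  # uniform glide at (0.3, 0, 0.4): speed 0.5 by the 3-4-5 triangle
  glide <- make_pose(n = n, offsets = whole_body(function(t)
    cbind(0.3 * t, 0, 0.4 * t)))
  sacg <- estimate_sacrum(glide)
  stg <- sacrum_translation_stats(sacg, differentiate(array(sacg, c(n, 1, 3)),
                                                      fps, no_smooth))
  expect_equal(stg$xz_speed_mean, 0.5, tolerance = 1e-9)
  # vertical sinusoid of amplitude A over whole periods: SD = A / sqrt(2)
  A <- 0.07
  bob <- make_pose(n = n, offsets = whole_body(function(t)
    cbind(0, A * sin(2 * pi * 2 * t), 0)))
  sacb <- estimate_sacrum(bob)
  stb <- sacrum_translation_stats(sacb, differentiate(array(sacb, c(n, 1, 3)),
                                                      fps, no_smooth))
  expect_equal(stb$height_sd, A / sqrt(2), tolerance = 0.01)
})

test_that("bounce frequency and regularity separate periodic from aperiodic", {
  fps <- 60; n <- 600
  t <- (seq_len(n) - 1) / fps
  # pure 2 Hz sine: frequency within one spectral bin, regularity near 1
  sac <- cbind(0, 0.9 + 0.05 * sin(2 * pi * 2 * t), 0)
  got <- bounce_features(sac, fps)
  expect_equal(got$frequency, 2, tolerance = fps / n / 2)
  expect_gt(got$regularity, 0.95)
  expect_lte(got$regularity, 1)
  # constant series: degenerate (0, 0) convention
  gotc <- bounce_features(cbind(0, rep(0.9, n), 0), fps)
  expect_equal(gotc$frequency, 0); expect_equal(gotc$regularity, 0)
  # white noise: no credible periodicity
  sacn <- withr::with_seed(12, cbind(0, 0.9 + rnorm(n, sd = 0.05), 0))
  expect_lt(bounce_features(sacn, fps)$regularity, 0.3)
  expect_error(bounce_features(sac[1:30, ], fps), "length error")
})

test_that("autocorrelation peak counts reflect whole periods in the lag window", {
  fps <- 60; n <- 600
  t <- (seq_len(n) - 1) / fps
  # 2 Hz sinusoid, 10 s: acf peaks every 0.5 s across the 5 s lag window
  counts <- autocorr_peak_counts(trace_from_series(sin(2 * pi * 2 * t)))
  expect_gte(unname(counts["n_y"]), 8)
  expect_lte(unname(counts["n_y"]), 11)
  expect_equal(unname(counts["n_x"]), 0)
  # white noise: about zero
  noise <- withr::with_seed(21, rnorm(n))
  expect_lte(unname(autocorr_peak_counts(trace_from_series(noise))["n_y"]), 2)
  # constant series
  expect_equal(unname(autocorr_peak_counts(trace_from_series(rep(1, n)))),
               c(0, 0, 0))
})

test_that("the full 17-vector is finite and zeroes out on a static pose", {
  pose <- generate_motion(motion_spec(duration = 6, bounce_amplitude = 0.04,
                                      bounce_frequency = 2, spin_rate = 0.5,
                                      limb_amplitude = 0.1,
                                      limb_frequency = 1.5,
                                      noise_sd = 0.004, seed = 2))
  fv <- extract_features(pose)
  expect_length(fv, 17)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_registry()$specs$name)
  # static standing pose: every dynamic feature zero, expandedness intact
  static <- make_pose(n = 360)
  fs <- extract_features(static, smoothing = no_smooth)
  dynamic <- setdiff(names(fs), c("expandedness_mean", "expandedness_sd",
                                  "ankle_height_mean", "ankle_height_sd"))
  expect_equal(max(abs(fs[dynamic])), 0)
  sacs <- estimate_sacrum(static)
  expect_equal(unname(fs["expandedness_mean"]),
               expandedness_stats(static, sacs)$mean)
})

test_that("features are invariant to global translation and vertical rotation", {
  pose <- generate_motion(motion_spec(duration = 8, bounce_amplitude = 0.05,
                                      bounce_frequency = 2, spin_rate = 0.7,
                                      limb_amplitude = 0.15,
                                      limb_frequency = 2, seed = 5))
  fv <- extract_features(pose, smoothing = no_smooth)
  # translation
  shifted <- pose$positions
  for (a in 1:3) shifted[, , a] <- shifted[, , a] + c(4, 1.5, -2)[a]
  fv_t <- extract_features(pose_sequence(shifted, pose$fps),
                           smoothing = no_smooth)
  expect_lt(max(abs(fv_t - fv)), 1e-9)
  # rotation about the vertical axis: everything except the axis-resolved
  # horizontal sharp rates is preserved
  fv_r <- extract_features(pose_sequence(rotate_y(pose$positions, 0.7),
                                         pose$fps), smoothing = no_smooth)
  keep <- setdiff(names(fv), c("sharp_rate_x", "sharp_rate_z"))
  expect_equal(unclass(fv_r[keep]), unclass(fv[keep]), tolerance = 1e-6)
})

test_that("features scale with uniform spatial scaling as their units dictate", {
  pose <- generate_motion(motion_spec(duration = 8, bounce_amplitude = 0.05,
                                      bounce_frequency = 2, spin_rate = 0.7,
                                      limb_amplitude = 0.15,
                                      limb_frequency = 2, seed = 6))
  c_scale <- 2.5
  fv <- extract_features(pose, smoothing = no_smooth)
  fv_s <- extract_features(pose_sequence(pose$positions * c_scale, pose$fps),
                           smoothing = no_smooth)
  linear <- c("sacrum_xz_speed_mean", "sacrum_height_sd", "sacrum_jerkiness",
              "wrist_accel_mean", "ankle_accel_mean", "ankle_height_mean",
              "ankle_height_sd", "expandedness_mean", "expandedness_sd")
  quadratic <- c("angmom_mean_mag", "angmom_sd_mag", "horizontal_rotation")
  invariant <- c("bounce_frequency", "bounce_regularity", "sharp_rate_x",
                 "sharp_rate_y", "sharp_rate_z")
  expect_equal(unclass(fv_s[linear]), unclass(fv[linear]) * c_scale,
               tolerance = 1e-9)
  expect_equal(unclass(fv_s[quadratic]), unclass(fv[quadratic]) * c_scale^2,
               tolerance = 1e-9)
  expect_equal(unclass(fv_s[invariant]), unclass(fv[invariant]),
               tolerance = 1e-9)
})

test_that("tiling a periodic sequence leaves averaged features stable", {
  pose <- generate_motion(motion_spec(duration = 5, bounce_amplitude = 0.05,
                                      bounce_frequency = 2,
                                      limb_amplitude = 0.15,
                                      limb_frequency = 2, seed = 7))
  tiled <- pose_sequence(
    pose$positions[rep(seq_len(n <- dim(pose$positions)[1]), 3), , ],
    pose$fps)
  fv1 <- extract_features(pose, smoothing = no_smooth)
  fv3 <- extract_features(tiled, smoothing = no_smooth)
  compare <- setdiff(names(fv1), c("sharp_rate_x", "sharp_rate_y",
                                   "sharp_rate_z"))
  nonzero <- compare[abs(fv1[compare]) > 1e-9]
  expect_lt(max(abs(fv3[nonzero] / fv1[nonzero] - 1)), 0.02)
  zero <- setdiff(compare, nonzero)
  expect_lt(max(abs(fv3[zero])), 1e-6)
})
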