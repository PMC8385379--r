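test_that("elevation traces are zero for static strikes and body-referenced", {
  ch <- tiny_chain(3)
  pr <- joint_program(numeric(0), ch$n_joints)
  s <- simulate_strike(ch, pr, 0.05, noise_model(0))
  elev <- elevation_trace(s, use_markers = FALSE)
  expect_equal(elev$elevation_deg, rep(0, n_frames(s$markers)))
  expect_equal(attr(elev, "peak_deg"), 0)
  # whole-fish pitch: co-rotating neurocranium and body plane -> trace 0
  G <- function(i) vertkin:::rotation_about_point(rot_z(0.2 * i), c(0, 0, 0))
  poses <- strike_pose_sequences(s, use_markers = FALSE)
  for (nm in names(poses)) {
    for (i in seq_len(n_frames(poses[[nm]])))
      poses[[nm]]$transforms[, , i] <- G(i) %*% poses[[nm]]$transforms[, , i]
  }
  elev2 <- elevation_trace(s, poses)
  expect_equal(elev2$elevation_deg, rep(0, n_frames(s$markers)),
               tolerance = 1e-9)
})

test_that("the inclusion rule is boundary-inclusive and monotone", {
  expect_false(include_strike(4.99))
  expect_true(include_strike(5.0))
  expect_true(include_strike(18.6))
  thresholds <- seq(0, 20, 0.5)
  inc <- vapply(thresholds, function(th) include_strike(12.3, th), logical(1))
  expect_true(all(diff(as.integer(inc)) <= 0))  # monotone in threshold
})

test_that("joint deltas at peak equal the programmed amplitudes (round trip)", {
  ch <- build_preset("frogfish")
  pr <- joint_program(c("1" = 18, "2" = 24, "5" = 6, "8" = -5), ch$n_joints)
  s <- simulate_strike(ch, pr, 0.05, noise_model(0))
  res <- analyze_strike(s, use_markers = TRUE, filter_cutoff = NULL)
  expect_equal(unname(res$deltas_deg), pr$amplitude, tolerance = 1e-6)
  # static strike -> all deltas zero
  s0 <- simulate_strike(ch, joint_program(numeric(0), ch$n_joints), 0.01,
                        noise_model(0))
  r0 <- analyze_strike(s0, use_markers = FALSE)
  expect_equal(unname(r0$deltas_deg), rep(0, ch$n_joints), tolerance = 1e-10)
})

test_that("full noise-free round trip recovers every trace on both presets", {
  for (preset in c("frogfish", "trout")) {
    ch <- build_preset(preset)
    pr <- preset_program(ch)
    s <- simulate_strike(ch, pr, if (preset == "frogfish") 0.05 else 0.15,
                         noise_model(0))
    res <- analyze_strike(s, use_markers = TRUE, filter_cutoff = NULL)
    for (j in seq_len(ch$n_joints)) {
      expect_lt(max(abs(res$joint_traces[[j]]$rot_z - s$truth_angles[, j])),
                1e-6)
    }
    elev_truth <- rowSums(s$truth_angles)
    expect_lt(max(abs(res$elevation$elevation_deg - elev_truth)), 1e-6)
  }
})

test_that("curvature profiles follow planar geometry and frame invariance", {
  ch <- tiny_chain(4)
  # static straight chain -> all zeros after baseline subtraction
  s0 <- simulate_strike(ch, joint_program(numeric(0), ch$n_joints), 0.02,
                        noise_model(0))
  p0 <- curvature_profile(s0, n_frames(s0$markers), use_markers = FALSE)
  expect_equal(p0$dy_mm, rep(0, 5), tolerance = 1e-10)
  expect_equal(p0$y_mm[5], 0)  # caudal-most defines the frame
  # single rotating joint: landmarks cranial to it rise by r*sin(theta)
  theta <- 10
  pr <- joint_program(c("3" = theta), ch$n_joints, onset_s = 0, rise_s = 0.01)
  s <- simulate_strike(ch, pr, 0.02, noise_model(0))
  nf <- n_frames(s$markers)
  prof <- curvature_profile(s, nf, use_markers = FALSE)
  pivot_x <- ch$pivot_world_ref[[3]][1]
  sin_t <- sin(theta * pi / 180)
  # landmark x positions at reference: joint-1 pivot for the neurocranium,
  # centrum centroids for vertebrae
  lx <- c(ch$pivot_world_ref[[1]][1],
          vapply(2:5, function(k) ch$ref_pose[[k]][1, 4], numeric(1)))
  expected <- pmax(lx - pivot_x, 0) * sin_t
  expect_equal(prof$dy_mm, expected, tolerance = 1e-9)
  # per-centrum first differences: the rigid unit cranial of the rotating
  # joint steps uniformly; everything caudal of the joint is flat zero
  d <- per_centrum_translation(prof)
  expect_equal(d$delta_y_mm, expected[-5] - expected[-1], tolerance = 1e-9)
  expect_gt(abs(d$delta_y_mm[3]), 0)   # step present at the joint
  expect_equal(d$delta_y_mm[4], 0, tolerance = 1e-10)  # quiet caudally
  # whole-chain rigid translation leaves the profile unchanged
  poses <- strike_pose_sequences(s, use_markers = FALSE)
  G <- homogeneous(diag(3), c(25, -10, 5))
  for (nm in names(poses))
    for (i in seq_len(nf))
      poses[[nm]]$transforms[, , i] <- G %*% poses[[nm]]$transforms[, , i]
  prof2 <- curvature_profile(s, nf, poses)
  expect_equal(prof2$dy_mm, prof$dy_mm, tolerance = 1e-9)
})

test_that("per-centrum translation is the caudal-neighbour first difference", {
  prof <- structure(
    data.frame(position = 0:2, bone = c("neurocranium", "v1", "v2"),
               y_mm = c(3, 1, 0), dy_mm = c(3, 1, 0)),
    class = c("curvature_profile", "data.frame"))
  d <- per_centrum_translation(prof)
  expect_equal(d$delta_y_mm, c(2, 1))
  expect_equal(per_centrum_translation(
    within(prof, dy_mm <- rep(2, 3)))$delta_y_mm, c(0, 0))
})

test_that("cohort summaries report mean, s.e., max and n", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$max, 3)
  expect_equal(s$n, 3)
  s1 <- cohort_summary(7)
  expect_equal(s1$se, 0)
  expect_true(s1$single_strike)
  expect_error(cohort_summary(numeric(0)), "no values")
})

test_that("cohort summaries recover the moments of a programmed cohort", {
  set.seed(501)
  ch <- build_preset("frogfish", n_vertebrae = 6)
  pr <- joint_program(c("1" = 18, "2" = 23), ch$n_joints)
  strikes <- strike_cohort(ch, pr, 18, 0.05, noise_model(0), seed = 77,
                           jitter_sd_frac = 0.1)
  peaks <- vapply(strikes, function(s)
    attr(elevation_trace(s, use_markers = FALSE), "peak_deg"), numeric(1))
  cs <- cohort_summary(peaks)
  expect_equal(cs$n, 18)
  # programmed: mean 41 with 10% per-joint jitter; Monte-Carlo tolerance
  expect_lt(abs(cs$mean - 41) / 41, 0.1)
  expect_gt(cs$se, 0)
  expect_gte(cs$max, cs$mean)
})

test_that("mean traces average aligned strikes where at least two overlap", {
  base <- data.frame(frame = 1:50, time_s = (0:49) / 500,
                     elevation_deg = c(rep(0, 9), seq(0, 10, length.out = 41)))
  mk <- function(df) {
    pk <- which.max(df$elevation_deg)
    structure(df, class = c("elevation_trace", "data.frame"),
              peak_deg = max(df$elevation_deg), peak_frame = pk,
              onset_frame = vertkin:::detect_onset(df$elevation_deg,
                                                   max(df$elevation_deg)),
              duration_ms = NA_real_)
  }
  t1 <- mk(base)
  m_same <- mean_trace(list(t1, t1))
  expect_equal(m_same$mean_deg,
               base$elevation_deg[m_same$step + attr(t1, "onset_frame")])
  t2 <- mk(within(base, elevation_deg <- elevation_deg * 2))
  m <- mean_trace(list(t1, t2))
  expect_equal(m$mean_deg,
               1.5 * base$elevation_deg[m$step + attr(t1, "onset_frame")],
               tolerance = 1e-12)
  # different lengths: mean defined only where >= 2 strikes overlap
  t3 <- mk(base[1:30, ])
  m2 <- mean_trace(list(t1, t3))
  expect_lte(max(m2$step), 30 - attr(t3, "onset_frame"))
  expect_true(all(m2$n_strikes >= 2))
})
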