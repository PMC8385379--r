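test_that("build_acs constructs a right-handed anatomical frame", {
  # landmarks on the world axes -> identity orientation, origin at centroid
  a <- build_acs("v1", cranial_endplate = c(1, 0, 0),
                 caudal_endplate = c(-1, 0, 0), dorsal_landmark = c(0, 1, 0))
  expect_equal(a$orientation, diag(3), tolerance = 1e-12)
  expect_equal(a$origin, c(0, 0, 0))
  # equivariance: rotating the landmarks rotates the orientation exactly
  set.seed(401)
  R <- random_rotation()
  b <- build_acs("v1", as.numeric(R %*% c(1, 0, 0)),
                 as.numeric(R %*% c(-1, 0, 0)), as.numeric(R %*% c(0, 1, 0)))
  expect_equal(b$orientation, R, tolerance = 1e-12)
  # non-orthogonal dorsal landmark: y is orthogonalized against x
  c_ <- build_acs("v1", c(1, 0, 0), c(-1, 0, 0), c(0.7, 1, 0))
  expect_equal(sum(c_$orientation[, 1] * c_$orientation[, 2]), 0,
               tolerance = 1e-12)
  expect_equal(sqrt(sum(c_$orientation[, 2]^2)), 1, tolerance = 1e-12)
  expect_equal(det(c_$orientation), 1, tolerance = 1e-12)
  expect_error(build_acs("v1", c(1, 0, 0), c(-1, 0, 0), c(0.5, 0, 0)),
               "degenerate")
})

test_that("jcs_decompose reports the six DOF with the stated sign convention", {
  j_flip <- jcs(1, acs("a"), acs("b"), sign_flip_z = TRUE)
  j_raw <- jcs(1, acs("a"), acs("b"), sign_flip_z = FALSE)
  # coincident ACSs -> all zero
  row <- jcs_decompose(j_raw, diag(4), diag(4))
  expect_equal(unlist(row[1:6]), rep(0, 6), ignore_attr = TRUE)
  # pure 10 deg z rotation of the distal bone
  row <- jcs_decompose(j_raw, diag(4), homogeneous(rot_z(10)))
  expect_equal(row$rot_z, 10, tolerance = 1e-10)
  expect_equal(c(row$rot_y, row$rot_x, row$trans_x, row$trans_y, row$trans_z),
               rep(0, 5), tolerance = 1e-10)
  row <- jcs_decompose(j_flip, diag(4), homogeneous(rot_z(10)))
  expect_equal(row$rot_z, -10, tolerance = 1e-10)
  # 2 mm dorsal displacement, no rotation
  row <- jcs_decompose(j_raw, diag(4), homogeneous(diag(3), c(0, 2, 0)))
  expect_equal(row$trans_y, 2, tolerance = 1e-12)
  expect_equal(row$rot_z, 0, tolerance = 1e-12)
})

test_that("decomposed joint rotations recompose to the relative rotation", {
  set.seed(402)
  j <- jcs(1, acs("a"), acs("b"))
  for (i in 1:300) {
    Wp <- homogeneous(random_rotation(), rnorm(3))
    Wd <- homogeneous(random_rotation(), rnorm(3))
    row <- jcs_decompose(j, Wp, Wd)
    if (abs(row$rot_y) > 89) next
    R_rel <- (invert_rigid(Wp) %*% Wd)[1:3, 1:3]
    R_back <- euler_zyx_to_mat(row$rot_z, row$rot_y, row$rot_x)
    expect_lt(rotation_angle_deg(R_rel, R_back), 1e-9)
  }
})

test_that("joint traces are world-frame invariant and propagate gaps", {
  set.seed(403)
  ch <- tiny_chain(3)
  pr <- joint_program(c("1" = 9, "2" = -4), ch$n_joints, onset_s = 0.01,
                      rise_s = 0.05)
  s <- simulate_strike(ch, pr, 0.1, noise_model(0))
  j <- ch$joint_cs[[1]]
  prox <- s$truth_poses[[ch$bones[1]]]
  dist <- s$truth_poses[[ch$bones[2]]]
  tr <- joint_trace(j, prox, dist)
  # matches the programmed angles (dorsal positive)
  expect_equal(tr$rot_z, unname(s$truth_angles[, 1]), tolerance = 1e-9)
  # pre-multiplying all world poses by a rigid transform changes nothing
  G <- homogeneous(random_rotation(), c(100, -5, 40))
  re <- function(seqp) {
    arr <- seqp$transforms
    for (i in seq_len(dim(arr)[3])) arr[, , i] <- G %*% arr[, , i]
    pose_sequence(arr, seqp$bone_name, frame_rate = seqp$frame_rate,
                  validate = FALSE)
  }
  tr2 <- joint_trace(j, re(prox), re(dist))
  expect_equal(tr2$rot_z, tr$rot_z, tolerance = 1e-9)
  expect_equal(tr2$trans_y, tr$trans_y, tolerance = 1e-9)
  # a one-frame gap in the distal bone propagates to that frame only
  dist$transforms[, , 7] <- NA
  tr3 <- joint_trace(j, prox, dist)
  expect_equal(which(is.na(tr3$rot_z)), 7)
  # frame-count mismatch is an alignment error
  short <- pose_sequence(prox$transforms[, , 1:5], "x", validate = FALSE)
  expect_error(joint_trace(j, short, dist), "aligned")
})

test_that("virtual landmark trajectories follow planar joint geometry", {
  ch <- tiny_chain(3)
  theta <- 10
  poses0 <- chain_pose_at(ch, rep(0, 3))
  poses1 <- chain_pose_at(ch, c(0, theta, 0))  # only joint 2 rotates
  mk_seq <- function(poselist, bone) {
    pose_sequence(array(c(poses0[[bone]], poselist[[bone]]), c(4, 4, 2)),
                  bone, validate = FALSE)
  }
  ref_bone <- ch$bones[4]  # caudal-most vertebra
  ref_acs <- acs(ref_bone)
  ref_seq <- mk_seq(poses1, ref_bone)
  # landmark on the reference bone itself: constant trajectory
  traj <- virtual_landmark_trajectory(c(2, 1, 0), ref_seq, ref_acs, ref_seq)
  expect_equal(traj[1, ], traj[2, ], tolerance = 1e-12)
  # landmark on bone 2 (vertebra_01) at distance r cranial of joint 2's
  # pivot rises by r*sin(theta)
  bone <- ch$bones[2]
  pivot_b <- transform_points(invert_rigid(ch$ref_pose[[2]]),
                              ch$pivot_world_ref[[2]])
  r <- 4
  lm <- pivot_b + c(r, 0, 0)
  bone_seq <- mk_seq(poses1, bone)
  traj <- virtual_landmark_trajectory(lm, bone_seq, ref_acs, ref_seq)
  expect_equal(unname(traj[2, 2] - traj[1, 2]), r * sin(theta * pi / 180),
               tolerance = 1e-9)
  # whole-chain rigid translation leaves the trajectory unchanged
  G <- homogeneous(diag(3), c(30, 10, -5))
  shift <- function(sq) {
    arr <- sq$transforms
    for (i in 1:2) arr[, , i] <- G %*% arr[, , i]
    pose_sequence(arr, sq$bone_name, validate = FALSE)
  }
  traj2 <- virtual_landmark_trajectory(lm, shift(bone_seq), ref_acs,
                                       shift(ref_seq))
  expect_equal(traj2, traj, tolerance = 1e-9)
})
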