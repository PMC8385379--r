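# Shared fixtures: random rotations, small rigid bodies, tiny chains.

random_rotation <- function() {
  # uniform on SO(3) via quaternion from 4 normals
  q <- stats::rnorm(4)
  quat2mat(q / sqrt(sum(q^2)))
}

# 4 non-coplanar reference markers, pairwise separations within 5-15 mm
tetra_markers <- function(scale = 6) {
  pts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale / 2
  rownames(pts) <- paste0("m", 1:4)
  pts
}

# marker set for a rigid body following per-frame poses (list of 4x4)
markers_under_poses <- function(points, poses, frame_rate = 500,
                                sigma = 0, prefix = NULL) {
  nf <- length(poses)
  pos <- array(NA_real_, c(nf, nrow(points), 3))
  for (i in seq_len(nf)) pos[i, , ] <- transform_points(poses[[i]], points)
  if (sigma > 0) pos <- pos + array(stats::rnorm(length(pos), 0, sigma), dim(pos))
  nm <- rownames(points)
  if (!is.null(prefix)) nm <- paste0(prefix, nm)
  marker_trajectory_set(pos, frame_rate, nm)
}

# angle (deg) between two rotation matrices, accurate at tiny angles
# (Frobenius norm of Q - I resolves angles far below the acos() floor)
rotation_angle_deg <- function(Ra, Rb) {
  Q <- crossprod(Ra, Rb)
  2 * asin(pmin(1, norm(Q - diag(3), "F") / (2 * sqrt(2)))) * 180 / pi
}

# brute-force least-squares rigid fit: optimize intrinsic z-y-x Euler angles
# (translation closed-form given R), multi-start Nelder-Mead refined to high
# precision; independent of the SVD path under test
brute_force_fit <- function(ref, obs) {
  Pc <- colMeans(ref); Qc <- colMeans(obs)
  P0 <- sweep(ref, 2, Pc); Q0 <- sweep(obs, 2, Qc)
  obj <- function(ang) {
    R <- euler_zyx_to_mat(ang[1], ang[2], ang[3])
    sum((Q0 - P0 %*% t(R))^2)
  }
  starts <- expand.grid(z = c(-90, 0, 90, 180), y = c(-45, 0, 45),
                        x = c(-90, 0, 90))
  best <- Inf; best_ang <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (o$value < best) { best <- o$value; best_ang <- o$par }
  }
  o <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 10000))
  o2 <- stats::optim(o$par, obj, method = "BFGS",
                     control = list(reltol = 1e-16, maxit = 1000))
  if (o2$value < o$value) o <- o2
  R <- euler_zyx_to_mat(o$par[1], o$par[2], o$par[3])
  list(objective = o$value, pose = homogeneous(R, as.numeric(Qc - R %*% Pc)))
}

# minimal chain for unit work: neurocranium + nv vertebrae, straight
tiny_chain <- function(nv = 3, frame_rate = 500) {
  chain_model(c(10, rep(5, nv)), frame_rate = frame_rate,
              filter_cutoff = 60, body_speed = 0, species = NA_character_)
}
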