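#' Articulated-chain models
#'
#' A `chain_model` describes a neurocranium plus N vertebrae as an ordered
#' rigid chain: per-bone centrum lengths and reference poses, joint pivots
#' at the centrum endplate interfaces, bone-fixed marker placements, a
#' body-plane rigid reference attached to the caudal (base) region, and the
#' joint coordinate systems used to measure motion. Bone 1 is the
#' neurocranium; joint k connects bone k (cranial) to bone k+1 (caudal);
#' joint 1 is the craniovertebral joint. The caudal-most vertebra is the
#' fixed base of the chain.
#'
#' @param lengths centrum (and neurocranium) lengths, mm, cranial-first.
#' @param bone_names bone names, cranial-first (default: neurocranium,
#'   vertebra_01, ...).
#' @param ref_angles_deg per-joint reference z rotations (deg, dorsal
#'   positive) giving the chain's resting curvature; default straight.
#' @param frame_rate recording rate emulated, Hz.
#' @param filter_cutoff default low-pass cutoff, Hz.
#' @param body_speed whole-body forward translation speed superimposed on
#'   the chain, mm/s (0 = body stationary).
#' @param species preset label, if any.
#' @return an object of class `chain_model`.
#' @export
chain_model <- function(lengths, bone_names = NULL, ref_angles_deg = NULL,
                        frame_rate = 500, filter_cutoff = 60,
                        body_speed = 0, species = NA_character_) {
  M <- length(lengths)
  stopifnot(M >= 2, all(lengths > 0))
  if (is.null(bone_names))
    bone_names <- c("neurocranium", sprintf("vertebra_%02d", seq_len(M - 1)))
  J <- M - 1
  if (is.null(ref_angles_deg)) ref_angles_deg <- rep(0, J)
  stopifnot(length(ref_angles_deg) == J)

  # straight layout along +x (cranial), base caudal end at x = 0
  cranial_end <- rev(cumsum(rev(lengths)))
  center <- cranial_end - lengths / 2
  straight <- lapply(center, function(cx) homogeneous(diag(3), c(cx, 0, 0)))
  # pivot of joint j in the caudal bone's (bone j+1) local frame
  pivot_local <- lapply(seq_len(J), function(j) c(lengths[j + 1] / 2, 0, 0))

  ref_pose <- fk_poses(straight, pivot_local, ref_angles_deg)
  pivot_world_ref <- lapply(seq_len(J), function(j)
    transform_points(ref_pose[[j + 1]], pivot_local[[j]]))

  # bone-fixed markers: 4 per bone spanning the bone's full extent, as
  # implanted constellations do - caudal and cranial ends of the centrum,
  # the neural spine tip, and the neural arch (non-coplanar)
  markers <- list()
  for (k in seq_len(M)) {
    L <- lengths[k]
    pts <- rbind(
      c(-0.50, -0.30, 0.00),
      c( 0.50, -0.30, 0.20),
      c( 0.00,  1.20, -0.10),
      c( 0.30,  0.50, 0.20)
    ) * L
    rownames(pts) <- paste0(bone_names[k], "_m", 1:4)
    markers[[bone_names[k]]] <- pts
  }
  # body plane: intramuscular markers over the caudal half of the chain,
  # rigid with the base; body-plane frame = world frame at reference
  span <- cranial_end[1]
  bp <- rbind(
    c(0.05 * span, -6, 4),
    c(0.35 * span, 6, -4),
    c(0.20 * span, 8, 5),
    c(0.45 * span, -8, -5)
  )
  rownames(bp) <- paste0("bodyplane_m", 1:4)

  # chain-joint JCSs: both ACSs at the pivot, world orientation at
  # reference = the caudal bone's reference orientation; dorsal-positive
  # sign flip on
  joint_cs <- vector("list", J)
  for (j in seq_len(J)) {
    Rp <- ref_pose[[j]][1:3, 1:3]
    Rd <- ref_pose[[j + 1]][1:3, 1:3]
    prox <- acs(bone_names[j],
                origin = transform_points(invert_rigid(ref_pose[[j]]),
                                          pivot_world_ref[[j]]),
                orientation = crossprod(Rp, Rd))
    dist <- acs(bone_names[j + 1], origin = pivot_local[[j]],
                orientation = diag(3))
    joint_cs[[j]] <- jcs(j, prox, dist, sign_flip_z = TRUE)
  }
  # cranial-elevation JCS: body plane (proximal) vs neurocranium (distal),
  # placed at the craniovertebral pivot, no sign flip
  R1 <- ref_pose[[1]][1:3, 1:3]
  elev <- jcs("cranial_elevation",
              proximal = acs("bodyplane", origin = pivot_world_ref[[1]],
                             orientation = R1),
              distal = acs(bone_names[1],
                           origin = transform_points(invert_rigid(ref_pose[[1]]),
                                                     pivot_world_ref[[1]]),
                           orientation = diag(3)),
              sign_flip_z = FALSE)

  structure(
    list(bones = bone_names, lengths = lengths, n_joints = J,
         ref_angles_deg = ref_angles_deg, ref_pose = ref_pose,
         pivot_local = pivot_local, pivot_world_ref = pivot_world_ref,
         markers = markers, body_plane_markers = bp,
         joint_cs = joint_cs, elevation_jcs = elev,
         frame_rate = frame_rate, filter_cutoff = filter_cutoff,
         body_speed = body_speed, species = species),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model>%s %d bones (%s + %d vertebrae), %d joints @ %g Hz\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              length(x$bones), x$bones[1], length(x$bones) - 1, x$n_joints,
              x$frame_rate))
  invisible(x)
}

# forward kinematics: world poses of all bones given per-joint z rotations
# (deg, dorsal positive, relative to the supplied base poses)
fk_poses <- function(base_poses, pivot_local, theta_deg) {
  M <- length(base_poses)
  out <- vector("list", M)
  out[[M]] <- base_poses[[M]]
  for (k in (M - 1):1) {
    local_k <- invert_rigid(base_poses[[k + 1]]) %*% base_poses[[k]]
    joint_rot <- rotation_about_point(rot_z(theta_deg[k]), pivot_local[[k]])
    out[[k]] <- out[[k + 1]] %*% joint_rot %*% local_k
  }
  out
}

#' World poses of a chain at given joint angles
#'
#' Evaluates the chain's forward kinematics: each joint rotates its cranial
#' bone (and everything cranial to it) about the joint pivot's lateral (z)
#' axis, dorsal positive, relative to the reference pose. The caudal-most
#' vertebra is fixed.
#'
#' @param chain a `chain_model`.
#' @param theta_deg per-joint rotations, deg (length `chain$n_joints`).
#' @return named list of 4x4 world poses, one per bone.
#' @export
chain_pose_at <- function(chain, theta_deg) {
  stopifnot(length(theta_deg) == chain$n_joints)
  poses <- fk_poses(chain$ref_pose, chain$pivot_local, theta_deg)
  names(poses) <- chain$bones
  poses
}

#' Species presets
#'
#' `trout`: 25 modelled vertebrae (the cranial portion of the 62-vertebra
#' trout column that is animated in practice) plus neurocranium, uniform
#' 4 mm centra, straight resting column, 500 fps, 60 Hz default cutoff,
#' slow whole-body forward motion. `frogfish`: 18 vertebrae plus
#' neurocranium, centra graded from 12 mm cranially to 6 mm caudally, a
#' resting S-curve (dorsal over the cranial joints, ventral over the 8th to
#' 10th), 1000 fps, 100 Hz default cutoff, stationary body.
#'
#' @param name "trout" or "frogfish".
#' @param n_vertebrae optional override of the vertebra count (e.g. a
#'   minimal 2-3 bone chain for unit work).
#' @return a `chain_model`.
#' @export
build_preset <- function(name = c("trout", "frogfish"), n_vertebrae = NULL) {
  name <- match.arg(name)
  if (name == "trout") {
    nv <- n_vertebrae %||% 25
    lengths <- c(10, rep(4, nv))
    ref <- rep(0, nv)
    chain_model(lengths, ref_angles_deg = ref, frame_rate = 500,
                filter_cutoff = 60, body_speed = 50, species = "trout")
  } else {
    nv <- n_vertebrae %||% 18
    lengths <- c(18, seq(12, 6, length.out = nv))
    ref <- rep(0, nv)
    # resting S-curve, sagittal plane: dorsal cranially, ventral mid-column
    if (nv >= 10) {
      ref[3:5] <- 6
      ref[8:10] <- -6
    }
    chain_model(lengths, ref_angles_deg = ref, frame_rate = 1000,
                filter_cutoff = 100, body_speed = 0, species = "frogfish")
  }
}

#' Joint motion programs
#'
#' A joint program prescribes, per joint, a smooth ramp of dorsoventral (z)
#' rotation: amplitude (deg), onset (s), rise time (s), with a smoothstep
#' (3u^2 - 2u^3) profile that holds the amplitude after the ramp.
#'
#' @param amplitudes_deg named or indexed numeric vector of per-joint
#'   amplitudes, deg (joints not listed stay at 0). Names are joint indices.
#' @param n_joints number of joints in the target chain.
#' @param onset_s ramp onset, s (recycled per joint).
#' @param rise_s ramp duration, s (recycled; must be > 0).
#' @return an object of class `joint_program`.
#' @export
joint_program <- function(amplitudes_deg, n_joints,
                          onset_s = 0.005, rise_s = 0.03) {
  amp <- rep(0, n_joints)
  if (!is.null(names(amplitudes_deg))) {
    j <- as.integer(names(amplitudes_deg))
  } else {
    j <- seq_along(amplitudes_deg)
  }
  if (any(j < 1 | j > n_joints))
    stop("program references joint(s) outside 1..", n_joints)
  amp[j] <- amplitudes_deg
  stopifnot(all(rise_s > 0), all(is.finite(amp)))
  structure(list(amplitude = amp,
                 onset = rep_len(onset_s, n_joints),
                 rise = rep_len(rise_s, n_joints)),
            class = "joint_program")
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Programmed joint angles at given times
#'
#' @param program a `joint_program`.
#' @param t numeric vector of times, s.
#' @return length(t) x n_joints matrix of angles, deg.
#' @export
program_angles <- function(program, t) {
  J <- length(program$amplitude)
  out <- matrix(0, length(t), J)
  for (j in seq_len(J)) {
    out[, j] <- program$amplitude[j] *
      smoothstep((t - program$onset[j]) / program$rise[j])
  }
  out
}

#' Marker noise model
#'
#' Additive isotropic Gaussian noise per marker coordinate plus optional
#' per-marker-per-frame dropout, emulating X-ray marker tracking error.
#'
#' @param sigma_mm noise SD per axis, mm (default 0.05, inside the
#'   sub-0.1 mm precision regime of marker-based XROMM).
#' @param dropout probability a marker observation is lost in a frame.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_mm = 0.05, dropout = 0) {
  stopifnot(sigma_mm >= 0, dropout >= 0, dropout < 1)
  structure(list(sigma_mm = sigma_mm, dropout = dropout),
            class = "noise_model")
}

#' Simulate a feeding strike
#'
#' Drives the chain's forward kinematics with a joint program, records
#' noise-free ground-truth bone poses and programmed joint angles, and
#' emits marker trajectories (bone-fixed markers plus body-plane markers)
#' with the given noise model. The caudal-most vertebra is fixed in the
#' body frame; any whole-body forward motion of the preset is superimposed
#' on all bones and the body plane alike.
#'
#' @param chain a `chain_model`.
#' @param program a `joint_program` with `chain$n_joints` joints.
#' @param duration_s recording duration, s.
#' @param noise a `noise_model`.
#' @param seed RNG seed for the noise (optional).
#' @param id strike identifier.
#' @param individual individual identifier.
#' @return an object of class `strike_recording`: marker trajectories,
#'   ground-truth pose sequences (incl. the body plane), the programmed
#'   angle matrix, and the chain.
#' @export
simulate_strike <- function(chain, program, duration_s,
                            noise = noise_model(0), seed = NULL,
                            id = "strike1", individual = "ind1") {
  stopifnot(inherits(chain, "chain_model"), inherits(program, "joint_program"))
  if (length(program$amplitude) != chain$n_joints)
    stop("program has ", length(program$amplitude), " joints; chain has ",
         chain$n_joints)
  if (!is.null(seed)) set.seed(seed)
  fps <- chain$frame_rate
  nf <- round(duration_s * fps) + 1
  t <- (seq_len(nf) - 1) / fps
  theta <- program_angles(program, t)

  M <- length(chain$bones)
  pose_arr <- array(NA_real_, c(4, 4, nf, M))
  bp_arr <- array(NA_real_, c(4, 4, nf))
  n_mk <- 4 * M + nrow(chain$body_plane_markers)
  mk_names <- c(unlist(lapply(chain$markers, rownames), use.names = FALSE),
                rownames(chain$body_plane_markers))
  pos <- array(NA_real_, c(nf, n_mk, 3))
  for (i in seq_len(nf)) {
    body <- homogeneous(diag(3), c(chain$body_speed * t[i], 0, 0))
    poses <- fk_poses(chain$ref_pose, chain$pivot_local, theta[i, ])
    col <- 0
    for (k in seq_len(M)) {
      W <- body %*% poses[[k]]
      pose_arr[, , i, k] <- W
      mk <- transform_points(W, chain$markers[[chain$bones[k]]])
      pos[i, col + seq_len(nrow(mk)), ] <- mk
      col <- col + nrow(mk)
    }
    bp_arr[, , i] <- body
    pos[i, col + seq_len(nrow(chain$body_plane_markers)), ] <-
      transform_points(body, chain$body_plane_markers)
  }
  if (noise$sigma_mm > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, noise$sigma_mm), dim(pos))
  if (noise$dropout > 0) {
    drop <- matrix(stats::runif(nf * n_mk) < noise$dropout, nf, n_mk)
    for (k in 1:3) pos[, , k][drop] <- NA_real_
  }

  truth <- vector("list", M + 1)
  for (k in seq_len(M)) {
    truth[[k]] <- pose_sequence(pose_arr[, , , k, drop = TRUE],
                                chain$bones[k], frame_rate = fps,
                                validate = FALSE)
  }
  truth[[M + 1]] <- pose_sequence(bp_arr, "bodyplane", frame_rate = fps,
                                  validate = FALSE)
  names(truth) <- c(chain$bones, "bodyplane")
  colnames(theta) <- paste0("joint_", seq_len(chain$n_joints))

  structure(
    list(id = id, individual = individual, species = chain$species,
         frame_rate = fps,
         markers = marker_trajectory_set(pos, fps, mk_names),
         truth_poses = truth, truth_angles = theta,
         program = program, chain = chain),
    class = "strike_recording"
  )
}

#' @export
print.strike_recording <- function(x, ...) {
  cat(sprintf("<strike_recording> '%s' (%s), %d frames @ %g Hz, %d bones\n",
              x$id, x$species, n_frames(x$markers), x$frame_rate,
              length(x$chain$bones)))
  invisible(x)
}

#' Simulate a cohort of strikes
#'
#' Repeats [simulate_strike()] with per-strike, per-joint amplitude jitter
#' (Gaussian, SD = `jitter_sd_frac` x amplitude), emulating strike-to-strike
#' variation within and across individuals. Reproducible given `seed`.
#'
#' @param chain a `chain_model`.
#' @param program the cohort-mean `joint_program`.
#' @param n number of strikes (>= 1).
#' @param duration_s recording duration per strike, s.
#' @param noise a `noise_model`.
#' @param seed RNG seed.
#' @param jitter_sd_frac fractional SD of amplitude jitter (0 = identical
#'   strikes).
#' @return list of `strike_recording` objects.
#' @export
strike_cohort <- function(chain, program, n, duration_s,
                          noise = noise_model(0), seed = 1,
                          jitter_sd_frac = 0.15) {
  stopifnot(n >= 1)
  set.seed(seed + 700001L)
  jitter <- matrix(stats::rnorm(n * length(program$amplitude), 1,
                                jitter_sd_frac),
                   n, length(program$amplitude))
  strike_seeds <- seed + seq_len(n) - 1L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- program
    p$amplitude <- program$amplitude * jitter[i, ]
    out[[i]] <- simulate_strike(chain, p, duration_s, noise,
                                seed = strike_seeds[i],
                                id = sprintf("strike%02d", i))
  }
  out
}
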