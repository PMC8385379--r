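#' Anatomical coordinate systems
#'
#' An ACS is a bone-fixed frame whose axes follow anatomical directions:
#' +x craniocaudal (pointing cranially), +y dorsoventral (pointing
#' dorsally), +z lateral (pointing to the animal's left; right-handed).
#' Origin and orientation are expressed in the bone's reference frame (mm).
#'
#' @param bone_name bone the ACS is attached to.
#' @param origin length-3 origin, mm, bone reference frame.
#' @param orientation 3x3 proper rotation: columns are the ACS x, y, z axes
#'   in bone reference coordinates.
#' @return an object of class `acs`.
#' @export
acs <- function(bone_name, origin = c(0, 0, 0), orientation = diag(3)) {
  if (!is_rotation(orientation, tol = 1e-9))
    stop("ACS orientation must be a proper rotation matrix")
  structure(list(bone_name = bone_name, origin = as.numeric(origin),
                 orientation = orientation),
            class = "acs")
}

# world-from-ACS transform given the bone's world pose
acs_world <- function(a, bone_pose) {
  bone_pose %*% homogeneous(a$orientation, a$origin)
}

#' Build an ACS from centrum landmarks
#'
#' Constructs an anatomical coordinate system from three bone-frame
#' landmarks: the cranial and caudal endplate centroids of the centrum and
#' a dorsal landmark. The origin is the centrum centroid (endplate
#' midpoint); +x points from the caudal to the cranial endplate centroid;
#' +y is the component of (dorsal landmark - origin) orthogonal to x,
#' normalized; +z = x cross y (to the animal's left).
#'
#' @param bone_name bone name.
#' @param cranial_endplate,caudal_endplate,dorsal_landmark length-3
#'   landmarks in the bone reference frame, mm.
#' @return an `acs`.
#' @export
build_acs <- function(bone_name, cranial_endplate, caudal_endplate,
                      dorsal_landmark) {
  origin <- (cranial_endplate + caudal_endplate) / 2
  x <- cranial_endplate - caudal_endplate
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("endplate centroids coincide (degenerate)")
  x <- x / nx
  y <- dorsal_landmark - origin
  y <- y - sum(y * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9) stop("dorsal landmark collinear with endplate axis (degenerate)")
  y <- y / ny
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  acs(bone_name, origin, unname(cbind(x, y, z)))
}

#' Joint coordinate systems
#'
#' A JCS pairs two ACSs, one on each bone of a joint. The proximal ACS
#' defines the frame in which the distal ACS's motion is expressed. For
#' chain joints (craniovertebral and intervertebral) the proximal ACS sits
#' on the cranial bone and the distal on the caudal bone, and `sign_flip_z
#' = TRUE` negates the z rotation so that dorsal joint rotation is
#' positive. The cranial-elevation JCS instead uses the body plane as
#' proximal and the neurocranium as distal with no flip, so positive z is
#' elevation directly. Both ACSs coincide in the reference (CT) pose, making
#' all six degrees of freedom zero there.
#'
#' @param joint joint index (1 = craniovertebral) or a label.
#' @param proximal,distal `acs` objects.
#' @param sign_flip_z negate the reported z rotation (TRUE for chain
#'   joints, FALSE for the elevation JCS).
#' @return an object of class `jcs`.
#' @export
jcs <- function(joint, proximal, distal, sign_flip_z = FALSE) {
  stopifnot(inherits(proximal, "acs"), inherits(distal, "acs"))
  structure(list(joint = joint, proximal = proximal, distal = distal,
                 sign_flip_z = sign_flip_z),
            class = "jcs")
}

#' Decompose one frame of relative joint motion
#'
#' Computes the relative transform T = (world-from-proximal-ACS)^-1 *
#' (world-from-distal-ACS) and decomposes its rotation as intrinsic z-y-x
#' Euler angles (R = Rz Ry Rx). The reported `rot_z` is negated when the
#' JCS has `sign_flip_z`. Translations are the position of the distal ACS
#' origin in the proximal ACS frame. Frames within 0.5 deg of the gimbal
#' singularity (|rot_y| = 90 deg) carry a `gimbal` flag.
#'
#' @param joint_cs a `jcs`.
#' @param proximal_pose,distal_pose 4x4 world poses of the two bones.
#' @return one-row data.frame: rot_z, rot_y, rot_x (deg), trans_x, trans_y,
#'   trans_z (mm), gimbal (logical).
#' @export
jcs_decompose <- function(joint_cs, proximal_pose, distal_pose) {
  Wp <- acs_world(joint_cs$proximal, proximal_pose)
  Wd <- acs_world(joint_cs$distal, distal_pose)
  T <- invert_rigid(Wp) %*% Wd
  e <- euler_zyx(T[1:3, 1:3])
  data.frame(
    rot_z = if (joint_cs$sign_flip_z) -e$z else e$z,
    rot_y = e$y, rot_x = e$x,
    trans_x = T[1, 4], trans_y = T[2, 4], trans_z = T[3, 4],
    gimbal = e$gimbal
  )
}

#' Per-frame kinematics trace of one joint
#'
#' Applies [jcs_decompose()] over aligned pose sequences of the two bones.
#' A gap in either bone propagates to the trace.
#'
#' @param joint_cs a `jcs`.
#' @param proximal_seq,distal_seq `pose_sequence` objects of the proximal
#'   and distal bones, same frame count.
#' @return a `joint_kinematics_trace`: data.frame with frame, rot_z, rot_y,
#'   rot_x (deg), trans_x/y/z (mm), gimbal; NA rows at gaps.
#' @export
joint_trace <- function(joint_cs, proximal_seq, distal_seq) {
  if (n_frames(proximal_seq) != n_frames(distal_seq))
    stop("pose sequences are not aligned: ", n_frames(proximal_seq), " vs ",
         n_frames(distal_seq), " frames")
  nf <- n_frames(proximal_seq)
  out <- data.frame(frame = seq_len(nf), rot_z = NA_real_, rot_y = NA_real_,
                    rot_x = NA_real_, trans_x = NA_real_, trans_y = NA_real_,
                    trans_z = NA_real_, gimbal = NA)
  ok <- pose_present(proximal_seq) & pose_present(distal_seq)
  for (i in which(ok)) {
    row <- jcs_decompose(joint_cs, proximal_seq$transforms[, , i],
                         distal_seq$transforms[, , i])
    out[i, -1] <- row
  }
  class(out) <- c("joint_kinematics_trace", "data.frame")
  attr(out, "joint") <- joint_cs$joint
  out
}

#' Trajectory of a virtual landmark in a reference ACS
#'
#' Expresses a bone-fixed landmark's world path in the (moving) frame of a
#' reference ACS - typically an ACS on the caudal-most vertebra, so that
#' whole-body motion cancels and only column deformation remains.
#'
#' @param point length-3 landmark in the carrying bone's reference frame, mm.
#' @param bone_seq `pose_sequence` of the carrying bone.
#' @param ref_acs `acs` on the reference bone.
#' @param ref_seq `pose_sequence` of the reference bone, same frames.
#' @return frames x 3 matrix of landmark positions in the reference ACS
#'   frame (NA rows at gaps).
#' @export
virtual_landmark_trajectory <- function(point, bone_seq, ref_acs, ref_seq) {
  if (n_frames(bone_seq) != n_frames(ref_seq))
    stop("pose sequences are not aligned")
  nf <- n_frames(bone_seq)
  out <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  ok <- pose_present(bone_seq) & pose_present(ref_seq)
  ph <- c(point, 1)
  for (i in which(ok)) {
    Wref <- acs_world(ref_acs, ref_seq$transforms[, , i])
    p <- invert_rigid(Wref) %*% bone_seq$transforms[, , i] %*% ph
    out[i, ] <- p[1:3]
  }
  out
}
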