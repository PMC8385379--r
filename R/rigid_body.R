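#' Rigid body definitions
#'
#' Reference marker positions of a bone, expressed in the bone's reference
#' (CT) frame. At least three non-collinear markers are required for pose
#' estimation.
#'
#' @param bone_name bone name.
#' @param points named n x 3 matrix of reference marker positions, mm
#'   (rownames are marker names).
#' @return an object of class `rigid_body_definition`.
#' @export
rigid_body_definition <- function(bone_name, points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (is.null(rownames(points)))
    rownames(points) <- paste0(bone_name, "_m", seq_len(nrow(points)))
  if (nrow(points) < 3)
    stop("rigid body '", bone_name, "' needs at least 3 markers")
  ctr <- sweep(points, 2, colMeans(points))
  if (min(svd(ctr)$d[1:2]) <= 1e-6)
    stop("markers of '", bone_name, "' are collinear (degenerate geometry)")
  structure(list(bone_name = bone_name, points = points),
            class = "rigid_body_definition")
}

#' Fit a rigid pose to observed marker positions
#'
#' Least-squares superposition (Kabsch/orthogonal Procrustes with proper
#' rotation): finds the rigid transform T minimising the sum of squared
#' distances between transformed reference markers and their observed world
#' positions. Markers are matched by name; observed markers missing a
#' coordinate are dropped.
#'
#' @param definition a [rigid_body_definition()].
#' @param observed named n x 3 matrix of observed positions, mm (world).
#' @return list with `pose` (4x4 world-from-bone transform), `rmse` (mm,
#'   over the markers used) and `n_markers_used`.
#' @export
fit_rigid_pose <- function(definition, observed) {
  observed <- as.matrix(observed)
  ok <- stats::complete.cases(observed)
  observed <- observed[ok, , drop = FALSE]
  common <- intersect(rownames(definition$points), rownames(observed))
  if (length(common) < 3)
    stop("insufficient markers: only ", length(common),
         " common marker(s) between reference and observation")
  P <- definition$points[common, , drop = FALSE]
  Q <- observed[common, , drop = FALSE]
  Pc <- colMeans(P); Qc <- colMeans(Q)
  P0 <- sweep(P, 2, Pc); Q0 <- sweep(Q, 2, Qc)
  if (min(svd(P0)$d[1:2]) <= 1e-6)
    stop("common markers are collinear (degenerate geometry)")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(Qc - R %*% Pc)
  resid <- Q - (P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE))
  list(pose = homogeneous(R, t),
       rmse = sqrt(mean(rowSums(resid^2))),
       n_markers_used = length(common))
}

#' Fit a pose sequence from marker trajectories
#'
#' Applies [fit_rigid_pose()] frame by frame. Frames with fewer than three
#' usable markers become gaps; no interpolation is performed.
#'
#' @param set a `marker_trajectory_set`.
#' @param definition a [rigid_body_definition()]; only its markers are used.
#' @return a `pose_sequence` with per-frame `rmse` attached (NA at gaps).
#' @export
fit_pose_sequence <- function(set, definition) {
  nf <- n_frames(set)
  arr <- array(NA_real_, c(4, 4, nf))
  rmse <- rep(NA_real_, nf)
  usable <- 0
  for (i in seq_len(nf)) {
    obs <- marker_frame(set, i)
    obs <- obs[rownames(obs) %in% rownames(definition$points), , drop = FALSE]
    if (nrow(obs) < 3) next
    fit <- fit_rigid_pose(definition, obs)
    arr[, , i] <- fit$pose
    rmse[i] <- fit$rmse
    usable <- usable + 1
  }
  if (usable == 0)
    stop("no frame has enough markers to fit a pose for '",
         definition$bone_name, "'")
  pose_sequence(arr, definition$bone_name, frame_rate = set$frame_rate,
                rmse = rmse, validate = FALSE)
}

#' Marker tracking precision
#'
#' The precision statistic used for marker-based XROMM animation: for every
#' unordered pair of markers in the subset, take the per-frame Euclidean
#' inter-marker distance series and its sample standard deviation over
#' frames; return the mean of these standard deviations over all pairs.
#' Rigid noiseless motion gives exactly zero.
#'
#' @param set a `marker_trajectory_set`.
#' @param marker_subset marker names to use (default: all markers).
#' @return precision, mm.
#' @export
tracking_precision <- function(set, marker_subset = NULL) {
  if (is.null(marker_subset)) marker_subset <- set$markers
  marker_subset <- intersect(marker_subset, set$markers)
  if (length(marker_subset) < 2)
    stop("tracking_precision needs at least 2 markers")
  idx <- match(marker_subset, set$markers)
  sds <- c()
  for (a in seq_along(idx)[-length(idx)]) {
    for (b in (a + 1):length(idx)) {
      diff <- set$positions[, idx[a], , drop = FALSE] -
              set$positions[, idx[b], , drop = FALSE]
      d <- sqrt(rowSums(matrix(diff, ncol = 3)^2))
      d <- d[!is.na(d)]
      if (length(d) >= 2) sds <- c(sds, stats::sd(d))
    }
  }
  if (!length(sds))
    stop("no marker pair has 2 or more frames with both markers present")
  mean(sds)
}
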