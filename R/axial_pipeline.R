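#' Fit bone pose sequences from a strike's markers
#'
#' Rebuilds every bone's pose sequence (and the body plane's) from the
#' strike's marker trajectories by per-frame least-squares superposition,
#' optionally low-pass filtering the result. With `use_markers = FALSE` the
#' recording's stored (ground-truth or externally rotoscoped) pose
#' sequences are used instead.
#'
#' @param strike a `strike_recording`.
#' @param use_markers fit poses from markers (TRUE) or take the stored pose
#'   sequences (FALSE).
#' @param filter_cutoff low-pass cutoff in Hz, or NULL for no filtering.
#' @return named list of `pose_sequence` objects (bones + "bodyplane").
#' @export
strike_pose_sequences <- function(strike, use_markers = TRUE,
                                  filter_cutoff = NULL) {
  chain <- strike$chain
  if (use_markers) {
    seqs <- lapply(chain$bones, function(b)
      fit_pose_sequence(strike$markers,
                        rigid_body_definition(b, chain$markers[[b]])))
    names(seqs) <- chain$bones
    seqs$bodyplane <- fit_pose_sequence(
      strike$markers,
      rigid_body_definition("bodyplane", chain$body_plane_markers))
  } else {
    seqs <- strike$truth_poses
  }
  if (!is.null(filter_cutoff))
    seqs <- lapply(seqs, lowpass_filter_poses, cutoff = filter_cutoff,
                   frame_rate = strike$frame_rate)
  seqs
}

#' Cranial elevation trace of a strike
#'
#' Dorsal rotation of the neurocranium relative to the body plane: the z
#' rotation of the craniovertebral-joint JCS whose ACSs are attached to the
#' neurocranium and the body plane (positive z = elevation), baseline-
#' subtracted so the trace is zero at the first frame. Also locates the
#' peak and the motion onset (first frame where elevation exceeds 5% of
#' peak and stays above it for at least 5 frames).
#'
#' @param strike a `strike_recording`.
#' @param poses pose sequences from [strike_pose_sequences()] (computed
#'   noise-path by default).
#' @param ... passed to [strike_pose_sequences()] when `poses` is NULL.
#' @return an `elevation_trace`: data.frame (frame, time_s, elevation_deg)
#'   with attributes peak_deg, peak_frame, onset_frame, duration_ms.
#' @export
elevation_trace <- function(strike, poses = NULL, ...) {
  if (is.null(poses)) poses <- strike_pose_sequences(strike, ...)
  if (is.null(poses$bodyplane))
    stop("strike has no body-plane pose sequence")
  chain <- strike$chain
  tr <- joint_trace(chain$elevation_jcs, poses$bodyplane,
                    poses[[chain$bones[1]]])
  elev <- tr$rot_z - tr$rot_z[which(!is.na(tr$rot_z))[1]]
  out <- data.frame(frame = tr$frame,
                    time_s = (tr$frame - 1) / strike$frame_rate,
                    elevation_deg = elev)
  peak_frame <- which.max(elev)
  peak <- elev[peak_frame]
  onset <- detect_onset(elev, peak)
  structure(out,
            class = c("elevation_trace", "data.frame"),
            peak_deg = peak, peak_frame = peak_frame, onset_frame = onset,
            duration_ms = if (is.na(onset)) NA_real_ else
              (peak_frame - onset) / strike$frame_rate * 1000)
}

# first frame exceeding 5% of peak that stays above for >= 5 frames
detect_onset <- function(elev, peak, frac = 0.05, hold = 5) {
  if (!is.finite(peak) || peak <= 0) return(NA_integer_)
  above <- !is.na(elev) & elev > frac * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= hold)
  if (!length(cand)) return(NA_integer_)
  starts[cand[1]]
}

#' Strike inclusion rule
#'
#' A strike enters the cohort analysis only if its peak cranial elevation
#' reaches the threshold (boundary inclusive).
#'
#' @param trace an `elevation_trace` (or its peak in degrees).
#' @param threshold_deg inclusion threshold, deg (default 5).
#' @return TRUE/FALSE.
#' @export
include_strike <- function(trace, threshold_deg = 5) {
  peak <- if (inherits(trace, "elevation_trace"))
    attr(trace, "peak_deg") else as.numeric(trace)
  peak >= threshold_deg
}

#' Per-joint kinematics traces of a strike
#'
#' Dorsoventral (and off-axis) rotations plus translations at every chain
#' joint: joint 1 is the craniovertebral joint, joint k >= 2 the (k-1)-th
#' intervertebral joint. Dorsal rotation is positive.
#'
#' @param strike a `strike_recording`.
#' @param poses pose sequences (see [strike_pose_sequences()]).
#' @param ... passed to [strike_pose_sequences()] when `poses` is NULL.
#' @return named list of `joint_kinematics_trace` data.frames.
#' @export
joint_traces <- function(strike, poses = NULL, ...) {
  if (is.null(poses)) poses <- strike_pose_sequences(strike, ...)
  chain <- strike$chain
  out <- lapply(seq_len(chain$n_joints), function(j)
    joint_trace(chain$joint_cs[[j]], poses[[chain$bones[j]]],
                poses[[chain$bones[j + 1]]]))
  names(out) <- paste0("joint_", seq_len(chain$n_joints))
  out
}

#' Joint rotation deltas at peak cranial elevation
#'
#' For each joint, the change in dorsoventral (z) rotation between the
#' strike's baseline frame and the frame of peak cranial elevation -
#' rotations relative to their initial value, read off at peak elevation.
#' Joints with a pose gap at either frame are NA.
#'
#' @param strike a `strike_recording`.
#' @param traces per-joint traces from [joint_traces()].
#' @param elevation an `elevation_trace` (for the peak frame).
#' @param baseline_frame frame the deltas are measured from (default 1, the
#'   start of the recording).
#' @param ... passed to [strike_pose_sequences()] when traces/elevation are
#'   NULL.
#' @return named numeric vector of per-joint rot_z deltas, deg.
#' @export
joint_rotation_deltas_at_peak <- function(strike, traces = NULL,
                                          elevation = NULL,
                                          baseline_frame = 1, ...) {
  if (is.null(traces) || is.null(elevation)) {
    poses <- strike_pose_sequences(strike, ...)
    if (is.null(traces)) traces <- joint_traces(strike, poses)
    if (is.null(elevation)) elevation <- elevation_trace(strike, poses)
  }
  pk <- attr(elevation, "peak_frame")
  vapply(traces, function(tr) tr$rot_z[pk] - tr$rot_z[baseline_frame],
         numeric(1))
}

#' Vertebral-column curvature profile
#'
#' Dorsoventral (y) translations, in the frame of an ACS attached to the
#' caudal-most vertebra, of a virtual landmark on each bone: the
#' craniovertebral joint for the neurocranium (position 0) and the centrum
#' centroid for each vertebra (positions 1..N). Baseline-subtracted values
#' (relative to `baseline_frame`) describe how the column has bent since
#' the start of the strike; the caudal-most entry is zero by construction.
#'
#' @param strike a `strike_recording`.
#' @param frame frame at which the profile is taken (e.g. peak elevation).
#' @param poses pose sequences (see [strike_pose_sequences()]).
#' @param baseline_frame frame subtracted in `dy_mm` (default 1).
#' @param ... passed to [strike_pose_sequences()] when `poses` is NULL.
#' @return a `curvature_profile` data.frame: position (0 = neurocranium),
#'   bone, y_mm (raw), dy_mm (baseline-subtracted).
#' @export
curvature_profile <- function(strike, frame, poses = NULL,
                              baseline_frame = 1, ...) {
  if (is.null(poses)) poses <- strike_pose_sequences(strike, ...)
  chain <- strike$chain
  M <- length(chain$bones)
  ref_acs <- acs(chain$bones[M])   # caudal-most vertebra, centrum centroid
  ref_seq <- poses[[chain$bones[M]]]
  y <- dy <- rep(NA_real_, M)
  for (k in seq_len(M)) {
    lm <- if (k == 1) {
      # neurocranium: virtual landmark at the craniovertebral joint
      transform_points(invert_rigid(chain$ref_pose[[1]]),
                       chain$pivot_world_ref[[1]])
    } else c(0, 0, 0)
    traj <- virtual_landmark_trajectory(lm, poses[[chain$bones[k]]],
                                        ref_acs, ref_seq)
    y[k] <- traj[frame, 2]
    dy[k] <- traj[frame, 2] - traj[baseline_frame, 2]
  }
  structure(data.frame(position = 0:(M - 1), bone = chain$bones,
                       y_mm = y, dy_mm = dy),
            class = c("curvature_profile", "data.frame"),
            frame = frame, baseline_frame = baseline_frame)
}

#' Per-centrum dorsoventral translation
#'
#' First difference of the (baseline-subtracted) curvature profile along
#' the column: position k's value minus its caudal neighbour's, so a single
#' bending joint shows up as a step at that position. Position 0 compares
#' the neurocranium with vertebra 1.
#'
#' @param profile a [curvature_profile()].
#' @return data.frame: position, bone, delta_y_mm.
#' @export
per_centrum_translation <- function(profile) {
  stopifnot(nrow(profile) >= 2)
  n <- nrow(profile)
  data.frame(position = profile$position[-n], bone = profile$bone[-n],
             delta_y_mm = profile$dy_mm[-n] - profile$dy_mm[-1])
}

#' Cohort summary of a per-strike quantity
#'
#' Mean, standard error of the mean (sample SD / sqrt(n)), maximum and n
#' over strikes. NAs are dropped. With a single strike the s.e. is reported
#' as 0 and flagged.
#'
#' @param values numeric vector, one value per strike.
#' @return data.frame: mean, se, max, n, single_strike.
#' @export
cohort_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to summarize")
  data.frame(mean = mean(values),
             se = if (n > 1) stats::sd(values) / sqrt(n) else 0,
             max = max(values), n = n, single_strike = n == 1)
}

#' Mean elevation trace across strikes
#'
#' Aligns the strikes' elevation traces (at motion onset by default, or at
#' peak) and averages elevation at every time step; steps where fewer than
#' two strikes overlap are dropped.
#'
#' @param traces list of `elevation_trace` objects from included strikes.
#' @param align "onset" or "peak".
#' @return data.frame: step (frames from alignment point), mean_deg,
#'   n_strikes.
#' @export
mean_trace <- function(traces, align = c("onset", "peak")) {
  align <- match.arg(align)
  stopifnot(length(traces) >= 2)
  anchors <- vapply(traces, function(tr) {
    a <- attr(tr, if (align == "onset") "onset_frame" else "peak_frame")
    if (is.na(a)) 1L else as.integer(a)
  }, integer(1))
  steps <- lapply(seq_along(traces), function(i)
    traces[[i]]$frame - anchors[i])
  rng <- range(unlist(steps))
  grid <- rng[1]:rng[2]
  acc <- matrix(NA_real_, length(grid), length(traces))
  for (i in seq_along(traces)) {
    acc[match(steps[[i]], grid), i] <- traces[[i]]$elevation_deg
  }
  n <- rowSums(!is.na(acc))
  keep <- n >= 2
  data.frame(step = grid[keep],
             mean_deg = rowMeans(acc[keep, , drop = FALSE], na.rm = TRUE),
             n_strikes = n[keep])
}

#' Full strike analysis
#'
#' Runs the complete pipeline on one strike: pose fitting from markers
#' (optionally filtered), elevation trace, inclusion decision, per-joint
#' traces, joint deltas at peak elevation, and the curvature profile at
#' peak.
#'
#' @param strike a `strike_recording`.
#' @param use_markers fit poses from markers (TRUE) or use stored poses.
#' @param filter_cutoff low-pass cutoff Hz, NULL to disable, or "chain" for
#'   the chain's default.
#' @param threshold_deg inclusion threshold, deg.
#' @return list: elevation (trace), included, joint_traces, deltas_deg,
#'   curvature (profile at peak), per_centrum, poses.
#' @export
analyze_strike <- function(strike, use_markers = TRUE, filter_cutoff = NULL,
                           threshold_deg = 5) {
  if (identical(filter_cutoff, "chain"))
    filter_cutoff <- strike$chain$filter_cutoff
  poses <- strike_pose_sequences(strike, use_markers = use_markers,
                                 filter_cutoff = filter_cutoff)
  elev <- elevation_trace(strike, poses)
  traces <- joint_traces(strike, poses)
  deltas <- joint_rotation_deltas_at_peak(strike, traces, elev)
  prof <- curvature_profile(strike, attr(elev, "peak_frame"), poses)
  list(elevation = elev,
       included = include_strike(elev, threshold_deg),
       joint_traces = traces,
       deltas_deg = deltas,
       curvature = prof,
       per_centrum = per_centrum_translation(prof),
       poses = poses)
}
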