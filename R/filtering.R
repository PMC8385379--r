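# Zero-phase low-pass filtering of rigid pose sequences.

# Forward-backward Butterworth with symmetric (even) reflection padding at
# both ends (padlen samples). Applying the filter in both directions squares
# its magnitude response and cancels its phase. Even reflection is chosen
# over the odd reflection used by scipy/MATLAB filtfilt: odd reflection pins
# the endpoint values, leaving endpoint noise completely unsmoothed, which
# matters here because baselines and peaks are read near recording edges;
# even reflection smooths the edges and is unbiased when the signal is
# near-flat there (pre-strike rest, post-strike hold).
butter_filtfilt <- function(x, cutoff, frame_rate, order = 2,
                            padlen = 3 * (2 * order + 1)) {
  ba <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  n <- length(x)
  # the recursion starts from zero state, so remove the mean first: constant
  # signals then pass through exactly, and the map stays linear
  m <- mean(x)
  x <- x - m
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- x[(padlen + 1):2]
    post <- x[(n - 1):(n - padlen)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  y <- signal::filter(ba, xp)
  y <- rev(signal::filter(ba, rev(y)))
  y <- as.numeric(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y + m
}

# Squared (zero-phase) magnitude response of the digital Butterworth at
# frequency f: bilinear transform prewarps the analog prototype.
#' Zero-phase Butterworth gain
#'
#' Expected amplitude gain of [lowpass_filter_poses()] for a sinusoid at
#' frequency `f`, accounting for the forward-backward (squared-magnitude)
#' application and the bilinear-transform frequency warping of the digital
#' filter.
#'
#' @param f signal frequency, Hz.
#' @param cutoff filter cutoff, Hz.
#' @param frame_rate sampling rate, Hz.
#' @param order single-pass filter order (default 2).
#' @return gain in (0, 1].
#' @export
butter_zero_phase_gain <- function(f, cutoff, frame_rate, order = 2) {
  r <- tan(pi * f / frame_rate) / tan(pi * cutoff / frame_rate)
  1 / (1 + r^(2 * order))
}

#' Low-pass filter a pose sequence
#'
#' Filters the six pose parameters - three translations plus the rotation
#' as a unit quaternion with sign continuity enforced - with a zero-phase
#' Butterworth (the given order applied forward and backward, so the
#' effective order is doubled and the output has no time lag). Filtered
#' quaternions are renormalized and the rotation blocks re-orthonormalized.
#' Gaps split the sequence into independently filtered segments; segments
#' shorter than 3x the filter length are passed through unfiltered with a
#' warning.
#'
#' @param seq a `pose_sequence`.
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param frame_rate sampling rate, Hz; defaults to the sequence's own.
#' @param order single-pass Butterworth order (default 2).
#' @return a filtered `pose_sequence` with the same frames and gaps.
#' @export
lowpass_filter_poses <- function(seq, cutoff, frame_rate = seq$frame_rate,
                                 order = 2) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (is.null(frame_rate))
    stop("frame_rate must be given (sequence stores none)")
  if (cutoff <= 0 || cutoff >= frame_rate / 2)
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                 cutoff, frame_rate / 2))
  present <- pose_present(seq)
  nf <- n_frames(seq)
  out <- seq$transforms
  min_len <- 3 * (2 * order + 1)
  # contiguous runs of present frames
  runs <- rle(present)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    if (length(idx) < min_len) {
      if (length(idx) < nf)
        warning(sprintf("segment of %d frames too short to filter; passed through",
                        length(idx)))
      else if (length(idx) < min_len)
        warning("sequence too short to filter; passed through")
      next
    }
    tr <- t(seq$transforms[1:3, 4, idx])
    quat <- matrix(0, length(idx), 4)
    for (j in seq_along(idx)) {
      q <- mat2quat(seq$transforms[1:3, 1:3, idx[j]])
      if (j > 1 && sum(q * quat[j - 1, ]) < 0) q <- -q
      quat[j, ] <- q
    }
    ftr <- apply(tr, 2, butter_filtfilt, cutoff = cutoff,
                 frame_rate = frame_rate, order = order)
    fq <- apply(quat, 2, butter_filtfilt, cutoff = cutoff,
                frame_rate = frame_rate, order = order)
    for (j in seq_along(idx)) {
      R <- orthonormalize_rotation(quat2mat(fq[j, ]))
      out[, , idx[j]] <- homogeneous(R, ftr[j, ])
    }
  }
  pose_sequence(out, seq$bone_name, frame_rate = frame_rate,
                rmse = seq$rmse, validate = FALSE)
}
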