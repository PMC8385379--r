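#' Rigid pose sequences
#'
#' A `pose_sequence` stores per-frame 4x4 homogeneous rigid transforms for
#' one bone, mapping bone-reference coordinates into the world (mm). Frames
#' without a valid pose (tracking gaps) are NA.
#'
#' @param transforms a 4 x 4 x frames array, or a list of 4x4 matrices
#'   (NULL/NA entries become gap frames).
#' @param bone_name name of the bone the sequence animates.
#' @param frame_rate optional recording rate, Hz.
#' @param rmse optional per-frame fit RMSE, mm.
#' @param validate check rigidity of every non-gap frame (orthonormal
#'   rotation, det +1, tolerance `tol`).
#' @param tol rigidity tolerance.
#' @return an object of class `pose_sequence`.
#' @export
pose_sequence <- function(transforms, bone_name, frame_rate = NULL,
                          rmse = NULL, validate = TRUE, tol = 1e-6) {
  if (is.list(transforms)) {
    nf <- length(transforms)
    arr <- array(NA_real_, c(4, 4, nf))
    for (i in seq_len(nf)) {
      Ti <- transforms[[i]]
      if (!is.null(Ti) && !anyNA(Ti)) arr[, , i] <- Ti
    }
    transforms <- arr
  }
  stopifnot(length(dim(transforms)) == 3, all(dim(transforms)[1:2] == c(4, 4)))
  if (validate) {
    for (i in seq_len(dim(transforms)[3])) {
      T <- transforms[, , i]
      if (anyNA(T)) next
      R <- T[1:3, 1:3]
      if (max(abs(crossprod(R) - diag(3))) > tol)
        stop(sprintf("non-rigid rotation at frame %d: ||R'R - I|| > %g", i, tol))
      if (abs(det(R) - 1) > tol)
        stop(sprintf("improper rotation (det != +1) at frame %d", i))
      if (max(abs(T[4, ] - c(0, 0, 0, 1))) > tol)
        stop(sprintf("last row not (0,0,0,1) at frame %d", i))
    }
  }
  structure(
    list(transforms = transforms, bone_name = bone_name,
         frame_rate = frame_rate, rmse = rmse),
    class = "pose_sequence"
  )
}

#' @export
n_frames.pose_sequence <- function(x) dim(x$transforms)[3]

#' @export
print.pose_sequence <- function(x, ...) {
  gaps <- sum(is.na(x$transforms[1, 1, ]))
  cat(sprintf("<pose_sequence> bone '%s', %d frames (%d gaps)%s\n",
              x$bone_name, n_frames(x), gaps,
              if (!is.null(x$frame_rate)) sprintf(" @ %g Hz", x$frame_rate) else ""))
  invisible(x)
}

#' Frames with a valid (non-gap) pose
#' @param seq a `pose_sequence`.
#' @return logical vector over frames.
#' @export
pose_present <- function(seq) !is.na(seq$transforms[1, 1, ])

#' Extract one frame's transform
#' @param seq a `pose_sequence`.
#' @param frame 1-based frame index.
#' @return 4x4 matrix, or NULL for a gap frame.
#' @export
pose_at <- function(seq, frame) {
  T <- seq$transforms[, , frame]
  if (anyNA(T)) NULL else T
}

#' Read a pose-matrix CSV
#'
#' One row per frame, 16 numeric columns holding the 4x4 world-from-bone
#' transform in row-major order (XROMM MayaTools rigid-body convention).
#' Blank rows or rows of NAs are gap frames. Rotation blocks are validated
#' for rigidity on read.
#'
#' @param path CSV file path.
#' @param bone_name bone name for the sequence; defaults to a stored
#'   `# bone=` comment, then to the file's base name.
#' @param frame_rate optional rate, Hz; overrides a stored
#'   `# frame_rate=` comment.
#' @return a `pose_sequence`.
#' @export
read_pose_csv <- function(path, bone_name = NULL, frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  stored_rate <- NULL
  stored_bone <- NULL
  meta <- grep("^#", lines, value = TRUE)
  for (cm in meta) {
    m <- regmatches(cm, regexec("frame_rate\\s*=\\s*([0-9.eE+-]+)", cm))[[1]]
    if (length(m) == 2) stored_rate <- as.numeric(m[2])
    b <- regmatches(cm, regexec("bone\\s*=\\s*(\\S+)", cm))[[1]]
    if (length(b) == 2) stored_bone <- b[2]
  }
  body <- lines[!grepl("^#", lines)]
  # optional header of non-numeric names
  if (length(body) && !grepl("^[-0-9.eE+ ,naNA]*$", body[1])) body <- body[-1]
  body <- body[nzchar(trimws(body))]
  nf <- length(body)
  arr <- array(NA_real_, c(4, 4, nf))
  for (i in seq_len(nf)) {
    vals <- suppressWarnings(as.numeric(strsplit(body[i], ",")[[1]]))
    if (length(vals) != 16)
      stop(sprintf("pose CSV row %d has %d values, expected 16", i, length(vals)))
    if (all(is.na(vals))) next
    arr[, , i] <- matrix(vals, 4, 4, byrow = TRUE)
  }
  if (is.null(bone_name))
    bone_name <- stored_bone %||% tools::file_path_sans_ext(basename(path))
  fr <- if (!is.null(frame_rate)) frame_rate else stored_rate
  pose_sequence(arr, bone_name, frame_rate = fr, validate = TRUE)
}

#' Write a pose-matrix CSV
#'
#' Inverse of [read_pose_csv()]: 16 row-major values per frame at 12
#' significant digits, gap frames as blank rows, convention and frame rate
#' recorded in leading comments.
#'
#' @param seq a `pose_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bone=%s world-from-bone 4x4 row-major, mm", seq$bone_name), con)
  if (!is.null(seq$frame_rate))
    writeLines(sprintf("# frame_rate=%.12g", seq$frame_rate), con)
  for (i in seq_len(n_frames(seq))) {
    T <- seq$transforms[, , i]
    if (anyNA(T)) {
      writeLines(paste(rep("NA", 16), collapse = ","), con)
    } else {
      writeLines(paste(sprintf("%.12g", as.vector(t(T))), collapse = ","), con)
    }
  }
  invisible(path)
}
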