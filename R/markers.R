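#' Marker trajectory sets
#'
#' A `marker_trajectory_set` holds time-stamped 3D positions (mm, world
#' frame) of named markers, the raw input of the kinematics pipeline.
#' Positions are stored as a frames x markers x 3 array; missing
#' observations (markers lost from tracking in some frames) are NA.
#'
#' @param positions numeric array, frames x markers x 3 (xyz), mm. A
#'   frames x 3 matrix is accepted for a single marker.
#' @param frame_rate recording rate, Hz (> 0).
#' @param markers character vector of unique marker names; defaults to the
#'   array's dimnames.
#' @return an object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(positions, frame_rate, markers = NULL) {
  if (length(dim(positions)) == 2 && ncol(positions) == 3)
    positions <- array(positions, c(nrow(positions), 1, 3))
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  if (is.null(markers)) markers <- dimnames(positions)[[2]]
  if (is.null(markers)) markers <- paste0("m", seq_len(dim(positions)[2]))
  if (anyDuplicated(markers))
    stop("marker names must be unique")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  if (any(is.infinite(positions)))
    stop("marker positions must be finite or NA")
  dimnames(positions) <- list(NULL, markers, c("X", "Y", "Z"))
  structure(
    list(positions = positions, frame_rate = frame_rate, markers = markers),
    class = "marker_trajectory_set"
  )
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf("<marker_trajectory_set> %d frames x %d markers @ %g Hz\n",
              n_frames(x), length(x$markers), x$frame_rate))
  cat("  markers:", paste(utils::head(x$markers, 8), collapse = ", "),
      if (length(x$markers) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of frames in a trajectory or pose sequence
#' @param x a `marker_trajectory_set` or `pose_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.marker_trajectory_set <- function(x) dim(x$positions)[1]

#' Extract one frame's marker positions
#'
#' @param set a `marker_trajectory_set`.
#' @param frame 1-based frame index.
#' @param drop_missing drop markers with any NA coordinate at this frame.
#' @return named markers x 3 matrix.
#' @export
marker_frame <- function(set, frame, drop_missing = TRUE) {
  pts <- set$positions[frame, , , drop = FALSE]
  pts <- matrix(pts, ncol = 3, dimnames = list(set$markers, c("X", "Y", "Z")))
  if (drop_missing) pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  pts
}

#' Read marker trajectories from a wide-format CSV
#'
#' Dialect: one row per frame, columns `<marker>_X`, `<marker>_Y`,
#' `<marker>_Z` (mm), mandatory header, comma separated, empty cells for
#' missing observations. An optional leading comment line
#' `# frame_rate=<Hz>` carries the frame rate; otherwise pass `frame_rate`.
#'
#' @param path CSV file path.
#' @param frame_rate frame rate in Hz; overrides any value stored in the
#'   file header comment. Required if the file stores none.
#' @return a `marker_trajectory_set`.
#' @export
read_marker_csv <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  stored_rate <- NULL
  skip <- 0
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("frame_rate\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) stored_rate <- as.numeric(m[2])
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        colClasses = "numeric", na.strings = c("", "NA", "NaN"))
  cols <- names(df)
  if (!all(grepl("_(X|Y|Z)$", cols))) {
    bad <- cols[!grepl("_(X|Y|Z)$", cols)]
    stop("malformed marker CSV header, column(s) without _X/_Y/_Z suffix: ",
         paste(bad, collapse = ", "))
  }
  base <- sub("_(X|Y|Z)$", "", cols)
  markers <- unique(base)
  for (mk in markers) {
    need <- paste0(mk, "_", c("X", "Y", "Z"))
    if (!all(need %in% cols))
      stop("malformed marker CSV header, incomplete xyz triplet for marker: ", mk)
  }
  nf <- nrow(df)
  pos <- array(NA_real_, c(nf, length(markers), 3))
  for (j in seq_along(markers)) {
    for (k in 1:3) {
      pos[, j, k] <- df[[paste0(markers[j], "_", c("X", "Y", "Z")[k])]]
    }
  }
  fr <- if (!is.null(frame_rate)) frame_rate else stored_rate
  if (is.null(fr))
    stop("frame rate not stored in file; supply frame_rate=")
  marker_trajectory_set(pos, fr, markers)
}

#' Write marker trajectories to wide-format CSV
#'
#' Inverse of [read_marker_csv()]; numbers are written with 12 significant
#' digits so a round trip is value-identical, and the frame rate is stored
#' in a leading `# frame_rate=` comment. Missing observations become empty
#' cells.
#'
#' @param set a `marker_trajectory_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(set, path) {
  stopifnot(inherits(set, "marker_trajectory_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%.12g", set$frame_rate), con)
  header <- as.vector(t(outer(set$markers, c("_X", "_Y", "_Z"), paste0)))
  writeLines(paste(header, collapse = ","), con)
  nf <- n_frames(set)
  if (nf > 0) {
    flat <- matrix(NA_real_, nf, length(header))
    for (j in seq_along(set$markers)) {
      flat[, (j - 1) * 3 + 1:3] <- set$positions[, j, ]
    }
    txt <- apply(flat, 1, function(r) {
      s <- sprintf("%.12g", r)
      s[is.na(r)] <- ""
      paste(s, collapse = ",")
    })
    writeLines(txt, con)
  }
  invisible(path)
}
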