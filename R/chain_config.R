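#' Chain configuration
#'
#' A `chain_config` declares the skeletal chain being analysed: the ordered
#' bone list (neurocranium first, then vertebra 1..N running caudally), the
#' joints connecting consecutive bones (joint 1 = craniovertebral), marker
#' assignments, the body-plane marker set, the recording frame rate, the
#' low-pass cutoff, and the cranial-elevation inclusion threshold.
#'
#' @name chain_config
NULL

species_preset_defaults <- function(name) {
  switch(name,
    trout = list(n_vertebrae = 25, frame_rate = 500, filter_cutoff = 60),
    frogfish = list(n_vertebrae = 18, frame_rate = 1000, filter_cutoff = 100),
    stop("unknown species preset: ", name)
  )
}

new_chain_config <- function(bones, frame_rate, filter_cutoff,
                             elevation_threshold = 5,
                             markers = NULL, rotoscoped = character(),
                             body_plane_markers = character(),
                             species = NA_character_) {
  if (length(bones) < 2) stop("chain needs at least two bones")
  if (anyDuplicated(bones)) stop("bone names must be unique")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (!is.null(filter_cutoff) && filter_cutoff >= frame_rate / 2)
    stop(sprintf("filter cutoff %g Hz is at or above Nyquist (%g Hz)",
                 filter_cutoff, frame_rate / 2))
  if (!all(rotoscoped %in% bones))
    stop("rotoscoped flag references unknown bone(s): ",
         paste(setdiff(rotoscoped, bones), collapse = ", "))
  if (!is.null(markers) && !all(names(markers) %in% bones))
    stop("marker assignment references unknown bone(s): ",
         paste(setdiff(names(markers), bones), collapse = ", "))
  joints <- data.frame(
    joint = seq_len(length(bones) - 1),
    cranial_bone = bones[-length(bones)],
    caudal_bone = bones[-1],
    stringsAsFactors = FALSE
  )
  structure(
    list(bones = bones, joints = joints, frame_rate = frame_rate,
         filter_cutoff = filter_cutoff,
         elevation_threshold = elevation_threshold,
         markers = markers, rotoscoped = rotoscoped,
         body_plane_markers = body_plane_markers, species = species),
    class = "chain_config"
  )
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("<chain_config> %d bones, %d joints @ %g Hz (cutoff %s Hz, threshold %g deg)\n",
              length(x$bones), nrow(x$joints), x$frame_rate,
              if (is.null(x$filter_cutoff)) "off" else format(x$filter_cutoff),
              x$elevation_threshold))
  invisible(x)
}

#' Load a chain configuration from YAML
#'
#' Recognised keys: `species` (a preset name, `trout` or `frogfish`,
#' supplying bone count, frame rate and filter cutoff defaults), `bones`
#' (explicit ordered list, neurocranium first), `n_vertebrae`, `frame_rate`
#' (Hz), `filter_cutoff` (Hz, must be below Nyquist),
#' `elevation_threshold` (deg, default 5), `markers` (map of bone to marker
#' names), `rotoscoped` (bones whose poses are supplied externally rather
#' than fitted from markers), `body_plane_markers`. Joints are enumerated
#' automatically between consecutive bones; joint 1 is the craniovertebral
#' joint.
#'
#' @param path YAML file path.
#' @return a `chain_config`.
#' @export
load_chain_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  species <- cfg$species %||% NA_character_
  defaults <- if (!is.na(species)) species_preset_defaults(species) else list()
  n_vert <- cfg$n_vertebrae %||% defaults$n_vertebrae
  bones <- cfg$bones
  if (is.null(bones)) {
    if (is.null(n_vert)) stop("config must give either 'bones' or 'n_vertebrae'/'species'")
    bones <- c("neurocranium", sprintf("vertebra_%02d", seq_len(n_vert)))
  }
  frame_rate <- cfg$frame_rate %||% defaults$frame_rate
  if (is.null(frame_rate)) stop("config must give 'frame_rate' (or a species preset)")
  cutoff <- cfg$filter_cutoff %||% defaults$filter_cutoff
  new_chain_config(
    bones = as.character(bones),
    frame_rate = as.numeric(frame_rate),
    filter_cutoff = if (is.null(cutoff)) NULL else as.numeric(cutoff),
    elevation_threshold = as.numeric(cfg$elevation_threshold %||% 5),
    markers = cfg$markers,
    rotoscoped = as.character(cfg$rotoscoped %||% character()),
    body_plane_markers = as.character(cfg$body_plane_markers %||% character()),
    species = species
  )
}

#' Write a chain configuration to YAML
#'
#' @param config a `chain_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_config <- function(config, path) {
  stopifnot(inherits(config, "chain_config"))
  out <- list(
    species = if (is.na(config$species)) NULL else config$species,
    bones = config$bones,
    frame_rate = config$frame_rate,
    filter_cutoff = config$filter_cutoff,
    elevation_threshold = config$elevation_threshold,
    markers = config$markers,
    rotoscoped = if (length(config$rotoscoped)) config$rotoscoped else NULL,
    body_plane_markers = if (length(config$body_plane_markers)) config$body_plane_markers else NULL
  )
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
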