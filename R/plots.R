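#' Plot cranial-elevation traces of a cohort
#'
#' Per-strike traces in grey with the cohort mean overlaid in black,
#' aligned at motion onset.
#'
#' @param traces list of `elevation_trace` objects (included strikes).
#' @param frame_rate frame rate, Hz (for the time axis).
#' @return a ggplot object.
#' @export
plot_elevation_traces <- function(traces, frame_rate) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_elevation_traces requires ggplot2")
  onsets <- vapply(traces, function(tr) {
    a <- attr(tr, "onset_frame"); if (is.na(a)) 1L else as.integer(a)
  }, integer(1))
  df <- do.call(rbind, lapply(seq_along(traces), function(i)
    data.frame(strike = i,
               t_ms = (traces[[i]]$frame - onsets[i]) / frame_rate * 1000,
               elevation_deg = traces[[i]]$elevation_deg)))
  m <- mean_trace(traces, align = "onset")
  m$t_ms <- m$step / frame_rate * 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$elevation_deg,
                                   group = .data$strike)) +
    ggplot2::geom_line(colour = "grey65") +
    ggplot2::geom_line(data = m,
                       ggplot2::aes(x = .data$t_ms, y = .data$mean_deg),
                       inherit.aes = FALSE, colour = "black", linewidth = 1) +
    ggplot2::labs(x = "time from onset (ms)", y = "cranial elevation (deg)") +
    ggplot2::theme_classic()
}

#' Plot a vertebral-column curvature profile
#'
#' Baseline-subtracted dorsoventral translations along the column (position
#' 0 = neurocranium) at the profiled frame.
#'
#' @param profile a [curvature_profile()].
#' @return a ggplot object.
#' @export
plot_curvature_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_curvature_profile requires ggplot2")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$dy_mm)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "position along column (0 = neurocranium)",
                  y = "dorsoventral translation (mm)") +
    ggplot2::theme_classic()
}
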