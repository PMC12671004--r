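# ggplot2 visualizations.

#' Plot a comodulogram
#'
#' Tile plot of coupling strength over the frequency grid; non-significant
#' cells (after cluster correction) can be blanked, mirroring the common
#' presentation of cluster-corrected comodulograms.
#'
#' @param object a [comodulogram()] result.
#' @param blank_nonsignificant if `TRUE` (default), cells outside surviving
#'   clusters are drawn as `NA`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pcfc_comodulogram <- function(object, blank_nonsignificant = TRUE,
                                       ...) {
  df <- tibble::as_tibble(object)
  if (blank_nonsignificant) {
    df$value[!df$significant] <- NA_real_
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_hz, y = .data$amp_hz,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Phase frequency (Hz)",
                  y = "Amplitude frequency (Hz)",
                  fill = attr(object, "kind"),
                  title = sprintf("%s comodulogram", attr(object, "kind")))
}

#' Plot paired signals
#'
#' @param object a `pcfc_signals` tibble.
#' @param max_seconds plot at most this many seconds (default 3).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pcfc_signals <- function(object, max_seconds = 3, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$time_s <= max_seconds, ]
  long <- tidyr::pivot_longer(df, c("x", "y"), names_to = "channel",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL)
}

#' Plot a sensitivity sweep
#'
#' Detection and false-alarm rates with binomial confidence ribbons as a
#' function of the swept variable.
#'
#' @param object a [run_sweep()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pcfc_sweep <- function(object, ...) {
  sw <- attr(object, "sweep")
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(value = df$value, rate = df$detection_rate,
                   lo = df$detection_ci_lo, hi = df$detection_ci_hi,
                   series = "detection (dataset 2)"),
    tibble::tibble(value = df$value, rate = df$false_alarm_rate,
                   lo = df$false_alarm_ci_lo, hi = df$false_alarm_ci_hi,
                   series = "false alarm (dataset 1)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$rate,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = sw$variable, y = "Rate", colour = NULL, fill = NULL)
}

#' Plot a DTF spectrum
#'
#' @param object a [dtf()] or [dtf_significance()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pcfc_dtf <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$direction <- paste(df$from, "→", df$to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$dtf2,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized DTF²",
                  colour = NULL)
}

#' @rdname autoplot.pcfc_dtf
#' @export
autoplot.pcfc_dtf_significance <- autoplot.pcfc_dtf
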