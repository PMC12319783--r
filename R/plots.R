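#' Plot per-condition mean traces
#'
#' Line-plus-ribbon plot of `condition_mean()` output. Simulated accumulator
#' traces are conventionally sign-inverted at presentation time to match the
#' negative-going EEG convention; set `invert = TRUE` for that.
#'
#' @param cm tibble from `condition_mean()`
#' @param invert flip the sign of mean and ribbon (plotting convention only;
#'   all computation stays on the natural sign)
#' @return a ggplot object
#' @export
plot_condition_means <- function(cm, invert = FALSE) {
  s <- if (invert) -1 else 1
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$time, y = s * .data$mean,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = s * .data$mean - .data$se,
                                      ymax = s * .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Time relative to event (s)",
                  y = if (invert) "Amplitude (inverted)" else "Amplitude",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epoch_set <- function(object, ...) {
  plot_condition_means(condition_mean(object), ...)
}

#' @export
autoplot.tf_power <- function(object, trials = NULL, ...) {
  rows <- trials %||% seq_len(dim(object$power)[1])
  avg <- apply(object$power[rows, , , drop = FALSE], c(2, 3), mean)
  df <- tibble::tibble(
    freq = rep(object$freqs, each = length(object$time)),
    time = rep(object$time, length(object$freqs)),
    power = as.vector(t(avg)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)", fill = "Power") +
    ggplot2::theme_minimal()
}

#' Plot a time-frequency contrast map
#'
#' @param map tibble from `tf_condition_map()`
#' @param white_out blank pairs with `p > alpha` (the exploratory-map
#'   convention)
#' @param alpha significance cutoff for the white-out
#' @return a ggplot object
#' @export
plot_tf_map <- function(map, white_out = TRUE, alpha = 0.05) {
  df <- map
  if (white_out) df$estimate[df$p > alpha | is.na(df$p)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$estimate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(na.value = "white") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  fill = "Contrast") +
    ggplot2::theme_minimal()
}
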