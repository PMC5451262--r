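#' Plot methods
#'
#' `autoplot()` methods for the package's main result types: kymograms
#' (time x position raster), FRAP fits (trace with the two-line
#' construction), FLIP fits (trace with trendline and plateau), trajectory
#' sets (lines over the kymogram grid) and experiments (per-replicate
#' jitter with summary bars).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name iftpool-plots
NULL

#' @rdname iftpool-plots
#' @export
autoplot.ift_kymogram <- function(object, ...) {
  df <- tidyr::expand_grid(frame = seq_len(nrow(object)),
                           px = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass(object))
  df$time <- attr(object, "time")[df$frame]
  df$position <- (df$px - 1) * attr(object, "pixel_size")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$time,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (um)", y = "time (s)",
                  fill = "counts",
                  title = sprintf("Kymogram, channel %s", attr(object, "channel"))) +
    ggplot2::theme_minimal()
}

#' @rdname iftpool-plots
#' @export
autoplot.frap_fit <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr[!tr$mask, ],
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$t_bleach, linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity (%)") +
    ggplot2::theme_minimal()
  if (!object$censored) {
    rw <- tr[!tr$mask & tr$time >= object$rise_window[1] &
               tr$time <= object$rise_window[2], ]
    ft <- lm(value ~ time, data = rw)
    p <- p +
      ggplot2::geom_hline(yintercept = object$plateau_level,
                          colour = "red", linetype = 2) +
      ggplot2::geom_abline(intercept = coef(ft)[1], slope = coef(ft)[2],
                           colour = "red", linetype = 2) +
      ggplot2::annotate("point",
                        x = object$t_bleach + object$recovery_time,
                        y = object$plateau_level, colour = "red", size = 2)
  }
  p
}

#' @rdname iftpool-plots
#' @export
autoplot.flip_fit <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr[!tr$mask, ],
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$t_start, linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity (%)") +
    ggplot2::theme_minimal()
  if (object$declined && !is.na(object$plateau_time)) {
    p <- p + ggplot2::geom_hline(yintercept = object$plateau_level,
                                 colour = "red", linetype = 2) +
      ggplot2::geom_vline(xintercept = object$t_start + object$plateau_time,
                          colour = "red", linetype = 2)
  }
  p
}

#' @rdname iftpool-plots
#' @export
autoplot.ift_trajectories <- function(object, ...) {
  seg <- dplyr::mutate(object,
    x0 = .data$origin_position,
    x1 = .data$origin_position + .data$velocity * .data$duration,
    t1 = .data$origin_time + .data$duration)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x0, xend = .data$x1, y = .data$origin_time, yend = .data$t1,
      colour = .data$direction, linewidth = .data$intensity), alpha = 0.8) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (um)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' @rdname iftpool-plots
#' @export
autoplot.ift_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$replicates[, vapply(object$replicates, is.numeric, logical(1))],
    -"replicate", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, na.rm = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s (%s)", object$assay,
                                  paste(object$protein, collapse = "+"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
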