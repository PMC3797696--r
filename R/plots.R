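#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a log2 ratio track
#'
#' Per-position log2 ratio with optional focal calls overlaid and the
#' calling thresholds drawn as dashed lines.
#'
#' @param object A `ratio_track` from [log2_ratio_track()].
#' @param calls Optional call tibble from [call_focal_events()].
#' @param threshold Threshold lines to draw (default 0.4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_track <- function(object, calls = NULL, threshold = 0.4, ...) {
  df <- as_tibble(object[!object$masked, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "position (bp)", y = expression(log[2] ~ ratio)) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::geom_segment(
      data = calls,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   colour = .data$direction),
      linewidth = 1.5, inherit.aes = FALSE) +
      ggplot2::scale_colour_manual(values = c(gain = "#1b9e77", loss = "#d95f02"))
  }
  p
}

#' Plot a lesion support profile
#'
#' Step plot of the number of supporting samples along the chromosome, with
#' CDRs highlighted when supplied.
#'
#' @param object A `support_profile` from [build_support_profile()].
#' @param cdrs Optional CDR tibble from [find_cdrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.support_profile <- function(object, cdrs = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$support)) +
    ggplot2::labs(x = "position (bp)", y = "supporting samples") +
    ggplot2::theme_minimal()
  if (!is.null(cdrs) && nrow(cdrs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = cdrs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = .data$support),
      fill = "#d95f02", alpha = 0.3, inherit.aes = FALSE)
  }
  p
}

#' Plot per-diagnosis lesion frequencies
#'
#' Bar chart of the fraction of counting units carrying a lesion per
#' diagnosis (the totals row is dropped).
#'
#' @param object A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$diagnosis != "total", ]
  df$diagnosis <- factor(df$diagnosis, levels = df$diagnosis)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diagnosis, y = .data$frequency_pct)) +
    ggplot2::geom_col(fill = "grey20") +
    ggplot2::labs(x = NULL, y = "% with lesion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
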