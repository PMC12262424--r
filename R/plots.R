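# ggplot2 visualizations for scan results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an archaic-specific k-mer window count track
#'
#' @param track A `window_count_track`.
#' @param threshold Optional calibrated count cutoff to draw.
#' @return A ggplot.
#' @export
plot_window_counts <- function(track, threshold = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = (start + end) / 2,
                                           y = count)) +
    ggplot2::geom_step(color = "grey30") +
    ggplot2::labs(x = "position (bp)", y = "archaic-specific k-mers / window")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' @export
autoplot.tmrca_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = window, y = factor(tmrca),
                                   fill = posterior)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "window", y = "TMRCA (generations)",
                  fill = "posterior")
}

#' @export
autoplot.introgression_scan <- function(object, ...) {
  segs <- object$segments
  ggplot2::ggplot(segs,
                  ggplot2::aes(xmin = start, xmax = end,
                               ymin = as.integer(factor(hap)) - 0.4,
                               ymax = as.integer(factor(hap)) + 0.4,
                               fill = origin)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(segs$hap)),
      labels = sort(unique(segs$hap))) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "origin")
}

#' @export
autoplot.identity_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (query_start + query_end) / 2,
                               y = (target_start + target_end) / 2,
                               color = identity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "query position (bp)", y = "target position (bp)",
                  color = "% identity")
}

#' Plot a PBS segment scan
#'
#' @param scan Output of [segment_scan()], optionally with `p_pbs`.
#' @param alpha Significance level to highlight (on `p_pbs` if present).
#' @return A ggplot.
#' @export
plot_scan <- function(scan, alpha = 0.05) {
  scan <- as_tibble(scan)
  scan$signif <- if ("p_pbs" %in% names(scan)) scan$p_pbs < alpha else FALSE
  ggplot2::ggplot(scan, ggplot2::aes(x = (start + end) / 2, y = pbs,
                                     color = signif)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "position (bp)", y = "PBS")
}
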