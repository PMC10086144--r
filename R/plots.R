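#' Plot a differential-editing result
#'
#' Volcano-style view: change in editing efficiency (delta) against
#' -log10 adjusted p, with significant sites highlighted and labelled.
#'
#' @param object A `diff_editing` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_editing
#' @export
autoplot.diff_editing <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, !is.na(.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(
      data = dplyr::filter(df, .data$significant),
      ggplot2::aes(label = .data$site_id),
      vjust = -0.6, size = 2.8, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "change in editing efficiency (B - A)",
                  y = expression(-log[10]~adjusted~italic(p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot the per-site editing-efficiency profile of one or more samples
#'
#' @param estimates Output of [quantify_all()] (rows from several samples may
#'   be bound together).
#' @return A ggplot object.
#' @export
plot_editing_profile <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = factor(.data$site_id,
                                          levels = unique(.data$site_id)),
                               y = .data$efficiency,
                               colour = .data$sample_id,
                               group = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "editing efficiency", colour = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a chromatogram trace
#'
#' Draws the four channel intensities with basecall positions marked,
#' optionally restricted to a scan window.
#'
#' @param object A [sanger_trace()].
#' @param from,to Scan window (defaults to the whole trace).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sanger_trace
#' @export
autoplot.sanger_trace <- function(object, from = 0, to = object$length - 1, ...) {
  df <- tibble::as_tibble(object$channels)
  df$scan <- seq_len(object$length) - 1L
  df <- tidyr::pivot_longer(df, c("A", "C", "G", "T"),
                            names_to = "channel", values_to = "intensity")
  df <- dplyr::filter(df, .data$scan >= from, .data$scan <= to)
  bc <- dplyr::filter(object$basecalls, .data$scan >= from, .data$scan <= to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scan, y = .data$intensity,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = bc, ggplot2::aes(xintercept = .data$scan),
                        linetype = 3, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(A = "forestgreen", C = "blue",
                                            G = "black", T = "red")) +
    ggplot2::labs(y = "intensity") +
    ggplot2::theme_minimal()
}

#' Volcano plot of an SDEG result
#'
#' @param object An `sdeg_result` from [sdeg_call()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdeg_result
#' @export
autoplot.sdeg_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = expression(log[2]~fold~change),
                  y = expression(-log[10]~FDR)) +
    ggplot2::theme_minimal()
}
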