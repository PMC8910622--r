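#' Confusion-matrix heat map
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot: truth on the y axis, prediction on the x axis, tile
#'   fill and label by count.
#' @export
autoplot.stage_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(sleep_stages())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted stage", y = "True stage", fill = "Epochs") +
    ggplot2::theme_minimal()
}

#' Hypnogram comparison plot
#'
#' Step traces of the true and predicted stage sequences over a window of
#' epochs, the usual visual check of a staging run.
#'
#' @param truth,estimate Stage vectors of equal length.
#' @param window Number of leading epochs to show (default 100).
#' @return A ggplot with one panel per trace.
#' @export
plot_hypnogram <- function(truth, estimate, window = 100) {
  n <- min(window, length(truth))
  df <- tibble(
    epoch = rep(seq_len(n), 2),
    series = rep(c("expert", "model"), each = n),
    stage = c(as.character(truth[seq_len(n)]),
              as.character(estimate[seq_len(n)]))
  )
  # deeper sleep plotted lower, REM between W and N1 as on clinical charts
  depth <- c(W = 4, REM = 3, N1 = 2, N2 = 1, N3 = 0)
  df$level <- depth[df$stage]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~series, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = unname(depth),
                                labels = names(depth)) +
    ggplot2::labs(x = "Epoch (30 s)", y = NULL) +
    ggplot2::theme_minimal()
}
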