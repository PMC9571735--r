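#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the trial distribution of a model comparison
#'
#' Violin-and-box plot of per-trial balanced accuracy by model, by default
#' for the test (prediction) phase — the view used to compare how the four
#' algorithms generalize across repeated paired splits.
#'
#' @param object A `pod_comparison`.
#' @param phase `"test"` (default) or `"train"`.
#' @param metric Metric column to plot (`"bacc"`, `"sens"` or `"spec"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pod_comparison <- function(object, phase = "test", metric = "bacc", ...) {
  ph <- phase
  d <- dplyr::filter(object$trials, .data$phase == ph)
  d$model <- factor(d$model, levels = object$models)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(
      x = NULL, y = metric,
      title = sprintf("%s across %d paired splits (%s set)", metric,
                      object$n_trials, phase)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fast-and-frugal tree
#'
#' Simple structural diagram: one level per cue, exits drawn left
#' (negative) and right (positive), the final node branching both ways.
#'
#' @param object An [fftree()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fftree <- function(object, ...) {
  nodes <- object$nodes
  d <- nrow(nodes)
  rule <- sprintf("%s %s %g", nodes$cue, nodes$direction, nodes$threshold)
  node_df <- tibble::tibble(x = 0, y = -(seq_len(d)), label = rule)
  exit_df <- dplyr::bind_rows(
    tibble::tibble(  # one exit per non-final node
      from = seq_len(d - 1),
      x = ifelse(nodes$exit[-d] == "positive", 1, -1),
      label = ifelse(nodes$exit[-d] == "positive", "POD risk", "no risk")
    ),
    tibble::tibble(from = c(d, d), x = c(1, -1),
                   label = c("POD risk", "no risk"))
  )
  exit_df$y <- -(exit_df$from) - 0.45
  segs <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = -(seq_len(d - 1)), xend = 0,
                   yend = -(seq_len(d - 1)) - 1),
    tibble::tibble(x = 0, y = -exit_df$from, xend = exit_df$x,
                   yend = exit_df$y)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_label(data = node_df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label)) +
    ggplot2::geom_label(data = exit_df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label),
                        fill = "grey92", size = 3) +
    ggplot2::xlim(-1.6, 1.6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (!is.na(object$algorithm)) object$algorithm)
}

#' @importFrom rlang .data
NULL
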