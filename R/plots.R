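# ggplot2 views of the pipeline's result types.

#' Plot a mobility trace
#'
#' Raw and (when present) median-filtered mobility values over time, with
#' the reduced-trace mean and the detected twitch onset overlaid when a
#' twitch index is supplied.
#'
#' @param object A [mobility_trace()].
#' @param twitch_index Optional 0-based crossing index to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mobility_trace <- function(object, twitch_index = NULL, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$minutes)) +
    ggplot2::geom_line(aes(y = .data$raw), colour = "grey60") +
    ggplot2::labs(x = "time (min)", y = "mean |frame difference| (AU)",
                  title = "Embryo mobility trace")
  if (!all(is.na(d$filtered)))
    p <- p + ggplot2::geom_line(aes(y = .data$filtered), colour = "steelblue")
  if (!is.null(twitch_index) && !is.na(twitch_index))
    p <- p + ggplot2::geom_vline(
      xintercept = twitch_index * object$frame_interval,
      linetype = "dashed", colour = "firebrick")
  p
}

#' Plot a population fluorescence profile
#'
#' Mean background-normalized embryo intensity (I_SBR) with a +/- SEM
#' ribbon over time.
#'
#' @param object A [population_mean_profile()] tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fluo_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$minutes, y = .data$mean_sbr)) +
    ggplot2::geom_ribbon(aes(ymin = .data$mean_sbr - .data$sem_sbr,
                             ymax = .data$mean_sbr + .data$sem_sbr),
                         fill = "seagreen", alpha = 0.25) +
    ggplot2::geom_line(colour = "seagreen4") +
    ggplot2::labs(x = "time (min)", y = expression(I[SBR]~"(AU)"),
                  title = "Population mean embryo fluorescence")
}

#' Plot a phenotype clustergram
#'
#' Heatmap of the per-phenotype z-scored cohort means, rows and columns in
#' dendrogram order.
#'
#' @param object A [build_clustergram()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.clustergram <- function(object, ...) {
  d <- tidy(object)
  d$phenotype <- factor(d$phenotype, levels = rev(object$row_order))
  d$condition <- factor(d$condition, levels = object$col_order)
  ggplot(d, aes(x = .data$condition, y = .data$phenotype, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score",
                  title = "Normalized cohort phenotypes")
}
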