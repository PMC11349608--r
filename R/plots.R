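#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a V-J usage matrix
#'
#' @param object A `trb_usage` object.
#' @param ... Unused.
#' @return A ggplot tile heatmap (V rows, J columns, fill = frequency).
#' @export
autoplot.trb_usage <- function(object, ...) {
  d <- tidy_usage(object)
  ggplot2::ggplot(d, ggplot2::aes(x = j_call, y = v_call, fill = frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "J segment", y = "V segment", fill = "Usage",
                  title = object$sample_id) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' CDR3 length histogram with its Gaussian fit
#'
#' @param object A `trb_lengthdist` object.
#' @param ... Unused.
#' @export
autoplot.trb_lengthdist <- function(object, ...) {
  h <- object$histogram
  fit <- tibble(
    len = h$len,
    prop = {
      p <- pnorm(h$len + 0.5, object$mean, object$sd) -
        pnorm(h$len - 0.5, object$mean, object$sd)
      p / sum(p)
    }
  )
  ggplot2::ggplot(h, ggplot2::aes(x = len, y = prop)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::labs(x = "CDR3 length (aa)", y = "Proportion") +
    ggplot2::theme_minimal()
}

#' Group dot plot of a per-sample diversity metric
#'
#' One dot per sample, mean +/- SD bars per group - the standard panel for
#' comparing diversity indices between tumor and normal tissue.
#'
#' @param profiles Per-sample profile tibble with a `group` column.
#' @param metric Profile column to plot.
#' @return A ggplot.
#' @export
plot_diversity <- function(profiles, metric = "shannon_entropy") {
  if (!metric %in% names(profiles)) abort(paste0("unknown metric: ", metric))
  d <- tibble(group = profiles$group, value = profiles[[metric]])
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = value)) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "errorbar", width = 0.2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}
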