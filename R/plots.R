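# ggplot2 views of the containers and of fitted objects.

#' Plot a time-series set
#'
#' @param object a [ts_set()].
#' @param series optional character vector of series ids to show (default:
#'   first 4).
#' @param ... unused.
#' @return a ggplot: channels over time, one facet per channel, coloured by
#'   series.
#' @method autoplot ts_set
#' @export
autoplot.ts_set <- function(object, series = NULL, ...) {
  df <- as_tibble.ts_set(object)
  keep <- series %||% utils::head(unique(df$series_id), 4L)
  df <- df[df$series_id %in% keep, ]
  long <- tidyr::pivot_longer(df, -c("series_id", "time_index"),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_index * object$dt,
                                     .data$value,
                                     colour = .data$series_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time", y = NULL, colour = "series") +
    ggplot2::theme_minimal()
}

#' Plot a fit
#'
#' @param object an `idras_fit`.
#' @param type `"trace"` for the variance-ratio trace over outer
#'   iterations, `"predictions"` for the learned combination and its
#'   one-step prediction over time.
#' @param series series ids for the prediction view (default: first 2).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot idras_fit
#' @export
autoplot.idras_fit <- function(object, type = c("trace", "predictions"),
                               series = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- tidyr::pivot_longer(object$trace, c("ratio_pre", "ratio_post"),
                              names_to = "stage", values_to = "ratio")
    tr$stage <- ifelse(tr$stage == "ratio_pre", "after shuffle reset",
                       "after combination step")
    return(
      ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$ratio,
                                       colour = .data$stage)) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = 1, linetype = 2,
                            colour = "grey50") +
        ggplot2::labs(x = "outer iteration",
                      y = "filtering-error variance ratio",
                      colour = NULL) +
        ggplot2::theme_minimal()
    )
  }
  p <- object$predictions
  keep <- series %||% utils::head(unique(p$series_id), 2L)
  p <- p[p$series_id %in% keep, ]
  long <- tidyr::pivot_longer(p, c("c", "c_hat"), names_to = "which",
                              values_to = "value")
  long$which <- ifelse(long$which == "c", "learned c",
                       "one-step prediction")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_index, .data$value,
                                     colour = .data$which)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~series_id, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "sample index", y = "standardised combination",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
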