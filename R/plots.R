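#' Plot population counts
#'
#' Bar chart of per-class percentages over total nuclei.
#'
#' @param object a `population_counts` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot population_counts
#' @export
autoplot.population_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of total cells (DAPI+)") +
    ggplot2::theme_classic()
}

#' Plot a Kaplan-Meier fit
#'
#' Step survival curves with censor tick marks, one colour per group.
#'
#' @param object a `km_fit` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  td <- tidy.km_fit(object)
  if (!"group" %in% names(td)) td$group <- "all"
  # prepend S(0) = 1 per group for a complete step curve
  head0 <- td |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, estimate = 1, n_censor = 0)
  curve <- dplyr::bind_rows(head0, td)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$estimate,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(td, .data$n_censor > 0),
                        shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival fraction",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot per-gut values by group
#'
#' One dot per intestine, the convention used for all population and
#' intensity panels; group means are overlaid as crossbars.
#'
#' @param data data frame with one row per gut.
#' @param value,group column names.
#' @return a ggplot.
#' @export
plot_per_gut <- function(data, value = "value", group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_classic()
}
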