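# ggplot2 views of the result objects.

#' Quadrant plot of CNV signal vs correlation
#'
#' @param object A `cnv_result` with signal/correlation computed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_result
#' @export
autoplot.cnv_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation,
                                        y = .data$signal)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$malignant),
                        size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "CNV correlation", y = "CNV signal",
                  colour = "malignant")
  if (!is.null(object$thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = object$thresholds[["signal_min"]],
                          linetype = 2) +
      ggplot2::geom_vline(xintercept = object$thresholds[["corr_min"]],
                          linetype = 2)
  }
  p
}

#' Temporal pattern centroids along pseudotime
#'
#' @param object A `trend_set` with patterns assigned.
#' @param ... Unused.
#' @return A ggplot of the z-scored pattern centroids per bin.
#' @method autoplot trend_set
#' @export
autoplot.trend_set <- function(object, ...) {
  stopifnot(!is.null(object$pattern))
  cen <- lapply(sort(unique(object$pattern)), function(p) {
    genes <- names(object$pattern)[object$pattern == p]
    tibble::tibble(pattern = factor(p), bin = seq_len(object$n_bins),
                   centroid = colMeans(
                     object$trends[genes, , drop = FALSE]))
  })
  ggplot2::ggplot(dplyr::bind_rows(cen),
                  ggplot2::aes(x = .data$bin, y = .data$centroid,
                               colour = .data$pattern)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime bin", y = "z-scored expression",
                  colour = "pattern")
}

#' Kaplan-Meier step curves
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot of the survival curves (with the log-rank p in the
#'   subtitle when available).
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- object$curve |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x[, c("time", "surv")])) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "disease-free survival",
                  colour = NULL)
  if (!is.null(object$test)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-rank p = %.3g", object$test$p))
  }
  p
}

#' Stacked per-sample cluster composition
#'
#' @param comp Composition tibble from [composition()].
#' @return A ggplot stacked bar chart.
#' @export
plot_composition <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$sample,
                                     y = .data$proportion,
                                     fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "cluster")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance
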