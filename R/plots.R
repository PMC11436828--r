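#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_point autoplot
#'   scale_fill_manual labs facet_wrap theme_minimal coord_equal
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Plot hard parcel labels on a 2-D voxel grid
#'
#' @param space a [voxel_space()] with 2-D coordinates.
#' @param labels integer parcel labels, length P.
#' @param colors optional `K x 3` RGB matrix (e.g. from
#'   [colormap_from_similarity()]).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_parcellation <- function(space, labels, colors = NULL, title = NULL) {
  stopifnot(ncol(space$coords) >= 2)
  df <- tibble::tibble(
    x = space$coords[, 1], y = space$coords[, 2],
    parcel = factor(labels)
  )
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$parcel)) +
    geom_tile() +
    coord_equal() +
    theme_minimal() +
    labs(title = title, x = NULL, y = NULL)
  if (!is.null(colors)) {
    pal <- grDevices::rgb(colors[, 1], colors[, 2], colors[, 3])
    names(pal) <- as.character(seq_len(nrow(colors)))
    p <- p + scale_fill_manual(values = pal)
  }
  p
}

#' @rdname plot_parcellation
#' @param object an [individual_parcellation()].
#' @param ... passed on (expects `space`).
#' @export
autoplot.individual_parcellation <- function(object, ..., space,
                                             colors = NULL) {
  plot_parcellation(space, object$hard_labels, colors,
                    title = paste0(object$source, " parcellation"))
}

#' EM log-likelihood trace of a fused model
#'
#' @param object a [fused_model].
#' @param ... unused.
#' @return A ggplot object showing the winning start's trace.
#' @export
autoplot.fused_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$fit_info$loglik),
                       loglik = object$fit_info$loglik)
  ggplot(df, aes(x = .data$iteration, y = .data$loglik)) +
    geom_line() +
    geom_point(size = 0.8) +
    theme_minimal() +
    labs(y = "marginal log-likelihood",
         title = sprintf("EM trace (K = %d)", object$arrangement$K))
}

#' Plot a data-amount curve
#'
#' Visualizes the precision-mapping trade-off computed by
#' [data_amount_curve()]: per-source mean metric against minutes of
#' localizer data.
#'
#' @param curve tibble from [data_amount_curve()].
#' @param metric `"dcbc"` (higher better) or `"pred_error"` (lower
#'   better).
#' @return A ggplot object.
#' @export
plot_data_amount_curve <- function(curve, metric = c("dcbc", "pred_error")) {
  metric <- match.arg(metric)
  df <- curve |>
    dplyr::group_by(.data$minutes, .data$source) |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot(df, aes(x = .data$minutes, y = .data$value,
                 colour = .data$source)) +
    geom_line() +
    geom_point() +
    theme_minimal() +
    labs(y = metric, x = "minutes of localizer data")
}
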