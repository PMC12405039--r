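# ggplot2 views of the main result objects.

#' Scatter plot of a brain embedding
#'
#' @param object A `brain_embedding`.
#' @param dims Which two dimensions to plot (default 1 and 2).
#' @param meta Optional tibble (or `brain_cohort`) with `state_id` and
#'   `diagnosis`; points are coloured by diagnosis when given.
#' @param label Draw state-id labels (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brain_embedding <- function(object, dims = c(1, 2), meta = NULL,
                                     label = TRUE, ...) {
  df <- tidy(object)
  xcol <- paste0("dim_", dims[1]); ycol <- paste0("dim_", dims[2])
  if (inherits(meta, "brain_cohort")) meta <- meta$states
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta[, c("state_id", "diagnosis")], by = "state_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::labs(x = sprintf("MDS dimension %d", dims[1]),
                  y = sprintf("MDS dimension %d", dims[2]),
                  title = "Brain space") +
    ggplot2::theme_minimal()
  p <- if (is.null(meta)) p + ggplot2::geom_point(size = 2) else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$diagnosis), size = 2)
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$state_id),
                                vjust = -0.8, size = 2.8, show.legend = FALSE)
  }
  p
}

#' Heat map of a K-operator
#'
#' Diverging palette centred at the identity (0 for additive K, 1 for
#' multiplicative): blue = weakened links, red = strengthened.
#'
#' @param object A `k_operator`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.k_operator <- function(object, ...) {
  df <- as.data.frame(as.table(object$values))
  names(df) <- c("roi_i", "roi_j", "value")
  mid <- if (object$mode == "additive") 0 else 1
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_j, .data$roi_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = mid, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  na.value = "grey80") +
    ggplot2::labs(title = sprintf("K-operator: %s → %s (%s)",
                                  object$source_state_id,
                                  object$target_state_id, object$mode),
                  x = NULL, y = NULL, fill = "Δ connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Bar chart of the top ROIs per axis
#'
#' @param object An `axis_attribution` (from [attribute_axes()]).
#' @param ... Unused.
#' @return A ggplot faceted by axis.
#' @export
autoplot.axis_attribution <- function(object, ...) {
  df <- object$top_rois
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$roi, abs(.data$impact)),
                                   .data$impact)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$impact > 0), show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~axis, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "impact on axis",
                  title = "Most influential ROIs per MDS axis") +
    ggplot2::theme_minimal()
}
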