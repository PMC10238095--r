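#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_col geom_tile labs facet_wrap scale_fill_gradient2
NULL

#' @export
ggplot2::autoplot

#' Consensus CDF and delta-area plots
#'
#' `autoplot()` on a `consensus_result` draws the per-k consensus CDFs;
#' `plot_delta_area()` the relative area-gain curve used to pick k.
#'
#' @param object,result A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- purrr::imap_dfr(object$cdf, function(tab, k) {
    dplyr::mutate(tab, k = factor(k, levels = names(object$cdf)))
  })
  ggplot(df, aes(x = .data$support, y = .data$cdf, colour = .data$k)) +
    geom_step() +
    labs(x = "consensus index", y = "CDF",
         title = "Consensus CDF by cluster number")
}

#' @rdname autoplot.consensus_result
#' @export
plot_delta_area <- function(result) {
  df <- glance(result)
  ggplot(df, aes(x = .data$k, y = .data$delta_area)) +
    geom_line() + geom_point(aes(colour = .data$chosen), size = 2) +
    labs(x = "k", y = "relative change in CDF area",
         title = "Delta-area curve")
}

#' Cross-validation error curve of a shrunken-centroid model
#'
#' @param object An `nsc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nsc_model <- function(object, ...) {
  df <- tibble::tibble(threshold = object$grid, cv_error = object$cv_error)
  ggplot(df, aes(x = .data$threshold, y = .data$cv_error)) +
    geom_line() + geom_point() +
    geom_point(data = df[df$threshold == object$delta, ],
               colour = "red", size = 3) +
    labs(x = "shrinkage threshold", y = "CV error",
         title = "Threshold selection (red = selected)")
}

#' Signature-score heatmap
#'
#' Tile heatmap of a (typically z-scored) signatures x samples score
#' matrix, with samples optionally ordered by subtype label.
#'
#' @param scores Signatures x samples matrix.
#' @param labels Optional subtype label per sample used to order columns.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(scores, labels = NULL) {
  ord <- if (is.null(labels)) seq_len(ncol(scores)) else order(labels)
  df <- tibble::as_tibble(scores[, ord, drop = FALSE], rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "sample", values_to = "score") |>
    dplyr::mutate(sample = factor(.data$sample, levels = colnames(scores)[ord]))
  ggplot(df, aes(x = .data$sample, y = .data$signature, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    labs(x = "samples", y = NULL)
}

#' Region tissue-composition bar chart
#'
#' @param composition Tibble from [region_abundances()] (one or more
#'   regions row-bound together).
#' @return A ggplot object.
#' @export
plot_region_composition <- function(composition) {
  ggplot(composition, aes(x = .data$label, y = .data$fraction)) +
    geom_col() + facet_wrap(~region) +
    labs(x = "tissue class", y = "area fraction")
}

#' Exclusive-intersection bar chart (UpSet-style counts)
#'
#' @param counts Tibble from [upset_counts()].
#' @return A ggplot object.
#' @export
plot_upset_counts <- function(counts) {
  ggplot(counts, aes(x = stats::reorder(.data$combination, -.data$count),
                     y = .data$count)) +
    geom_col() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    labs(x = "exclusive membership", y = "features")
}
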