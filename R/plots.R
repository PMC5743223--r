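#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: the t-SNE map (optionally coloured by track or cluster), the
#' lineage co-ancestry MDS, the per-subset bias composition, and the
#' dosage-correlation heat map.
#'
#' @param object a result object.
#' @param colour optional vector (length N) used to colour points.
#' @param ... unused.
#' @return A ggplot object.
#' @name clonepotency-plots
NULL

#' @rdname clonepotency-plots
#' @export
autoplot.clone_tsne <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 0.8, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                            size = 0.8, alpha = 0.8) +
      ggplot2::labs(colour = NULL)
  }
}

#' @rdname clonepotency-plots
#' @export
autoplot.clone_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' @rdname clonepotency-plots
#' @export
autoplot.potency_composition <- function(object, ...) {
  df <- object$composition |>
    dplyr::mutate(lineage = factor(.data$lineage, levels = lineage_names()),
                  subset = factor(.data$subset, levels = subset_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset, y = .data$percent,
                                   fill = .data$lineage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of productive clones",
                  fill = "bias group") +
    ggplot2::theme_minimal()
}

#' @rdname clonepotency-plots
#' @export
autoplot.dosage_correlation <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      gate = factor(.data$gate,
                    levels = rownames(object$r)[object$row_order]),
      lineage = factor(.data$lineage,
                       levels = colnames(object$r)[object$col_order]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lineage, y = .data$gate,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @rdname clonepotency-plots
#' @export
autoplot.bias_yield_association <- function(object, ...) {
  ggplot2::ggplot(object$histograms,
                  ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~statistic, ncol = 1) +
    ggplot2::labs(x = "ratio bin", y = "fraction of non-unipotent clones") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
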