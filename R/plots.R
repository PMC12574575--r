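#' Boxplot of estimated cell-type proportions
#'
#' @param proportions Sample-by-cell-type proportion matrix.
#' @param groups Optional named group vector to color by.
#' @return A ggplot object.
#' @export
plot_proportions <- function(proportions, groups = NULL) {
  df <- tibble::as_tibble(proportions, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "cell_type",
                        values_to = "proportion")
  if (!is.null(groups)) {
    df$group <- unname(groups[df$sample])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type,
                                     y = .data$proportion,
                                     fill = .data$group)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(x = NULL, y = "Estimated proportion") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type,
                                     y = .data$proportion)) +
      ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey80") +
      ggplot2::labs(x = NULL, y = "Estimated proportion") +
      ggplot2::theme_minimal()
  }
}

#' Stacked bars of methylation-state proportions per cell type
#'
#' Shows, for each cell type, the proportion of functional pairs whose CpG
#' was hypo-, hyper- or dual-methylated in the high-AL group.
#'
#' @param pairs An `"al_pairs"` tibble.
#' @return A ggplot object.
#' @export
plot_state_proportions <- function(pairs) {
  df <- tibble::as_tibble(pairs) |>
    dplyr::count(.data$cell_type, .data$state) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$prop,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(hypo = "#4daf4a", hyper = "#377eb8",
                                          dual = "#e41a1c")) +
    ggplot2::labs(x = NULL, y = "Proportion of functional pairs",
                  fill = "State") +
    ggplot2::theme_minimal()
}

#' Stacked bars of regulation direction per cell type
#'
#' @param directions An `"al_directions"` tibble; inconsistent genes are
#'   excluded.
#' @return A ggplot object.
#' @export
plot_direction_proportions <- function(directions) {
  df <- tibble::as_tibble(directions) |>
    dplyr::filter(.data$direction %in% c("up", "down")) |>
    dplyr::count(.data$cell_type, .data$direction) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$prop,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#e41a1c", down = "#00bfc4")) +
    ggplot2::labs(x = NULL, y = "Proportion of DMGs", fill = "Direction") +
    ggplot2::theme_minimal()
}

#' Dot plot of over-representation results
#'
#' Significant gene sets plotted by gene ratio (overlap over query size),
#' dot size proportional to the overlap count and color to the adjusted
#' p-value; faceted by stratum when the result is stratified.
#'
#' @param object An `"al_enrichment"` tibble.
#' @param top Show at most this many sets per stratum (by adjusted p).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.al_enrichment <- function(object, top = 15, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("no enrichment results"))
  }
  stratified <- all(c("cell_type", "direction") %in% names(df))
  if (stratified) {
    df$stratum <- paste(df$cell_type, df$direction)
    df <- df |>
      dplyr::group_by(.data$stratum) |>
      dplyr::slice_min(.data$p_adj, n = top, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    df <- dplyr::slice_min(df, .data$p_adj, n = top, with_ties = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio,
                                        y = stats::reorder(.data$set,
                                                           -.data$p_adj),
                                        size = .data$k,
                                        color = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "#e41a1c", high = "#377eb8") +
    ggplot2::labs(x = "Gene ratio (k/n)", y = NULL, size = "Overlap",
                  color = "Adjusted p") +
    ggplot2::theme_minimal()
  if (stratified) p <- p + ggplot2::facet_wrap(~stratum, scales = "free_y")
  p
}
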