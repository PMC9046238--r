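#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cluster stability
#'
#' Bars of mean recall per cluster, filled by the unstable flag, with the
#' wrong-dominant fraction annotated.
#'
#' @param object a `stability_summary`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot stability_summary
#' @export
autoplot.stability_summary <- function(object, ...) {
  df <- object$per_cluster
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$mean_recall,
                                   fill = .data$unstable)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%% wrong", 100 * .data$frac_wrong_dominant)),
      vjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#4477AA",
                                          `TRUE` = "#CC3311")) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = NULL, y = "mean recall per cell",
                  fill = "unstable") +
    ggplot2::theme_minimal()
}

#' Plot dataset-mixing entropy per cluster
#'
#' @param object an `entropy_report`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot entropy_report
#' @export
autoplot.entropy_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$cluster, y = .data$entropy_norm)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "normalised mixing entropy H / ln(D)") +
    ggplot2::theme_minimal()
}

#' Plot top markers per cluster
#'
#' @param object a `marker_table`.
#' @param top_n markers shown per cluster.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot marker_table
#' @export
autoplot.marker_table <- function(object, top_n = 10, ...) {
  df <- dplyr::filter(object, .data$rank <= top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_log2fc,
                                   y = stats::reorder(.data$gene,
                                                      .data$avg_log2fc))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pct_in,
                                     colour = -log10(.data$p_adj + 1e-300))) +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = "average log2 fold change", y = NULL,
                  colour = "-log10 adj. p", size = "fraction expressing") +
    ggplot2::theme_minimal()
}

#' Plot conservation enrichment scores
#'
#' @param object an `es_result`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot es_result
#' @export
autoplot.es_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cluster, y = .data$es)) +
    ggplot2::geom_col(fill = "#228833") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "conservation enrichment score") +
    ggplot2::theme_minimal()
}

#' Plot a cluster tree
#'
#' Simple segment layout: leaves are spread along x in tree order, internal
#' nodes sit at the mean of their children, and depth maps to y.
#'
#' @param tree a `cluster_tree`.
#' @return a ggplot.
#' @export
plot_cluster_tree <- function(tree) {
  td <- tidy(tree)
  leaves <- td$name[td$is_leaf]
  xpos <- setNames(rep(NA_real_, nrow(td)), td$name)
  xpos[leaves] <- seq_along(leaves)
  for (lv in sort(unique(td$level), decreasing = TRUE)) {
    for (nm in td$name[td$level == lv & !td$is_leaf]) {
      kids <- td$name[!is.na(td$parent) & td$parent == nm]
      xpos[nm] <- mean(xpos[kids])
    }
  }
  td$x <- xpos[td$name]
  td$y <- -td$level
  seg <- td[!is.na(td$parent), ]
  seg$xend <- xpos[seg$parent]
  seg$yend <- -(seg$level - 1)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cells),
                        colour = "#4477AA") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1,
                       size = 3) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = NULL, y = "level", size = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Heatmap of cluster-mean expression
#'
#' @param means clusters x genes matrix from [cluster_mean_expression()].
#' @return a ggplot.
#' @export
plot_cluster_means <- function(means) {
  df <- tibble::as_tibble(as.data.frame(means), rownames = "cluster") %>%
    tidyr::pivot_longer(-"cluster", names_to = "gene", values_to = "mean")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$cluster,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean norm.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
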