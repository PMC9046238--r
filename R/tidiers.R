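#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster tree into one row per node
#'
#' @param x a `cluster_tree`.
#' @param ... ignored.
#' @return tibble `name`, `parent`, `level`, `n_cells`, `is_leaf`,
#'   `termination_reason`.
#' @method tidy cluster_tree
#' @export
tidy.cluster_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, parent) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = node$name, parent = parent, level = node$level,
      n_cells = length(node$cell_ids), is_leaf = node$is_leaf,
      termination_reason = node$termination_reason
    )
    for (ch in node$children) walk(ch, node$name)
  }
  walk(x$root, NA_character_)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.cluster_tree
#' @method glance cluster_tree
#' @export
glance.cluster_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_cells = length(x$root$cell_ids),
    n_nodes = nrow(td),
    n_leaves = sum(td$is_leaf),
    depth = max(td$level)
  )
}

#' Tidy a stability summary (per-cluster view)
#'
#' @param x a `stability_summary`.
#' @param ... ignored.
#' @method tidy stability_summary
#' @export
tidy.stability_summary <- function(x, ...) {
  x$per_cluster
}

#' @rdname tidy.stability_summary
#' @method glance stability_summary
#' @export
glance.stability_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$per_cell),
    n_clusters = nrow(x$per_cluster),
    n_unstable = sum(x$per_cluster$unstable),
    mean_recall = mean(x$per_cell$recall),
    n_repeats = x$n_repeats
  )
}

#' Tidy an entropy report
#'
#' @param x an `entropy_report`.
#' @param ... ignored.
#' @method tidy entropy_report
#' @export
tidy.entropy_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.entropy_report
#' @method glance entropy_report
#' @export
glance.entropy_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$summary),
    n_datasets = x$n_datasets,
    mean_entropy = mean(x$summary$entropy),
    mean_entropy_norm = mean(x$summary$entropy_norm)
  )
}
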