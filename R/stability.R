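# ---- bootstrap random-forest cluster stability -------------------------

#' Pairwise bootstrap random-forest classification of two clusters
#'
#' The core resampling step of the stability analysis. For one unordered
#' cluster pair, each repeat (a) splits each cluster's cells into `n_folds`
#' near-equal folds, (b) for every fold, computes differentially expressed
#' genes between the two clusters on the training 80% only (Wilcoxon
#' rank-sum, normal approximation), selects the top `genes_per_cluster`
#' genes per cluster by average log2 fold change (at most
#' `2 * genes_per_cluster` features), trains a random forest on the training
#' cells and classifies the held-out fold — so every cell of the pair is
#' classified exactly once per repeat and `n_repeats` times in total.
#'
#' @param ds a normalized [expression_dataset()].
#' @param part partition tibble `cell_id`/`label`.
#' @param pair character vector of two cluster names.
#' @param genes gene universe for the within-bootstrap DE (typically
#'   [select_mvg()] output; default all genes).
#' @param n_folds folds per repeat (both clusters must have at least this
#'   many cells).
#' @param n_repeats bootstrap repeats.
#' @param genes_per_cluster DEGs kept per cluster as classifier features.
#' @param num_trees random-forest trees.
#' @param seed integer seed (fold splits and forests are derived from it).
#' @return `bootstrap_records` tibble: `cell_id`, `cluster_a`, `cluster_b`,
#'   `run`, `predicted`, `truth`, with `(|a| + |b|) * n_repeats` rows.
#' @export
pairwise_bootstrap <- function(ds, part, pair, genes = NULL,
                               n_folds = 5, n_repeats = 10,
                               genes_per_cluster = 10, num_trees = 500,
                               seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"), length(pair) == 2)
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  part <- as_partition(part)
  pair <- sort(as.character(pair))
  cells_a <- part$cell_id[part$label == pair[1]]
  cells_b <- part$cell_id[part$label == pair[2]]
  if (length(cells_a) < n_folds || length(cells_b) < n_folds) {
    stop("Both clusters need at least n_folds = ", n_folds,
         " cells; merge or skip smaller clusters.")
  }
  if (is.null(genes)) genes <- gene_ids(ds)
  if (length(genes) < genes_per_cluster) {
    warning("Fewer than ", genes_per_cluster,
            " genes available; using all ", length(genes), ".")
  }
  cells <- c(cells_a, cells_b)
  truth <- c(rep(pair[1], length(cells_a)), rep(pair[2], length(cells_b)))
  x <- as.matrix(ds$norm[genes, cells, drop = FALSE])
  ia <- seq_along(cells_a)
  ib <- length(cells_a) + seq_along(cells_b)

  records <- vector("list", n_repeats * n_folds)
  ri <- 0L
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + 7919L * rep_i)
    fold_a <- sample(rep_len(seq_len(n_folds), length(ia)))
    fold_b <- sample(rep_len(seq_len(n_folds), length(ib)))
    fold <- integer(length(cells))
    fold[ia] <- fold_a
    fold[ib] <- fold_b
    for (f in seq_len(n_folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      feats <- bootstrap_features(x, intersect(train, ia),
                                  intersect(train, ib), genes_per_cluster)
      df_train <- data.frame(t(x[feats, train, drop = FALSE]),
                             check.names = FALSE)
      df_train$.cls <- factor(truth[train], levels = pair)
      rf <- ranger::ranger(
        dependent.variable.name = ".cls", data = df_train,
        num.trees = num_trees, num.threads = 1,
        seed = seed + 104729L * rep_i + f
      )
      df_test <- data.frame(t(x[feats, test, drop = FALSE]),
                            check.names = FALSE)
      pred <- as.character(predict(rf, df_test,
                                   num.threads = 1)$predictions)
      ri <- ri + 1L
      records[[ri]] <- tibble::tibble(
        cell_id = cells[test], cluster_a = pair[1], cluster_b = pair[2],
        run = rep_i, predicted = pred, truth = truth[test]
      )
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("bootstrap_records", class(out))
  out
}

# top DEGs per direction on training cells only (no test leakage)
bootstrap_features <- function(x, train_a, train_b, genes_per_cluster) {
  xa <- x[, train_a, drop = FALSE]
  xb <- x[, train_b, drop = FALSE]
  fc <- log2((rowMeans(expm1(xa)) + 1) / (rowMeans(expm1(xb)) + 1))
  k <- min(genes_per_cluster, nrow(x))
  up_a <- order(-fc)[seq_len(k)]
  up_b <- order(fc)[seq_len(k)]
  rownames(x)[union(up_a, up_b)]
}

#' Summarise bootstrap records into stability metrics
#'
#' For every cell and cluster pair, the *dominant cluster* is the cluster
#' the cell was assigned to in more than half the runs (a tie yields no
#' dominant). Per cell, *recall* is the fraction of all classifications
#' (over every pair and run) that hit the cell's original cluster, and
#' `n_correct` counts the pairs whose dominant equals the original cluster
#' (at most number of clusters - 1). A cluster is *unstable* when more than
#' `threshold` of its cells have at least one pair whose dominant is not
#' their own cluster — another cluster won more than half the runs, or no
#' cluster reached a majority (the cell was assigned away from home in at
#' least half of them).
#'
#' @param records row-bound [pairwise_bootstrap()] output covering all
#'   unordered cluster pairs of `part`.
#' @param part partition tibble.
#' @param threshold instability threshold on the wrong-dominant cell
#'   fraction.
#' @return a `stability_summary`: list with `per_cell`, `per_cluster` and
#'   `dominant` tibbles plus `threshold` and `n_repeats`.
#' @export
summarize_stability <- function(records, part, threshold = 0.5) {
  part <- as_partition(part)
  labs <- sort(unique(part$label))
  need <- combn(labs, 2)
  have <- unique(records[, c("cluster_a", "cluster_b")])
  for (i in seq_len(ncol(need))) {
    if (!any(have$cluster_a == need[1, i] & have$cluster_b == need[2, i])) {
      stop("Missing bootstrap records for pair (", need[1, i], ", ",
           need[2, i], ").")
    }
  }
  n_repeats <- max(records$run)

  by_pair <- records %>%
    dplyr::group_by(.data$cell_id, .data$cluster_a, .data$cluster_b) %>%
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_correct_runs = sum(.data$predicted == .data$truth),
      n_a = sum(.data$predicted == .data$cluster_a),
      truth = .data$truth[1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      dominant = dplyr::case_when(
        .data$n_a > n_repeats / 2 ~ .data$cluster_a,
        (.data$n_runs - .data$n_a) > n_repeats / 2 ~ .data$cluster_b,
        TRUE ~ "none"
      ),
      # a comparison fails a cell when its dominant is not its own cluster:
      # either another cluster won more than half the runs, or no cluster
      # did (the cell was assigned away from home in at least half of them)
      wrong_dominant = .data$dominant != .data$truth
    )

  per_cell <- by_pair %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(
      cluster = .data$truth[1],
      recall = sum(.data$n_correct_runs) / sum(.data$n_runs),
      n_correct = sum(.data$dominant == .data$truth),
      n_pairs = dplyr::n(),
      any_wrong_dominant = any(.data$wrong_dominant),
      .groups = "drop"
    )

  per_cluster <- per_cell %>%
    dplyr::group_by(cluster = .data$cluster) %>%
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_recall = mean(.data$recall),
      mean_n_correct = mean(.data$n_correct),
      frac_wrong_dominant = mean(.data$any_wrong_dominant),
      .groups = "drop"
    ) %>%
    dplyr::mutate(unstable = .data$frac_wrong_dominant > threshold)

  structure(
    list(per_cell = per_cell, per_cluster = per_cluster,
         dominant = by_pair[, c("cell_id", "cluster_a", "cluster_b",
                                "truth", "dominant", "wrong_dominant")],
         threshold = threshold, n_repeats = n_repeats),
    class = "stability_summary"
  )
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("stability_summary: %d cells, %d clusters (%d unstable), %d repeats\n",
              nrow(x$per_cell), nrow(x$per_cluster),
              sum(x$per_cluster$unstable), x$n_repeats))
  print(x$per_cluster)
  invisible(x)
}

#' Evaluate the stability of a whole partition
#'
#' Convenience wrapper: runs [pairwise_bootstrap()] for every unordered
#' cluster pair and summarises with [summarize_stability()].
#'
#' @inheritParams pairwise_bootstrap
#' @inheritParams summarize_stability
#' @return a `stability_summary` with the raw records attached as
#'   `$records`.
#' @export
evaluate_stability <- function(ds, part, genes = NULL, n_folds = 5,
                               n_repeats = 10, genes_per_cluster = 10,
                               num_trees = 500, threshold = 0.5, seed = 1L) {
  part <- as_partition(part)
  labs <- sort(unique(part$label))
  if (length(labs) < 2) stop("Need at least 2 clusters.")
  pairs <- combn(labs, 2)
  recs <- lapply(seq_len(ncol(pairs)), function(i) {
    pairwise_bootstrap(ds, part, pairs[, i], genes = genes,
                       n_folds = n_folds, n_repeats = n_repeats,
                       genes_per_cluster = genes_per_cluster,
                       num_trees = num_trees,
                       seed = seed + 1863L * i)
  })
  records <- dplyr::bind_rows(recs)
  out <- summarize_stability(records, part, threshold = threshold)
  out$records <- records
  out
}

#' Dissolve unstable clusters and reassign their cells
#'
#' Iteratively removes non-robust clusters: at each iteration the partition
#' is evaluated with the bootstrap procedure and, if any cluster is
#' unstable, the one with the highest wrong-dominant fraction is dissolved.
#' Its cells are reassigned among the remaining clusters by a random forest
#' trained on the remaining clusters' cells, using the union of the top
#' `genes_per_cluster` one-vs-rest DEGs of each remaining cluster as
#' features. Dissolving one cluster at a time keeps a dissolved cluster's
#' nearest sibling available to receive its cells; the loop re-evaluates
#' after each dissolution, up to `max_iter` dissolutions.
#'
#' @inheritParams evaluate_stability
#' @param max_iter maximum dissolutions.
#' @return list with `partition` (tibble; total cell count conserved),
#'   `dissolved` (cluster names, in dissolution order), and `summary` (the
#'   final `stability_summary`, or `NULL` when fewer than 2 clusters
#'   remain).
#' @export
dissolve_and_reassign <- function(ds, part, genes = NULL, n_folds = 5,
                                  n_repeats = 10, genes_per_cluster = 10,
                                  num_trees = 500, threshold = 0.5,
                                  max_iter = 3, seed = 1L) {
  part <- as_partition(part)
  dissolved <- character(0)
  summary <- NULL
  for (iter in seq_len(max_iter)) {
    if (length(unique(part$label)) < 2) break
    summary <- evaluate_stability(ds, part, genes = genes, n_folds = n_folds,
                                  n_repeats = n_repeats,
                                  genes_per_cluster = genes_per_cluster,
                                  num_trees = num_trees,
                                  threshold = threshold,
                                  seed = seed + iter)
    unst <- summary$per_cluster[summary$per_cluster$unstable, ]
    if (nrow(unst) == 0) break
    if (nrow(unst) == nrow(summary$per_cluster)) {
      stop("All clusters are unstable; consider a coarser clustering.")
    }
    victim <- unst$cluster[order(-unst$frac_wrong_dominant, unst$cluster)][1]
    part <- reassign_cells(ds, part, victim, genes = genes,
                           genes_per_cluster = genes_per_cluster,
                           num_trees = num_trees, seed = seed + 31L * iter)
    dissolved <- c(dissolved, victim)
    summary <- NULL
  }
  if (is.null(summary) && length(unique(part$label)) >= 2) {
    summary <- evaluate_stability(ds, part, genes = genes, n_folds = n_folds,
                                  n_repeats = n_repeats,
                                  genes_per_cluster = genes_per_cluster,
                                  num_trees = num_trees,
                                  threshold = threshold,
                                  seed = seed + max_iter + 1L)
  }
  list(partition = part, dissolved = dissolved, summary = summary)
}

# random-forest reassignment of one dissolved cluster's cells
reassign_cells <- function(ds, part, victim, genes = NULL,
                           genes_per_cluster = 10, num_trees = 500,
                           seed = 1L) {
  if (is.null(genes)) genes <- gene_ids(ds)
  keep <- part[part$label != victim, ]
  move <- part$cell_id[part$label == victim]
  labs <- sort(unique(keep$label))
  feats <- character(0)
  for (cl in labs) {
    in_cells <- keep$cell_id[keep$label == cl]
    out_cells <- keep$cell_id[keep$label != cl]
    x <- as.matrix(ds$norm[genes, c(in_cells, out_cells), drop = FALSE])
    feats <- union(feats,
                   bootstrap_features(x, seq_along(in_cells),
                                      length(in_cells) + seq_along(out_cells),
                                      genes_per_cluster)[seq_len(
                                        min(genes_per_cluster, length(genes)))])
  }
  df_train <- data.frame(t(as.matrix(ds$norm[feats, keep$cell_id,
                                             drop = FALSE])),
                         check.names = FALSE)
  df_train$.cls <- factor(keep$label, levels = labs)
  rf <- ranger::ranger(dependent.variable.name = ".cls", data = df_train,
                       num.trees = num_trees, num.threads = 1, seed = seed)
  df_move <- data.frame(t(as.matrix(ds$norm[feats, move, drop = FALSE])),
                        check.names = FALSE)
  pred <- as.character(predict(rf, df_move, num.threads = 1)$predictions)
  dplyr::bind_rows(keep, tibble::tibble(cell_id = move, label = pred)) %>%
    dplyr::arrange(match(.data$cell_id, part$cell_id))
}

#' Dataset-mixing Shannon entropy per cluster
#'
#' For each cluster, `p_d` is the fraction of its cells originating from
#' dataset `d` and the mixing entropy is `H = -Σ p_d ln p_d` (nats, with
#' `0 ln 0 = 0`); the normalised value `H / ln(D)` uses the total number of
#' datasets `D` in the experiment and reaches 1 under perfect mixing.
#'
#' @param part partition tibble.
#' @param cell_meta an [expression_dataset()] or a tibble with `cell_id` and
#'   `dataset_id`.
#' @return an `entropy_report`: list with `proportions` (cluster x dataset
#'   long tibble) and `summary` (`cluster`, `n_cells`, `entropy`,
#'   `entropy_norm`).
#' @export
dataset_entropy <- function(part, cell_meta) {
  part <- as_partition(part)
  if (inherits(cell_meta, "ExpressionDataset")) cell_meta <- cell_meta$cell_meta
  cell_meta <- tibble::as_tibble(cell_meta)
  stopifnot(all(c("cell_id", "dataset_id") %in% names(cell_meta)))
  if (!all(part$cell_id %in% cell_meta$cell_id)) {
    stop("Every cell in the partition needs a dataset_id.")
  }
  df <- dplyr::left_join(part, cell_meta[, c("cell_id", "dataset_id")],
                         by = "cell_id")
  n_datasets <- length(unique(cell_meta$dataset_id))
  props <- df %>%
    dplyr::count(cluster = .data$label, dataset = .data$dataset_id) %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::mutate(p = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  summary <- props %>%
    dplyr::group_by(cluster = .data$cluster) %>%
    dplyr::summarise(
      n_cells = sum(.data$n),
      entropy = -sum(.data$p * log(.data$p)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      entropy_norm = if (n_datasets > 1) .data$entropy / log(n_datasets)
                     else NA_real_
    )
  structure(list(proportions = props, summary = summary,
                 n_datasets = n_datasets),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("entropy_report: %d clusters, %d datasets\n",
              nrow(x$summary), x$n_datasets))
  print(x$summary)
  invisible(x)
}

#' Shannon entropy of a composition
#'
#' @param p vector of proportions (renormalised to sum to 1).
#' @return entropy in nats, with `0 ln 0 = 0`.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}
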