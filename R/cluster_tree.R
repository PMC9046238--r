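#' Default analysis configuration
#'
#' One place for every tunable of the clustering and stability machinery;
#' [read_config()] merges a YAML file over these defaults.
#'
#' @param n_mvg genes used for (re-)embedding at each node.
#' @param n_dims principal axes of the joint embedding.
#' @param k_neighbors kNN graph neighbors.
#' @param snn_cutoff shared-nearest-neighbor Jaccard pruning cutoff.
#' @param highres_resolution Louvain resolution of the high-resolution
#'   reference partition that bounds subclustering from above.
#' @param resolution_grid resolutions swept when splitting a node.
#' @param min_silhouette minimum mean silhouette a candidate sub-partition
#'   must reach; below it a node is considered to have no real subdivision
#'   (community detection always returns something, even on noise, where
#'   silhouettes sit near 0).
#' @param min_cells nodes below this size are not split.
#' @param max_level maximum tree depth.
#' @param n_folds,n_repeats,genes_per_cluster,num_trees,instability_threshold,max_dissolve_iter
#'   bootstrap stability parameters, see [pairwise_bootstrap()] and
#'   [dissolve_and_reassign()].
#' @param seed integer seed for every stochastic step.
#' @return a named list.
#' @export
nc_config <- function(n_mvg = 500, n_dims = 20, k_neighbors = 20,
                      snn_cutoff = 1 / 15, highres_resolution = 1,
                      resolution_grid = seq(0.1, 1.2, by = 0.1),
                      min_silhouette = 0.1,
                      min_cells = 40, max_level = 5,
                      n_folds = 5, n_repeats = 10, genes_per_cluster = 10,
                      num_trees = 500, instability_threshold = 0.5,
                      max_dissolve_iter = 3, seed = 1L) {
  list(n_mvg = n_mvg, n_dims = n_dims, k_neighbors = k_neighbors,
       snn_cutoff = snn_cutoff, highres_resolution = highres_resolution,
       resolution_grid = resolution_grid,
       min_silhouette = min_silhouette, min_cells = min_cells,
       max_level = max_level, n_folds = n_folds, n_repeats = n_repeats,
       genes_per_cluster = genes_per_cluster, num_trees = num_trees,
       instability_threshold = instability_threshold,
       max_dissolve_iter = max_dissolve_iter, seed = as.integer(seed))
}

#' Shared-nearest-neighbor graph
#'
#' Builds the undirected k-nearest-neighbor graph (Euclidean) and weights
#' each kNN edge by the Jaccard overlap of the two cells' neighbor sets
#' (each set being the cell itself plus its k nearest others); kNN edges
#' whose overlap falls below `cutoff` are pruned. Deterministic; one vertex
#' per cell.
#'
#' @param emb a `joint_embedding`, or a coordinate matrix with cell rownames.
#' @param k nearest neighbors per cell (excluding self); must be < number
#'   of cells.
#' @param cutoff SNN Jaccard pruning threshold.
#' @return an `igraph` graph.
#' @export
knn_graph <- function(emb, k = 20, cutoff = 1 / 15) {
  coords <- if (inherits(emb, "joint_embedding")) emb$coords else emb
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells.")
  if (!all(is.finite(coords))) stop("Embedding contains non-finite values.")
  d2 <- as.matrix(dist(coords))^2
  # neighbor sets: self + k nearest others
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k + 1)]))
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1), j = as.vector(t(nn)), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(a)               # |N(i) ∩ N(j)|
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  # keep only kNN edges (i-j where one is among the other's neighbors)
  knn_adj <- a
  Matrix::diag(knn_adj) <- 0
  knn_adj <- Matrix::drop0(pmin(knn_adj + Matrix::t(knn_adj), 1))
  jac <- jac * knn_adj
  jac@x[jac@x < cutoff] <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Louvain community detection on a cell graph
#'
#' Modularity-based Louvain communities at the given resolution;
#' disconnected components are handled independently by the algorithm.
#' Deterministic given the seed.
#'
#' @param graph an igraph graph with named vertices (see [knn_graph()]).
#' @param resolution positive resolution parameter.
#' @param seed integer seed.
#' @return partition tibble `cell_id`/`label`; labels are "1", "2", ...
#'   ordered by decreasing community size.
#' @export
graph_partition <- function(graph, resolution = 1, seed = 1L) {
  stopifnot(resolution > 0)
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  mem <- igraph::membership(comm)
  # stable label order: biggest community first
  sizes <- sort(table(mem), decreasing = TRUE)
  relab <- setNames(as.character(seq_along(sizes)), names(sizes))
  tibble::tibble(cell_id = igraph::V(graph)$name,
                 label = unname(relab[as.character(mem)]))
}

#' High-resolution reference partition
#'
#' Louvain clustering at resolution 1 on the SNN graph, used as the upper
#' bound on how far divide-and-conquer subclustering may go: a node whose
#' cells occupy at most one reference community is never split further.
#'
#' @inheritParams knn_graph
#' @inheritParams graph_partition
#' @return partition tibble `cell_id`/`label`.
#' @export
highres_reference <- function(emb, k = 20, resolution = 1, seed = 1L,
                              cutoff = 1 / 15) {
  graph_partition(knn_graph(emb, k = k, cutoff = cutoff),
                  resolution = resolution, seed = seed)
}

# ---- cluster tree structures -------------------------------------------

new_cluster_node <- function(name, cell_ids, level, children = list(),
                             termination_reason = NA_character_) {
  structure(
    list(name = name, cell_ids = cell_ids, level = level,
         children = children, is_leaf = length(children) == 0,
         termination_reason = termination_reason),
    class = "cluster_node"
  )
}

new_cluster_tree <- function(root, params = list()) {
  structure(list(root = root, params = params), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  td <- generics::tidy(x)
  cat(sprintf("cluster_tree: %d cells, %d nodes, %d leaves, depth %d\n",
              length(x$root$cell_ids), nrow(td), sum(td$is_leaf),
              max(td$level)))
  leaves <- td[td$is_leaf, ]
  cat("  leaves:", paste(sprintf("%s(%d)", leaves$name, leaves$n_cells),
                         collapse = " "), "\n")
  invisible(x)
}

#' Flat partition given by the leaves of a cluster tree
#'
#' @param tree a `cluster_tree`.
#' @return partition tibble `cell_id`/`label` covering every cell exactly
#'   once.
#' @export
leaf_partition <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  rows <- list()
  walk <- function(node) {
    if (node$is_leaf) {
      rows[[length(rows) + 1]] <<- tibble::tibble(cell_id = node$cell_ids,
                                                  label = node$name)
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  dplyr::bind_rows(rows)
}

# all nodes, depth-first, as a flat list
tree_nodes <- function(tree) {
  acc <- list()
  walk <- function(node) {
    acc[[length(acc) + 1]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  acc
}

# ---- divide and conquer -------------------------------------------------

# communities of `highres` considered occupied by `cells`: a community
# counts when more than half of its cells lie inside the node
occupied_communities <- function(highres, cells) {
  inside <- highres$cell_id %in% cells
  tab <- tapply(inside, highres$label, mean)
  names(tab)[tab > 0.5]
}

# silhouette-selected sub-partition of one node, capped by the high-res bound
choose_subpartition <- function(ds_node, config, cap) {
  n <- ncol(ds_node$counts)
  mvg <- select_mvg(ds_node, config$n_mvg)
  emb <- joint_embed(ds_node, mvg,
                     n_dims = min(config$n_dims, length(mvg), n - 1L))
  k <- min(config$k_neighbors, n - 1L)
  g <- knn_graph(emb, k = k, cutoff = config$snn_cutoff)
  dd <- dist(emb$coords)
  best <- NULL
  best_sil <- -Inf
  for (res in config$resolution_grid) {
    part <- graph_partition(g, resolution = res, seed = config$seed)
    kclust <- length(unique(part$label))
    if (kclust < 2 || kclust > cap) next
    lab <- as.integer(factor(part$label[match(rownames(emb$coords),
                                              part$cell_id)]))
    sil <- mean_silhouette(lab, dd)
    if (sil > best_sil + 1e-12) {
      best_sil <- sil
      best <- part
    }
  }
  # community detection returns a partition even on structureless data,
  # but there its silhouette hovers near 0; require a minimum separation
  if (!is.null(best) && best_sil < config$min_silhouette) best <- NULL
  best
}

# mean silhouette width from integer labels and a dist object (vectorised:
# per-cluster distance sums via one matrix product)
mean_silhouette <- function(labels, dd) {
  d <- as.matrix(dd)
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  ind <- outer(labels, ks, `==`) * 1
  sums <- d %*% ind                      # n x K per-cluster distance sums
  counts <- colSums(ind)
  own_k <- match(labels, ks)
  own_n <- counts[own_k] - 1
  a <- ifelse(own_n > 0, sums[cbind(seq_len(n), own_k)] / own_n, 0)
  means <- sweep(sums, 2, counts, "/")
  means[cbind(seq_len(n), own_k)] <- Inf
  b <- apply(means, 1, min)
  s <- ifelse(own_n > 0, (b - a) / pmax(a, b), 0)
  mean(s)
}

#' Split one tree node, or close it as a leaf
#'
#' Implements the per-node step of the divide-and-conquer strategy:
#' \enumerate{
#'   \item nodes smaller than `min_cells` or at `max_level` become leaves
#'     (`too_small` / `max_level`);
#'   \item if the node's cells occupy at most one community of the
#'     high-resolution reference (a community is occupied when more than
#'     half its cells lie in the node), the node has no subdivision under
#'     the high-resolution bound and becomes a leaf (`highres_single`);
#'   \item otherwise the node is re-embedded on its own most variable genes
#'     and the Louvain resolution grid is swept; the sub-partition with the
#'     best mean silhouette, among those with between 2 and
#'     (number of occupied reference communities) clusters, defines the
#'     children. If no resolution yields a valid sub-partition the node is
#'     closed as `highres_single`.
#' }
#'
#' @param ds full [expression_dataset()] (normalized).
#' @param node a `cluster_node` (see [run_divide_and_conquer()]).
#' @param highres the [highres_reference()] partition.
#' @param config [nc_config()] list.
#' @return a `cluster_node`, either a leaf or with children attached (the
#'   children themselves unexpanded).
#' @export
split_node <- function(ds, node, highres, config = nc_config()) {
  n <- length(node$cell_ids)
  if (n < config$min_cells) {
    node$termination_reason <- "too_small"
    node$is_leaf <- TRUE
    return(node)
  }
  if (node$level >= config$max_level) {
    node$termination_reason <- "max_level"
    node$is_leaf <- TRUE
    return(node)
  }
  occ <- occupied_communities(highres, node$cell_ids)
  if (length(occ) <= 1) {
    node$termination_reason <- "highres_single"
    node$is_leaf <- TRUE
    return(node)
  }
  part <- choose_subpartition(ds[, node$cell_ids], config, cap = length(occ))
  if (is.null(part)) {
    node$termination_reason <- "highres_single"
    node$is_leaf <- TRUE
    return(node)
  }
  groups <- split(part$cell_id, part$label)
  groups <- groups[order(-lengths(groups))]
  node$children <- lapply(seq_along(groups), function(i) {
    nm <- child_name(node$name, i, node$level + 1L)
    new_cluster_node(nm, groups[[i]], node$level + 1L)
  })
  node$is_leaf <- FALSE
  node$termination_reason <- NA_character_
  node
}

child_name <- function(parent, i, level) {
  if (level == 1) LETTERS[i]
  else if (level == 2) paste0(parent, i)
  else paste0(parent, ".", i)
}

#' Iterative divide-and-conquer clustering
#'
#' Runs the full strategy: a global joint embedding on the most variable
#' genes, a resolution-1 Louvain high-resolution reference as the upper
#' bound, then recursive [split_node()] until every node is a leaf. Nodes
#' are re-embedded locally before each split. Deterministic given
#' `config$seed`.
#'
#' @param ds a normalized [expression_dataset()] (multi-dataset allowed).
#' @param config [nc_config()] list.
#' @param verbose log each node decision to stderr.
#' @return a `cluster_tree`; its flat leaf partition is available via
#'   [leaf_partition()].
#' @export
run_divide_and_conquer <- function(ds, config = nc_config(),
                                   verbose = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  mvg <- select_mvg(ds, config$n_mvg)
  emb <- joint_embed(ds, mvg, n_dims = min(config$n_dims, length(mvg)))
  highres <- highres_reference(emb, k = config$k_neighbors,
                               resolution = config$highres_resolution,
                               seed = config$seed,
                               cutoff = config$snn_cutoff)
  say <- function(...) if (verbose) message(sprintf(...))
  expand <- function(node) {
    node <- split_node(ds, node, highres, config)
    if (node$is_leaf) {
      say("leaf %s (%d cells): %s", node$name, length(node$cell_ids),
          node$termination_reason)
      return(node)
    }
    say("split %s (%d cells) -> %s", node$name, length(node$cell_ids),
        paste(vapply(node$children, `[[`, "", "name"), collapse = ", "))
    node$children <- lapply(node$children, expand)
    node
  }
  root <- new_cluster_node("root", cell_ids(ds), 0L)
  root <- expand(root)
  new_cluster_tree(root, params = c(config, list(highres = highres)))
}

#' Serialise / restore a cluster tree as JSON
#'
#' @param tree a `cluster_tree`.
#' @param path JSON file.
#' @return `read_tree` returns the `cluster_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  to_list <- function(node) {
    list(name = node$name, level = node$level,
         termination_reason = node$termination_reason,
         cell_ids = node$cell_ids,
         children = lapply(node$children, to_list))
  }
  jsonlite::write_json(to_list(tree$root), path, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  from_list <- function(l, level) {
    new_cluster_node(
      name = l$name, cell_ids = unlist(l$cell_ids), level = level,
      children = lapply(l$children, from_list, level = level + 1L),
      termination_reason = if (is.null(l$termination_reason)) NA_character_
                           else l$termination_reason
    )
  }
  new_cluster_tree(from_list(raw, 0L), params = list(source = path))
}
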