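#' Joint embedding of multiple datasets
#'
#' Places cells from all datasets into a shared principal-component space:
#' each gene is standardized *within each dataset* (mean 0, sd 1 over that
#' dataset's cells, so per-dataset location/scale differences are removed),
#' the standardized matrices are concatenated, and cells are projected onto
#' the top `n_dims` principal axes of the pooled matrix. Axis signs are fixed
#' by making each axis's largest-magnitude gene loading positive, so the
#' embedding is fully deterministic. Anchor-based integration outputs can be
#' substituted by importing an embedding with [read_embedding()].
#'
#' @param ds an [expression_dataset()] with a norm layer (its `dataset_id`
#'   column defines the batches), or a list of such datasets sharing a gene
#'   universe.
#' @param genes gene basis, typically [select_mvg()] output.
#' @param n_dims number of principal axes (clipped to the number of genes
#'   with a warning).
#' @return object of class `joint_embedding`: list with `cell_ids`, `coords`
#'   (cells x n_dims), `gene_basis`, `loadings`, `sdev`.
#' @export
joint_embed <- function(ds, genes, n_dims = 20) {
  if (!inherits(ds, "ExpressionDataset")) ds <- bind_datasets(ds)
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing)) {
    stop("Gene(s) absent from the dataset: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (n_dims > length(genes)) {
    warning("n_dims clipped to the number of basis genes (", length(genes), ").")
    n_dims <- length(genes)
  }
  x <- as.matrix(Matrix::t(ds$norm[genes, , drop = FALSE]))  # cells x genes
  by_ds <- split(seq_len(nrow(x)), ds$cell_meta$dataset_id)
  for (idx in by_ds) {
    xi <- x[idx, , drop = FALSE]
    mu <- colMeans(xi)
    sdv <- apply(xi, 2, sd)
    sdv[sdv == 0] <- 1
    x[idx, ] <- sweep(sweep(xi, 2, mu), 2, sdv, "/")
  }
  n_dims <- min(n_dims, nrow(x) - 1L, ncol(x))
  cov <- crossprod(x) / max(1, nrow(x) - 1)
  eig <- eigen(cov, symmetric = TRUE)
  v <- eig$vectors[, seq_len(n_dims), drop = FALSE]
  # sign convention: largest-|loading| gene positive on every axis
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  coords <- x %*% v
  rownames(coords) <- cell_ids(ds)
  colnames(coords) <- paste0("PC", seq_len(n_dims))
  rownames(v) <- genes
  structure(
    list(cell_ids = cell_ids(ds), coords = coords, gene_basis = genes,
         loadings = v, n_dims = n_dims,
         sdev = sqrt(pmax(eig$values[seq_len(n_dims)], 0))),
    class = "joint_embedding"
  )
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("joint_embedding: %d cells x %d dims (basis: %d genes)\n",
              length(x$cell_ids), x$n_dims, length(x$gene_basis)))
  invisible(x)
}

#' Export / import an embedding as TSV
#'
#' The TSV has a `cell_id` column followed by one column per dimension, so
#' embeddings produced by external integration tools can be dropped into the
#' pipeline.
#'
#' @param emb a `joint_embedding` (or any matrix with cell rownames).
#' @param path TSV file.
#' @return `read_embedding` returns a `joint_embedding` (without loadings).
#' @export
write_embedding <- function(emb, path) {
  coords <- if (inherits(emb, "joint_embedding")) emb$coords else emb
  df <- data.frame(cell_id = rownames(coords), coords, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df$cell_id
  structure(
    list(cell_ids = df$cell_id, coords = coords, gene_basis = NULL,
         loadings = NULL, n_dims = ncol(coords), sdev = NULL),
    class = "joint_embedding"
  )
}

#' Transfer reference labels to query cells by embedding kNN
#'
#' Each query cell takes the majority label among its `k` nearest reference
#' cells (Euclidean distance in the joint embedding); the score is the
#' majority fraction. Ties are broken by smallest mean distance to the tied
#' label's neighbors, then lexicographically. Cells whose score falls below
#' `min_score` are labeled `"unassigned"`.
#'
#' @param ref tibble `cell_id`/`label` for the reference cells (e.g. the
#'   reference dataset's sorted-population identities).
#' @param query character vector of query cell ids.
#' @param emb a `joint_embedding` containing both reference and query cells.
#' @param k neighbors (clipped to the number of reference cells with a
#'   warning).
#' @param min_score assignment cutoff.
#' @return tibble `cell_id`, `label`, `score`.
#' @export
transfer_labels <- function(ref, query, emb, k = 30, min_score = 0.5) {
  ref <- as_partition(ref)
  stopifnot(inherits(emb, "joint_embedding"))
  if (!all(ref$cell_id %in% emb$cell_ids)) stop("Reference cells missing from embedding.")
  if (!all(query %in% emb$cell_ids)) stop("Query cells missing from embedding.")
  if (k > nrow(ref)) {
    warning("k clipped to the number of reference cells (", nrow(ref), ").")
    k <- nrow(ref)
  }
  rc <- emb$coords[ref$cell_id, , drop = FALSE]
  qc <- emb$coords[query, , drop = FALSE]
  d2 <- outer(rowSums(qc^2), rowSums(rc^2), "+") - 2 * tcrossprod(qc, rc)
  d2[d2 < 0] <- 0
  res <- lapply(seq_along(query), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    labs <- ref$label[nn]
    tab <- table(labs)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      meand <- vapply(best, function(l) mean(d2[i, nn[labs == l]]), numeric(1))
      best <- best[order(meand, best)]
    }
    tibble::tibble(cell_id = query[i], label = best[1],
                   score = max(tab) / k)
  })
  out <- dplyr::bind_rows(res)
  out$label[out$score < min_score] <- "unassigned"
  out
}
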