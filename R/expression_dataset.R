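#' Construct an ExpressionDataset
#'
#' The central container of the package: a genes x cells matrix of raw counts
#' with per-cell metadata, an optional normalized layer of identical shape,
#' and per-gene QC flags (mitochondrial / immunoglobulin genes). Counts are
#' kept as (sparse) integers so that rank-based tests see exact ties;
#' normalized values are doubles.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts, with unique rownames (gene ids) and unique
#'   colnames (cell ids / barcodes).
#' @param cell_meta data frame with one row per cell. Must contain `cell_id`
#'   matching `colnames(counts)` (or be `NULL`, in which case all cells are
#'   assigned `dataset_id = "dataset1"`); a `dataset_id` column records each
#'   cell's dataset of origin, and an optional `label` column carries
#'   reference annotations.
#' @param norm optional normalized layer, same dimensions and dimnames as
#'   `counts`.
#' @param gene_flags data frame with columns `gene_id`, `is_mito`,
#'   `is_immunoglobulin`; computed from gene-name prefixes by default (see
#'   [flag_genes()]).
#' @param mito_prefix,ig_prefix gene-name prefixes used when `gene_flags` is
#'   `NULL`; case-sensitive so mouse ("mt-", "Igh...") and human ("MT-",
#'   "IGH...") conventions can be told apart.
#'
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(counts,
                               cell_meta = NULL,
                               norm = NULL,
                               gene_flags = NULL,
                               mito_prefix = c("mt-", "MT-"),
                               ig_prefix = c("Igh", "Igk", "Igl",
                                             "IGH", "IGK", "IGL")) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene rownames and cell colnames.")
  }
  if (!is(counts, "sparseMatrix")) {
    m <- as.matrix(counts)
    storage.mode(m) <- "double"
    counts <- Matrix::Matrix(m, sparse = TRUE)
  } else {
    counts <- as(counts, "CsparseMatrix")
  }
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("Duplicate gene ids: ", paste(head(dup_g, 5), collapse = ", "))
  }
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) {
    stop("Duplicate cell barcodes: ", paste(head(dup_c, 5), collapse = ", "))
  }
  if (any(counts@x < 0)) stop("Counts must be non-negative.")

  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids, dataset_id = "dataset1")
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("`cell_meta` must have a `cell_id` column.")
  }
  if (!"dataset_id" %in% names(cell_meta)) cell_meta$dataset_id <- "dataset1"
  if (nrow(cell_meta) != length(cell_ids) ||
      !setequal(cell_meta$cell_id, cell_ids)) {
    stop("`cell_meta` must have exactly one row per cell in `counts`.")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), ]

  if (is.null(gene_flags)) {
    gene_flags <- flag_genes(gene_ids, mito_prefix, ig_prefix)
  } else {
    gene_flags <- tibble::as_tibble(gene_flags)
    stopifnot(all(c("gene_id", "is_mito", "is_immunoglobulin") %in%
                    names(gene_flags)))
    gene_flags <- gene_flags[match(gene_ids, gene_flags$gene_id), ]
  }

  if (!is.null(norm)) {
    if (!identical(dim(norm), dim(counts))) {
      stop("`norm` must have the same dimensions as `counts`.")
    }
    dimnames(norm) <- dimnames(counts)
  }

  structure(
    list(counts = counts, norm = norm, cell_meta = cell_meta,
         gene_flags = gene_flags),
    class = "ExpressionDataset"
  )
}

#' Flag mitochondrial and immunoglobulin genes by name prefix
#'
#' @param gene_ids character vector of gene symbols.
#' @param mito_prefix,ig_prefix case-sensitive prefixes.
#' @return tibble with `gene_id`, `is_mito`, `is_immunoglobulin`.
#' @export
flag_genes <- function(gene_ids,
                       mito_prefix = c("mt-", "MT-"),
                       ig_prefix = c("Igh", "Igk", "Igl",
                                     "IGH", "IGK", "IGL")) {
  has_prefix <- function(x, prefixes) {
    Reduce(`|`, lapply(prefixes, function(p) startsWith(x, p)),
           init = rep(FALSE, length(x)))
  }
  tibble::tibble(
    gene_id = gene_ids,
    is_mito = has_prefix(gene_ids, mito_prefix),
    is_immunoglobulin = has_prefix(gene_ids, ig_prefix)
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  datasets: %s\n",
              paste(unique(x$cell_meta$dataset_id), collapse = ", ")))
  cat(sprintf("  norm layer: %s\n", if (is.null(x$norm)) "absent" else "present"))
  cat(sprintf("  mito genes: %d, immunoglobulin genes: %d\n",
              sum(x$gene_flags$is_mito), sum(x$gene_flags$is_immunoglobulin)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Gene and cell identifiers of an ExpressionDataset
#' @param ds an `ExpressionDataset`.
#' @return character vector.
#' @export
gene_ids <- function(ds) rownames(ds$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(ds) colnames(ds$counts)

#' Subset an ExpressionDataset by genes and/or cells
#'
#' `ds[i, j]` with gene ids/indices `i` and cell ids/indices `j`; all layers,
#' metadata and flags are subset consistently, preserving order of the index.
#'
#' @param x an `ExpressionDataset`.
#' @param i,j gene and cell selectors (character ids, logical, or integer).
#' @param ... ignored.
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  norm <- if (!is.null(x$norm)) x$norm[i, j, drop = FALSE]
  meta <- x$cell_meta[match(colnames(counts), x$cell_meta$cell_id), ]
  flags <- x$gene_flags[match(rownames(counts), x$gene_flags$gene_id), ]
  structure(list(counts = counts, norm = norm, cell_meta = meta,
                 gene_flags = flags),
            class = "ExpressionDataset")
}

#' Split an ExpressionDataset by dataset of origin
#'
#' @param ds an `ExpressionDataset`.
#' @return named list of `ExpressionDataset`, one per `dataset_id`.
#' @export
split_by_dataset <- function(ds) {
  ids <- unique(ds$cell_meta$dataset_id)
  setNames(lapply(ids, function(d) {
    ds[, ds$cell_meta$cell_id[ds$cell_meta$dataset_id == d]]
  }), ids)
}

#' Combine ExpressionDatasets sharing a gene universe
#'
#' @param ... `ExpressionDataset` objects (or a single list of them).
#' @return one `ExpressionDataset` with cells concatenated.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && !inherits(dss[[1]], "ExpressionDataset")) {
    dss <- dss[[1]]
  }
  genes <- gene_ids(dss[[1]])
  for (d in dss[-1]) {
    if (!identical(gene_ids(d), genes)) {
      stop("All datasets must share an identical, identically ordered gene universe.")
    }
  }
  counts <- do.call(cbind, lapply(dss, function(d) d$counts))
  norms <- lapply(dss, function(d) d$norm)
  norm <- if (!any(vapply(norms, is.null, logical(1)))) do.call(cbind, norms)
  meta <- dplyr::bind_rows(lapply(dss, function(d) d$cell_meta))
  expression_dataset(counts, cell_meta = meta, norm = norm,
                     gene_flags = dss[[1]]$gene_flags)
}

# internal: validate a partition tibble against a dataset (or cell universe)
as_partition <- function(x, cells = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("cell_id", "label") %in% names(x))) {
    stop("A partition needs `cell_id` and `label` columns.")
  }
  if (anyDuplicated(x$cell_id)) stop("Partition assigns a cell more than once.")
  if (!is.null(cells) && !setequal(x$cell_id, cells)) {
    stop("Partition cells do not match the dataset's cells.")
  }
  x[, c("cell_id", "label")]
}
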