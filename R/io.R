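#' Read a count matrix into an ExpressionDataset
#'
#' Supports the 10x-style Matrix-Market layout (a directory containing
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv`; genes as rows, 1-based
#' indices) and a dense CSV (genes as rows, cells as columns, first column =
#' gene id).
#'
#' @param path directory (`mtx10x`) or file (`csv`).
#' @param fmt `"mtx10x"` or `"csv"`.
#' @param metadata optional path to a per-cell metadata TSV with header and a
#'   `cell_id` column.
#' @param mito_prefix,ig_prefix gene-flag prefixes, see [flag_genes()].
#' @return an [expression_dataset()].
#' @export
read_counts <- function(path, fmt = c("mtx10x", "csv"), metadata = NULL,
                        mito_prefix = c("mt-", "MT-"),
                        ig_prefix = c("Igh", "Igk", "Igl",
                                      "IGH", "IGK", "IGL")) {
  fmt <- match.arg(fmt)
  if (fmt == "mtx10x") {
    if (!dir.exists(path)) stop("Directory not found: ", path)
    fmtx <- file.path(path, "matrix.mtx")
    ffeat <- file.path(path, "features.tsv")
    fbar <- file.path(path, "barcodes.tsv")
    for (f in c(fmtx, ffeat, fbar)) {
      if (!file.exists(f)) stop("Missing file: ", f)
    }
    m <- Matrix::readMM(fmtx)
    feats <- read.delim(ffeat, header = FALSE, stringsAsFactors = FALSE)
    bars <- read.delim(fbar, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(m) || nrow(bars) != ncol(m)) {
      stop("features/barcodes row counts do not match the matrix dimensions.")
    }
    dup <- unique(bars[[1]][duplicated(bars[[1]])])
    if (length(dup)) {
      stop("Duplicate barcodes: ", paste(head(dup, 5), collapse = ", "))
    }
    rownames(m) <- feats[[1]]
    colnames(m) <- bars[[1]]
  } else {
    if (!file.exists(path)) stop("File not found: ", path)
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  meta <- NULL
  if (!is.null(metadata)) {
    if (!file.exists(metadata)) stop("File not found: ", metadata)
    meta <- tibble::as_tibble(read.delim(metadata, stringsAsFactors = FALSE))
  }
  expression_dataset(m, cell_meta = meta,
                     mito_prefix = mito_prefix, ig_prefix = ig_prefix)
}

#' Write an ExpressionDataset's counts to disk
#'
#' Inverse of [read_counts()]: `mtx10x` writes `matrix.mtx` + `features.tsv`
#' + `barcodes.tsv` (+ `metadata.tsv`) into a directory; `csv` writes a dense
#' genes x cells table.
#'
#' @param ds an `ExpressionDataset`.
#' @param path output directory (`mtx10x`) or file (`csv`).
#' @param fmt `"mtx10x"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ds, path, fmt = c("mtx10x", "csv")) {
  fmt <- match.arg(fmt)
  if (fmt == "mtx10x") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
    write.table(data.frame(gene_ids(ds), gene_ids(ds)),
                file.path(path, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    writeLines(cell_ids(ds), file.path(path, "barcodes.tsv"))
    write.table(as.data.frame(ds$cell_meta),
                file.path(path, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.csv(as.matrix(ds$counts), path, quote = FALSE)
  }
  invisible(path)
}

#' Write an analysis report to TSV or JSON
#'
#' Works for any of the package's tabular reports (QC tables, marker tables,
#' partitions, entropy and enrichment-score results) and for the composite
#' stability summary (whose per-cell table, one row per cell, forms the TSV
#' body). Column order is preserved as constructed and floating-point values
#' are written at 6 significant digits, so output is deterministic.
#'
#' @param obj a data frame / tibble, or a `stability_summary`.
#' @param path output file.
#' @param fmt `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path, fmt = c("tsv", "json")) {
  fmt <- match.arg(fmt)
  tab <- report_table(obj)
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.double),
                                          ~ signif(.x, 6)))
  if (fmt == "tsv") {
    write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, fmt = c("tsv", "json")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}

# internal: flatten report objects to a single table for serialisation
report_table <- function(obj) {
  if (inherits(obj, "stability_summary")) return(obj$per_cell)
  if (inherits(obj, "entropy_report")) return(obj$summary)
  if (is.data.frame(obj)) {
    return(tibble::as_tibble(obj[!vapply(obj, is.list, logical(1))]))
  }
  stop("Don't know how to serialise an object of class ",
       paste(class(obj), collapse = "/"))
}

#' Read / write a flat partition as TSV
#'
#' @param part tibble with `cell_id` and `label`.
#' @param path TSV file.
#' @return `read_partition` returns the partition tibble.
#' @export
write_partition <- function(part, path) {
  part <- as_partition(part)
  write.table(as.data.frame(part), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  as_partition(read.delim(path, colClasses = "character"))
}

#' Read a YAML analysis configuration
#'
#' Unknown keys are kept; missing keys fall back to [nc_config()] defaults.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(nc_config(), user)
}
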