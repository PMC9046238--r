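#' Quality-control thresholds
#'
#' Per-dataset cell filters: cells are kept when their number of detected
#' features AND total counts both fall within the `[q_low, q_high]` quantiles
#' of their dataset, their mitochondrial read fraction is at most `mito_max`,
#' and (if `ig_max` is set, as for human data contaminated by B cells) their
#' immunoglobulin read fraction is at most `ig_max`. Mouse convention: 10th /
#' 90th quantiles and 5% mitochondrial; human convention: 10% mitochondrial
#' and 10% immunoglobulin.
#'
#' @param q_low,q_high quantile bounds for features and counts.
#' @param mito_max maximum mitochondrial fraction.
#' @param ig_max maximum immunoglobulin fraction, or `NULL` to disable.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(q_low = 0.10, q_high = 0.90,
                          mito_max = 0.05, ig_max = NULL) {
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high,
            mito_max >= 0, mito_max <= 1)
  if (!is.null(ig_max)) stopifnot(ig_max >= 0, ig_max <= 1)
  structure(list(q_low = q_low, q_high = q_high,
                 mito_max = mito_max, ig_max = ig_max),
            class = "qc_thresholds")
}

#' Human-default QC thresholds
#' @rdname qc_thresholds
#' @export
qc_thresholds_human <- function(q_low = 0.10, q_high = 0.90,
                                mito_max = 0.10, ig_max = 0.10) {
  qc_thresholds(q_low, q_high, mito_max, ig_max)
}

#' Filter cells on QC metrics, per dataset
#'
#' Each dataset of origin is filtered independently: quantile bounds are
#' computed within the dataset (linear-interpolation quantiles; cells exactly
#' at a bound are retained). The returned QC table records every input cell's
#' metrics, per-criterion pass flags and a semicolon-separated list of fail
#' reasons.
#'
#' @param ds an [expression_dataset()].
#' @param th a [qc_thresholds()].
#' @return list with `dataset` (the filtered `ExpressionDataset`) and `qc`
#'   (per-cell tibble). If every cell fails, `dataset` is empty and a warning
#'   is raised.
#' @export
qc_filter <- function(ds, th = qc_thresholds()) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ncol(ds$counts) == 0) stop("Cannot QC-filter an empty dataset.")
  counts <- ds$counts
  totals <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[ds$gene_flags$is_mito, , drop = FALSE])
  ig <- Matrix::colSums(counts[ds$gene_flags$is_immunoglobulin, , drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  ig_frac <- ifelse(totals > 0, ig / totals, 0)

  qc <- tibble::tibble(
    cell_id = cell_ids(ds),
    dataset_id = ds$cell_meta$dataset_id,
    total_counts = as.numeric(totals),
    n_features = as.numeric(n_features),
    mito_frac = as.numeric(mito_frac),
    ig_frac = as.numeric(ig_frac)
  )
  qc <- qc %>%
    dplyr::group_by(.data$dataset_id) %>%
    dplyr::mutate(
      pass_counts = .data$total_counts >=
        quantile(.data$total_counts, th$q_low, type = 7) &
        .data$total_counts <= quantile(.data$total_counts, th$q_high, type = 7),
      pass_features = .data$n_features >=
        quantile(.data$n_features, th$q_low, type = 7) &
        .data$n_features <= quantile(.data$n_features, th$q_high, type = 7)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      pass_mito = .data$mito_frac <= th$mito_max,
      pass_ig = if (is.null(th$ig_max)) TRUE else .data$ig_frac <= th$ig_max,
      keep = .data$pass_counts & .data$pass_features &
        .data$pass_mito & .data$pass_ig
    )
  reasons <- c("counts", "features", "mito", "immunoglobulin")
  fails <- cbind(!qc$pass_counts, !qc$pass_features, !qc$pass_mito, !qc$pass_ig)
  qc$fail_reasons <- apply(fails, 1, function(f) {
    paste(reasons[f], collapse = ";")
  })

  kept <- qc$cell_id[qc$keep]
  if (length(kept) == 0) {
    warning("QC filtering removed every cell.")
  }
  list(dataset = ds[, kept], qc = qc)
}

#' Library-size log-normalization
#'
#' Adds a normalized layer: `norm[g, c] = log(1 + counts[g, c] * scale /
#' total_counts[c])` (natural log). Counts are left untouched and the zero
#' pattern is preserved. This is the package's default normalization; any
#' externally normalized layer of the same shape can be attached instead via
#' `expression_dataset(norm = ...)`.
#'
#' @param ds an [expression_dataset()].
#' @param scale library-size scale factor.
#' @return the dataset with its `norm` layer set.
#' @export
normalize_counts <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"), scale > 0)
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0)) {
    stop("Cell(s) with zero total counts: ",
         paste(head(cell_ids(ds)[totals == 0], 5), collapse = ", "))
  }
  norm <- ds$counts
  norm@x <- log1p(norm@x * scale / rep.int(totals, diff(norm@p)))
  ds$norm <- norm
  ds
}

#' Select most variable genes (MVG)
#'
#' Genes are ranked by standardized dispersion: the variance of the
#' normalized values divided by the expected variance of genes at a similar
#' mean (genes are grouped into `n_bins` equal-frequency mean bins and the
#' bin's mean variance is the expectation). Zero-variance genes rank last.
#'
#' @param ds an [expression_dataset()] with a norm layer.
#' @param n number of genes to return; values above the gene count return
#'   all genes, ordered.
#' @param n_bins number of mean bins.
#' @return character vector of gene ids, most variable first.
#' @export
select_mvg <- function(ds, n = 3000, n_bins = 20) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  m <- ds$norm
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  n_cells <- ncol(m)
  v <- (ex2 - mu^2) * n_cells / max(1, n_cells - 1)
  v[v < 0] <- 0

  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                         type = 7))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  expvar <- stats::ave(v, bin, FUN = mean)
  disp <- ifelse(expvar > 0, v / expvar, 0)
  disp[v == 0] <- 0

  ord <- order(-disp, -mu, gene_ids(ds))
  head(gene_ids(ds)[ord], min(n, nrow(m)))
}
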