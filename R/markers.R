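# ---- Wilcoxon rank-sum engine ------------------------------------------

# Vectorised two-sided rank-sum test over the rows of two matrices.
# Normal approximation with tie correction and continuity correction;
# exact enumeration of the rank-sum null when both groups are small.
# Returns a tibble with statistic W (rank-sum of group a minus its minimum),
# and p.
rank_sum_rows <- function(xa, xb, exact = NULL) {
  na <- ncol(xa); nb <- ncol(xb); n <- na + nb
  if (is.null(exact)) exact <- (na <= 10 && nb <= 10)
  x <- cbind(xa, xb)
  out_p <- numeric(nrow(x))
  out_w <- numeric(nrow(x))
  if (exact) {
    idx <- combn(n, na)
    for (g in seq_len(nrow(x))) {
      r <- rank(x[g, ])
      w <- sum(r[seq_len(na)])
      null_w <- colSums(matrix(r[idx], nrow = na))
      p_le <- mean(null_w <= w + 1e-9)
      p_ge <- mean(null_w >= w - 1e-9)
      out_p[g] <- min(1, 2 * min(p_le, p_ge))
      out_w[g] <- w - na * (na + 1) / 2
    }
  } else {
    mu <- na * (n + 1) / 2
    for (g in seq_len(nrow(x))) {
      r <- rank(x[g, ])
      w <- sum(r[seq_len(na)])
      cnt <- tabulate(match(x[g, ], unique(x[g, ])))
      tiesum <- sum(cnt^3 - cnt)
      sig2 <- na * nb / 12 * ((n + 1) - tiesum / (n * (n - 1)))
      if (sig2 <= 0) {
        out_p[g] <- 1
      } else {
        z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
        out_p[g] <- 2 * pnorm(-abs(z))
      }
      out_w[g] <- w - na * (na + 1) / 2
    }
  }
  tibble::tibble(statistic = out_w, p = pmin(out_p, 1))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided rank-sum test per gene on the normalized layer, with a normal
#' approximation (tie-corrected, continuity-corrected) in general and exact
#' enumeration of the rank-sum null when both groups have at most 10 cells.
#' The effect size is `avg_log2fc = log2((mean(expm1(norm_a)) + 1) /
#' (mean(expm1(norm_b)) + 1))` and p-values are Benjamini-Hochberg adjusted
#' across the tested gene universe.
#'
#' @param ds an [expression_dataset()] with a norm layer.
#' @param cells_a,cells_b disjoint, non-empty cell id vectors.
#' @param genes gene universe to test (default: all genes), typically a
#'   [select_mvg()] list.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by group size.
#' @return tibble `gene`, `avg_log2fc`, `p`, `p_adj`, `pct_in`, `pct_out`,
#'   sorted by decreasing `avg_log2fc`.
#' @export
wilcoxon_de <- function(ds, cells_a, cells_b, genes = NULL, exact = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop("Both cell groups must be non-empty.")
  }
  if (length(intersect(cells_a, cells_b))) stop("Cell groups must be disjoint.")
  if (is.null(genes)) genes <- gene_ids(ds)
  xa <- as.matrix(ds$norm[genes, cells_a, drop = FALSE])
  xb <- as.matrix(ds$norm[genes, cells_b, drop = FALSE])
  rs <- rank_sum_rows(xa, xb, exact = exact)
  fc <- log2((rowMeans(expm1(xa)) + 1) / (rowMeans(expm1(xb)) + 1))
  out <- tibble::tibble(
    gene = genes,
    avg_log2fc = unname(fc),
    p = rs$p,
    p_adj = p.adjust(rs$p, method = "BH"),
    pct_in = rowMeans(xa > 0),
    pct_out = rowMeans(xb > 0)
  )
  dplyr::arrange(out, dplyr::desc(.data$avg_log2fc))
}

#' Per-cluster marker tables (one-vs-rest)
#'
#' For every cluster, genes are tested against all remaining cells with
#' [wilcoxon_de()]; markers are the genes passing `p_adj < p_adj_max`,
#' ranked by average log2 fold change, with the top `top_n` retained.
#'
#' @param ds an [expression_dataset()] with a norm layer.
#' @param part partition tibble `cell_id`/`label` with at least 2 clusters.
#' @param genes gene universe (default: all genes).
#' @param top_n markers kept per cluster (the reference analyses use 30, 50
#'   and 100).
#' @param p_adj_max significance gate before ranking.
#' @return a `marker_table` tibble: `cluster`, `rank`, `gene`, `avg_log2fc`,
#'   `p`, `p_adj`, `pct_in`, `pct_out`.
#' @export
cluster_markers <- function(ds, part, genes = NULL, top_n = 30,
                            p_adj_max = 0.05) {
  part <- as_partition(part, cell_ids(ds))
  labs <- sort(unique(part$label))
  if (length(labs) < 2) stop("Need at least 2 clusters.")
  res <- lapply(labs, function(cl) {
    in_cells <- part$cell_id[part$label == cl]
    out_cells <- part$cell_id[part$label != cl]
    de <- wilcoxon_de(ds, in_cells, out_cells, genes = genes, exact = FALSE)
    de <- de[de$p_adj < p_adj_max, ]
    if (nrow(de) == 0) {
      warning("Cluster ", cl, " has no markers at p_adj < ", p_adj_max, ".")
    }
    de <- head(de, top_n)
    if (nrow(de)) de$rank <- seq_len(nrow(de))
    else de$rank <- integer(0)
    de$cluster <- rep(cl, nrow(de))
    de
  })
  out <- dplyr::bind_rows(res)
  out <- out[, c("cluster", "rank", "gene", "avg_log2fc", "p", "p_adj",
                 "pct_in", "pct_out")]
  class(out) <- c("marker_table", class(out))
  out
}

#' Added-value rates of integrated versus single-dataset markers
#'
#' Quantifies what an integrated analysis adds over each dataset alone:
#' treating the integrated marker set `I` of a cluster as the correct
#' result and a single dataset's set `S` as the attempt,
#' `recovered_pct = 100 |I∩S|/|I|`, `fn_pct = 100 |I\\S|/|I|` and
#' `fp_pct = 100 |S\\I|/|S|` (0, flagged, when `S` is empty).
#'
#' @param integrated_markers named list (cluster -> gene set) from the
#'   integrated analysis, or a `marker_table`.
#' @param single_markers named list (dataset -> named list cluster -> gene
#'   set), or a named list of `marker_table`s.
#' @return `added_value` tibble: `cluster`, `dataset`, `recovered_pct`,
#'   `fn_pct`, `fp_pct`, `empty_single`.
#' @export
added_value_rates <- function(integrated_markers, single_markers) {
  integrated <- marker_sets(integrated_markers)
  singles <- lapply(single_markers, marker_sets)
  rows <- list()
  for (d in names(singles)) {
    s_d <- singles[[d]]
    miss <- setdiff(names(integrated), names(s_d))
    if (length(miss)) {
      stop("Dataset ", d, " is missing cluster(s): ",
           paste(miss, collapse = ", "))
    }
    for (cl in names(integrated)) {
      i_set <- integrated[[cl]]
      s_set <- s_d[[cl]]
      rec <- 100 * length(intersect(i_set, s_set)) / length(i_set)
      fp <- if (length(s_set) == 0) 0 else
        100 * length(setdiff(s_set, i_set)) / length(s_set)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = cl, dataset = d,
        recovered_pct = rec, fn_pct = 100 - rec, fp_pct = fp,
        empty_single = length(s_set) == 0
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("added_value", class(out))
  out
}

marker_sets <- function(x) {
  if (inherits(x, "marker_table") ||
      (is.data.frame(x) && all(c("cluster", "gene") %in% names(x)))) {
    return(split(x$gene, x$cluster))
  }
  stopifnot(is.list(x), !is.null(names(x)))
  x
}

#' Jaccard index matrix between two partitions
#'
#' `J(c1, c2) = |c1 ∩ c2| / |c1 ∪ c2|` for every pair of clusters; used to
#' compare clusters found in a single dataset with those found in the
#' integrated analysis. If the partitions cover different cell sets, the
#' intersection universe is used (with a message).
#'
#' @param part1,part2 partition tibbles `cell_id`/`label`.
#' @return numeric matrix, rows = clusters of `part1`, columns = clusters of
#'   `part2`.
#' @export
jaccard_matrix <- function(part1, part2) {
  part1 <- as_partition(part1)
  part2 <- as_partition(part2)
  common <- intersect(part1$cell_id, part2$cell_id)
  if (length(common) == 0) stop("Partitions share no cells.")
  if (length(common) < nrow(part1) || length(common) < nrow(part2)) {
    message("Partitions cover different cells; using their intersection (",
            length(common), " cells).")
  }
  p1 <- part1[part1$cell_id %in% common, ]
  p2 <- part2[part2$cell_id %in% common, ]
  c1 <- split(p1$cell_id, p1$label)
  c2 <- split(p2$cell_id, p2$label)
  out <- matrix(0, length(c1), length(c2),
                dimnames = list(names(c1), names(c2)))
  for (i in names(c1)) {
    for (j in names(c2)) {
      out[i, j] <- length(intersect(c1[[i]], c2[[j]])) /
        length(union(c1[[i]], c2[[j]]))
    }
  }
  out
}

#' Reference expression profiles for signature annotation
#'
#' @param ds a normalized [expression_dataset()].
#' @param part partition tibble.
#' @param genes genes to profile (typically the union of per-cluster
#'   markers).
#' @return genes x clusters matrix of mean normalized expression.
#' @export
build_reference_profiles <- function(ds, part, genes) {
  t(cluster_mean_expression(ds, part, genes))
}

#' Annotate query cells by nearest reference signature
#'
#' Each query cell is labeled with the reference profile to which its
#' normalized expression over the signature genes has the highest Spearman
#' correlation (one-shot nearest-centroid; ties broken lexicographically).
#' At least half of the signature genes must be present in the query.
#'
#' @param query a normalized [expression_dataset()].
#' @param ref_profiles genes x clusters matrix of mean normalized
#'   expression (see [build_reference_profiles()]).
#' @return tibble `cell_id`, `label`, `correlation`.
#' @export
signature_annotate <- function(query, ref_profiles) {
  stopifnot(inherits(query, "ExpressionDataset"))
  if (is.null(query$norm)) stop("Run normalize_counts() first: no norm layer.")
  if (ncol(ref_profiles) < 2) stop("Need at least 2 reference profiles.")
  genes <- rownames(ref_profiles)
  present <- intersect(genes, gene_ids(query))
  if (length(present) < 0.5 * length(genes)) {
    stop("Fewer than half of the signature genes are present in the query. ",
         "Missing: ", paste(head(setdiff(genes, present), 10), collapse = ", "))
  }
  x <- as.matrix(query$norm[present, , drop = FALSE])
  r <- ref_profiles[present, , drop = FALSE]
  cors <- cor(x, r, method = "spearman")
  cors[is.na(cors)] <- -Inf
  labs <- colnames(r)[max.col(cors, ties.method = "first")]
  tibble::tibble(
    cell_id = cell_ids(query),
    label = labs,
    correlation = cors[cbind(seq_len(nrow(cors)), max.col(cors, "first"))]
  )
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between a query gene list and a gene set, within a stated
#' universe; the generic statistic behind gene-set over-representation
#' analyses (the annotation databases themselves are supplied by the user,
#' e.g. via [read_gmt()]).
#'
#' @param query_genes,gene_set,universe character vectors; `query_genes` and
#'   `gene_set` must be subsets of `universe`.
#' @return tibble `overlap`, `expected`, `fold_enrichment`, `p`.
#' @export
ora_hypergeometric <- function(query_genes, gene_set, universe) {
  query_genes <- unique(query_genes)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(query_genes) == 0) stop("Empty query gene list.")
  if (!all(query_genes %in% universe)) {
    stop("Query genes outside the universe: ",
         paste(head(setdiff(query_genes, universe), 5), collapse = ", "))
  }
  if (!all(gene_set %in% universe)) {
    stop("Gene-set genes outside the universe: ",
         paste(head(setdiff(gene_set, universe), 5), collapse = ", "))
  }
  q <- length(intersect(query_genes, gene_set))
  m <- length(gene_set)
  n <- length(universe) - m
  k <- length(query_genes)
  expected <- k * m / length(universe)
  tibble::tibble(
    overlap = q,
    expected = expected,
    fold_enrichment = if (expected > 0) q / expected else NA_real_,
    p = phyper(q - 1, m, n, k, lower.tail = FALSE)
  )
}

#' Batch over-representation across several gene sets
#'
#' @param query_genes character vector.
#' @param gene_sets named list of gene sets.
#' @param universe character vector.
#' @return tibble with one row per set and BH-adjusted p-values.
#' @export
ora_batch <- function(query_genes, gene_sets, universe) {
  out <- dplyr::bind_rows(
    lapply(gene_sets, ora_hypergeometric,
           query_genes = query_genes, universe = universe),
    .id = "set"
  )
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Mean normalized expression per cluster
#'
#' The summary statistic behind cluster-level expression heatmaps (e.g.
#' niche-factor panels): mean of the normalized layer per cluster per gene.
#'
#' @param ds a normalized [expression_dataset()].
#' @param part partition tibble.
#' @param genes genes to summarise; unknown genes are skipped with a
#'   warning.
#' @return clusters x genes matrix, rows in cluster-name sort order.
#' @export
cluster_mean_expression <- function(ds, part, genes) {
  part <- as_partition(part, cell_ids(ds))
  if (is.null(ds$norm)) stop("Run normalize_counts() first: no norm layer.")
  unknown <- setdiff(genes, gene_ids(ds))
  if (length(unknown)) {
    warning("Skipping unknown gene(s): ", paste(unknown, collapse = ", "))
    genes <- setdiff(genes, unknown)
  }
  if (length(genes) == 0) stop("No known genes to summarise.")
  labs <- sort(unique(part$label))
  out <- matrix(0, length(labs), length(genes),
                dimnames = list(labs, genes))
  for (cl in labs) {
    cells <- part$cell_id[part$label == cl]
    out[cl, ] <- Matrix::rowMeans(ds$norm[genes, cells, drop = FALSE])
  }
  out
}
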