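# Shared fixtures, built in code at test time.

# a tiny hand-built dataset: 4 genes x 4 cells over 2 datasets
tiny_ds <- function() {
  counts <- matrix(
    c(5, 0, 1, 2,
      0, 3, 0, 1,
      2, 2, 2, 2,
      0, 0, 4, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("mt-Co1", "Igh-V1", "Gene1", "Gene2"),
                    paste0("c", 1:4))
  )
  meta <- tibble::tibble(cell_id = paste0("c", 1:4),
                         dataset_id = rep(c("d1", "d2"), each = 2))
  expression_dataset(counts, cell_meta = meta)
}

# a normalized dataset with K well-separated planted clusters
sep_ds <- function(k = 3, cells = 60, n_genes = 400, seed = 1,
                   log2fc = 3, n_datasets = 1, batch_sd = 0) {
  spec <- simulation_spec(
    cluster_tree = sim_hierarchy(list(k), n_markers = 20, log2fc = log2fc),
    n_datasets = n_datasets, cells_per_cluster = cells, n_genes = n_genes,
    batch_logfc_sd = batch_sd, seed = seed
  )
  sim <- simulate_dataset(spec)
  sim$dataset <- normalize_counts(sim$dataset)
  sim
}

# independent brute-force recount of bootstrap records (loop-based, no
# dplyr): per-cell recall / n_correct / dominant and per-cluster verdicts
brute_force_summary <- function(records, threshold = 0.5) {
  n_repeats <- max(records$run)
  cells <- unique(records$cell_id)
  out <- list()
  for (cl in cells) {
    rec <- records[records$cell_id == cl, ]
    pairs <- unique(paste(rec$cluster_a, rec$cluster_b))
    total <- 0; correct <- 0; n_corr_dom <- 0; any_fail <- FALSE
    for (p in pairs) {
      pr <- rec[paste(rec$cluster_a, rec$cluster_b) == p, ]
      total <- total + nrow(pr)
      correct <- correct + sum(pr$predicted == pr$truth)
      counts <- table(factor(pr$predicted,
                             levels = c(pr$cluster_a[1], pr$cluster_b[1])))
      dominant <- if (max(counts) > n_repeats / 2) {
        names(counts)[which.max(counts)]
      } else "none"
      if (dominant == pr$truth[1]) n_corr_dom <- n_corr_dom + 1
      if (dominant != pr$truth[1]) any_fail <- TRUE
    }
    out[[cl]] <- data.frame(cell_id = cl, cluster = rec$truth[1],
                            recall = correct / total,
                            n_correct = n_corr_dom,
                            any_fail = any_fail)
  }
  do.call(rbind, unname(out))
}

# independent exact two-sided rank-sum p by subset enumeration
enum_wilcox_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)])
  sets <- combn(n, length(a))
  null_w <- apply(sets, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(null_w <= w + 1e-9), mean(null_w >= w - 1e-9)))
}
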