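test_that("simulation is reproducible and matches the planted design", {
  spec <- simulation_spec(cluster_tree = sim_hierarchy(list(2, c(2, 2))),
                          n_datasets = 2, cells_per_cluster = 10,
                          n_genes = 200, seed = 9)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$truth, b$truth)

  # planted cardinalities: 4 leaves x 2 datasets x 10 cells
  expect_equal(sort(unique(a$truth$label)), c("A1", "A2", "B1", "B2"))
  expect_equal(unname(table(a$truth$label)), rep(20L, 4),
               ignore_attr = TRUE)
  counts_by <- table(a$dataset$cell_meta$label,
                     a$dataset$cell_meta$dataset_id)
  expect_true(all(counts_by == 10))

  # truth tree partitions cells at every level
  td <- tidy(a$tree)
  expect_equal(sum(td$n_cells[td$is_leaf]), 80)
  expect_equal(td$n_cells[td$name == "A"],
               sum(td$n_cells[td$parent %in% "A"]))
})

test_that("unbalanced designs and degenerate specs are handled", {
  cells <- tibble::tibble(cluster = c("A", "A", "B", "B"),
                          dataset = c("dataset1", "dataset2",
                                      "dataset1", "dataset2"),
                          n = c(5, 0, 3, 7))
  spec <- simulation_spec(cluster_tree = sim_hierarchy(list(2)),
                          n_datasets = 2, cells_per_cluster = cells,
                          n_genes = 60, seed = 1)
  sim <- simulate_dataset(spec)
  expect_equal(ncol(sim$dataset$counts), 15)
  expect_equal(sum(sim$dataset$cell_meta$label == "A" &
                     sim$dataset$cell_meta$dataset_id == "dataset2"), 0)

  cells0 <- dplyr::mutate(cells, n = 0)
  expect_error(simulation_spec(cluster_tree = sim_hierarchy(list(2)),
                               cells_per_cluster = cells0, n_genes = 60),
               "zero cells")
  expect_error(simulation_spec(dispersion = 0), "dispersion")
})

test_that("a planted log2FC=2 marker quadruples the clade mean", {
  spec <- simulation_spec(
    cluster_tree = sim_hierarchy(list(2), n_markers = 10, log2fc = 2),
    n_datasets = 1, cells_per_cluster = 500, n_genes = 300,
    batch_logfc_sd = 0, baseline_mean = 1, dispersion = 2, seed = 21
  )
  sim <- simulate_dataset(spec)
  markers_a <- attr(sim$tree, "markers")[["A"]]
  in_a <- sim$truth$cell_id[sim$truth$label == "A"]
  x <- as.matrix(sim$dataset$counts[markers_a, in_a])
  mu <- 4 * spec$baseline_mean                     # 2^2 x baseline
  se <- sqrt(mean(mu + mu^2 / spec$dispersion) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # background genes keep the baseline
  bg <- setdiff(grep("^Gene", gene_ids(sim$dataset), value = TRUE),
                unlist(attr(sim$tree, "markers")))
  xb <- as.matrix(sim$dataset$counts[bg, in_a])
  se_b <- sqrt(mean(1 + 1 / spec$dispersion) / length(xb))
  expect_lt(abs(mean(xb) - 1), 3 * se_b)
})

test_that("without batch effects per-dataset mean profiles coincide", {
  spec <- simulation_spec(cluster_tree = sim_hierarchy(list(1)),
                          n_datasets = 2, cells_per_cluster = 300,
                          n_genes = 200, batch_logfc_sd = 0, seed = 31)
  sim <- simulate_dataset(spec)
  ds <- sim$dataset
  d1 <- cell_ids(ds)[ds$cell_meta$dataset_id == "dataset1"]
  d2 <- cell_ids(ds)[ds$cell_meta$dataset_id == "dataset2"]
  bg <- grep("^Gene", gene_ids(ds), value = TRUE)
  m1 <- Matrix::rowMeans(ds$counts[bg, d1])
  m2 <- Matrix::rowMeans(ds$counts[bg, d2])
  v1 <- apply(as.matrix(ds$counts[bg, d1]), 1, var)
  v2 <- apply(as.matrix(ds$counts[bg, d2]), 1, var)
  z <- (m1 - m2) / sqrt(v1 / length(d1) + v2 / length(d2))
  expect_lt(mean(abs(z) > 4), 0.01)
})

test_that("stronger markers separate clusters more (silhouette increases)", {
  sil_for <- function(fc, seed) {
    spec <- simulation_spec(
      cluster_tree = sim_hierarchy(list(2), n_markers = 15, log2fc = fc),
      n_datasets = 1, cells_per_cluster = 40, n_genes = 200,
      batch_logfc_sd = 0, seed = seed
    )
    sim <- simulate_dataset(spec)
    ds <- normalize_counts(sim$dataset)
    emb <- joint_embed(ds, select_mvg(ds, 100), n_dims = 10)
    lab <- as.integer(factor(sim$truth$label[match(rownames(emb$coords),
                                                   sim$truth$cell_id)]))
    nichecluster:::mean_silhouette(lab, dist(emb$coords))
  }
  diffs <- vapply(1:3, function(s) sil_for(2, s) - sil_for(0.5, s),
                  numeric(1))
  expect_gt(stats::median(diffs), 0)
})

test_that("mito and immunoglobulin content tracks the target fractions", {
  spec <- simulation_spec(cluster_tree = sim_hierarchy(list(1)),
                          n_datasets = 1, cells_per_cluster = 400,
                          n_genes = 300,
                          pct_mito = list(mean = 0.05, sd = 0.01),
                          pct_ig = list(mean = 0.02, sd = 0.005), seed = 8)
  sim <- simulate_dataset(spec)
  ds <- sim$dataset
  tot <- Matrix::colSums(ds$counts)
  mito <- Matrix::colSums(ds$counts[ds$gene_flags$is_mito, ])
  expect_lt(abs(mean(mito / tot) - 0.05), 0.01)
  ig <- Matrix::colSums(ds$counts[ds$gene_flags$is_immunoglobulin, ])
  expect_lt(abs(mean(ig / tot) - 0.02), 0.005)
})

test_that("cross-species fixtures plant exact overlaps", {
  degs <- tibble::tibble(cluster = c("A", "B"), l = c(40, 30),
                         overlap = c(0, 12))
  cs <- simulate_cross_species(1000, 500, 0.2, degs, seed = 4)
  expect_equal(length(cs$mouse_mvg), 1000)
  expect_equal(length(cs$human_mvg), 500)
  expect_equal(length(intersect(cs$human_mvg, toupper(cs$mouse_mvg))), 100)
  expect_equal(length(intersect(toupper(cs$cluster_degs$A), cs$human_mvg)), 0)
  expect_equal(length(intersect(toupper(cs$cluster_degs$B), cs$human_mvg)), 12)
  cs2 <- simulate_cross_species(1000, 500, 0.2, degs, seed = 4)
  expect_identical(cs, cs2)
  expect_error(
    simulate_cross_species(100, 50, 0.1,
                           tibble::tibble(cluster = "A", l = 10,
                                          overlap = 9)),
    "Impossible"
  )
})
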