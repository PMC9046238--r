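test_that("every cell of a pair is classified once per repeat", {
  sim <- sep_ds(k = 2, cells = 20, n_genes = 150, seed = 16)
  ds <- sim$dataset
  rec <- pairwise_bootstrap(ds, sim$truth, c("A", "B"),
                            genes = select_mvg(ds, 80),
                            n_repeats = 3, num_trees = 50, seed = 1)
  expect_equal(nrow(rec), 40 * 3)
  per_run <- table(rec$cell_id, rec$run)
  expect_true(all(per_run == 1))
  expect_true(all(rec$predicted %in% c("A", "B")))

  # too-small cluster is refused with advice
  tiny <- sim$truth
  tiny$label[1:37] <- "A"
  tiny$label[38:40] <- "tiny"
  expect_error(pairwise_bootstrap(ds, tiny, c("A", "tiny")), "merge or skip")
})

test_that("indistinguishable clusters classify at chance, separable ones near 1", {
  recalls <- vapply(1:10, function(s) {
    spec <- simulation_spec(cluster_tree = sim_hierarchy(list(1)),
                            n_datasets = 1, cells_per_cluster = 400,
                            n_genes = 300, batch_logfc_sd = 0,
                            seed = 700 + s)
    sim <- simulate_dataset(spec)
    ds <- normalize_counts(sim$dataset)
    # split the single population into two arbitrary "clusters" of 200
    part <- sim$truth
    set.seed(s)
    half <- sample(part$cell_id, 200)
    part$label <- ifelse(part$cell_id %in% half, "X", "Y")
    rec <- pairwise_bootstrap(ds, part, c("X", "Y"),
                              genes = select_mvg(ds, 150),
                              n_repeats = 5, num_trees = 100, seed = s)
    mean(rec$predicted == rec$truth)
  }, numeric(1))
  expect_gte(stats::median(recalls), 0.35)
  expect_lte(stats::median(recalls), 0.65)

  sim <- sep_ds(k = 2, cells = 100, n_genes = 300, seed = 17)
  rec <- pairwise_bootstrap(sim$dataset, sim$truth, c("A", "B"),
                            genes = select_mvg(sim$dataset, 150),
                            num_trees = 200, seed = 2)
  expect_gte(mean(rec$predicted == rec$truth), 0.95)
})

test_that("stability metrics follow their definitions on crafted records", {
  # K = 3; cell z1 correct in all runs of both pairs; z2 wrong in 6/10 of one
  mk <- function(cell, a, b, pred, truth) {
    tibble::tibble(cell_id = cell, cluster_a = a, cluster_b = b,
                   run = seq_along(pred), predicted = pred, truth = truth)
  }
  records <- dplyr::bind_rows(
    mk("z1", "A", "B", rep("A", 10), "A"),
    mk("z1", "A", "C", rep("A", 10), "A"),
    mk("z2", "A", "B", c(rep("B", 6), rep("A", 4)), "A"),
    mk("z2", "A", "C", rep("A", 10), "A"),
    mk("z3", "B", "C", c(rep("B", 5), rep("C", 5)), "B"),
    mk("z3", "A", "B", rep("B", 10), "B"),
    mk("z4", "A", "C", rep("C", 10), "C"),
    mk("z4", "B", "C", rep("C", 10), "C")
  )
  part <- tibble::tibble(cell_id = c("z1", "z2", "z3", "z4"),
                         label = c("A", "A", "B", "C"))
  s <- summarize_stability(records, part)
  pc <- s$per_cell
  expect_equal(pc$recall[pc$cell_id == "z1"], 1)
  expect_equal(pc$n_correct[pc$cell_id == "z1"], 2)
  d2 <- s$dominant[s$dominant$cell_id == "z2" & s$dominant$cluster_b == "B", ]
  expect_equal(d2$dominant, "B")              # 6/10 beats the >half rule
  expect_true(d2$wrong_dominant)
  tie <- s$dominant[s$dominant$cell_id == "z3" & s$dominant$cluster_b == "C", ]
  expect_equal(tie$dominant, "none")          # exact 5/5 tie
  expect_error(summarize_stability(records[!(records$cluster_a == "B" &
                                               records$cluster_b == "C"), ],
                                   part),
               "Missing")
})

test_that("summaries match an independent brute-force recount", {
  sim <- sep_ds(k = 3, cells = 10, n_genes = 120, seed = 18, log2fc = 1)
  ds <- sim$dataset
  genes <- select_mvg(ds, 60)
  labs <- sort(unique(sim$truth$label))
  pairs <- combn(labs, 2)
  records <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
    pairwise_bootstrap(ds, sim$truth, pairs[, i], genes = genes,
                       n_folds = 5, n_repeats = 4, num_trees = 50,
                       seed = 10 + i)
  }))
  s <- summarize_stability(records, sim$truth)
  bf <- brute_force_summary(records)
  merged <- merge(s$per_cell, bf, by = "cell_id")
  expect_equal(merged$recall.x, merged$recall.y)
  expect_equal(merged$n_correct.x, merged$n_correct.y)
  expect_equal(merged$any_wrong_dominant, merged$any_fail)
  # bounds: recall in [0,1], n_correct <= K-1
  expect_true(all(s$per_cell$recall >= 0 & s$per_cell$recall <= 1))
  expect_true(all(s$per_cell$n_correct <= length(labs) - 1))
})

test_that("stability verdicts are invariant to cluster renaming", {
  sim <- sep_ds(k = 2, cells = 25, n_genes = 150, seed = 19)
  ds <- sim$dataset
  genes <- select_mvg(ds, 80)
  s1 <- evaluate_stability(ds, sim$truth, genes = genes, n_repeats = 3,
                           num_trees = 50, seed = 5)
  ren <- sim$truth
  ren$label <- c(A = "Q2", B = "Q1")[ren$label]
  s2 <- evaluate_stability(ds, ren, genes = genes, n_repeats = 3,
                           num_trees = 50, seed = 5)
  m1 <- s1$per_cluster[order(s1$per_cluster$cluster), ]
  m2 <- s2$per_cluster[match(c("Q2", "Q1"), s2$per_cluster$cluster), ]
  expect_equal(m1$unstable, m2$unstable)
  expect_equal(nrow(s1$per_cell), nrow(s2$per_cell))
})

test_that("dissolution conserves cells and leaves stable partitions alone", {
  sim <- sep_ds(k = 2, cells = 40, n_genes = 200, seed = 20)
  ds <- sim$dataset
  genes <- select_mvg(ds, 100)
  r <- dissolve_and_reassign(ds, sim$truth, genes = genes, n_repeats = 3,
                             num_trees = 50, seed = 6)
  expect_equal(length(r$dissolved), 0)
  expect_equal(dplyr::arrange(r$partition, cell_id),
               dplyr::arrange(sim$truth, cell_id))
  expect_equal(nrow(r$partition), nrow(sim$truth))
})

test_that("dataset-mixing entropy matches closed forms and is maximal at uniformity", {
  part <- tibble::tibble(cell_id = paste0("c", 1:12),
                         label = rep(c("A", "B", "C"), each = 4))
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:12),
    dataset_id = c("d1", "d2", "d3", "d1",      # A: can't be uniform on 4
                   "d1", "d1", "d1", "d1",      # B: single dataset
                   "d1", "d1", "d2", "d2")      # C: half-half
  )
  # exact thirds on a 3-cell cluster
  part3 <- tibble::tibble(cell_id = paste0("x", 1:3), label = "T")
  meta3 <- tibble::tibble(cell_id = paste0("x", 1:3),
                          dataset_id = c("d1", "d2", "d3"))
  e3 <- dataset_entropy(part3, meta3)
  expect_equal(e3$summary$entropy, log(3))
  expect_equal(e3$summary$entropy_norm, 1)

  e <- dataset_entropy(part, meta)
  s <- e$summary
  expect_equal(s$entropy[s$cluster == "B"], 0)
  expect_equal(s$entropy[s$cluster == "C"], log(2))
  expect_true(all(s$entropy >= 0 & s$entropy <= log(3) + 1e-12))

  # property: entropy of a random composition never beats the uniform one
  for (i in 1:20) {
    set.seed(i)
    p <- as.vector(table(factor(sample(1:3, 30, TRUE), levels = 1:3))) / 30
    expect_lte(shannon_entropy(p), log(3) + 1e-12)
  }
})
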