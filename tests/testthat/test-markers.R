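test_that("exact rank-sum p-values match enumeration and wilcox.test", {
  counts <- matrix(1, 1, 6, dimnames = list("g", paste0("c", 1:6)))
  ds <- normalize_counts(expression_dataset(counts))
  ds$norm["g", ] <- c(5, 6, 7, 1, 2, 3)
  de <- wilcoxon_de(ds, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(de$p, 0.1)                      # 2 of 20 arrangements
  expect_equal(de$p_adj, de$p)                 # single gene: BH is identity

  # property: exact mode equals subset enumeration for group sizes <= 7,
  # with and without ties; tie-free cases also match stats::wilcox.test
  set.seed(99)
  for (i in 1:12) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    tied <- i %% 2 == 0
    a <- if (tied) sample(1:4, na, TRUE) else rnorm(na)
    b <- if (tied) sample(1:4, nb, TRUE) else rnorm(nb)
    m <- matrix(c(a, b), 1,
                dimnames = list("g", paste0("x", seq_len(na + nb))))
    dsx <- expression_dataset(matrix(1, 1, na + nb,
                                     dimnames = dimnames(m)))
    dsx$norm <- Matrix::Matrix(m, sparse = TRUE)
    p <- wilcoxon_de(dsx, paste0("x", 1:na),
                     paste0("x", na + 1:nb), exact = TRUE)$p
    expect_equal(p, enum_wilcox_p(a, b), tolerance = 1e-12)
    if (!tied) {
      expect_equal(p, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("effect sizes and adjustment behave as documented", {
  # equal library sizes so the flat gene stays flat after normalization
  counts <- matrix(c(2, 2, 2, 2,
                     8, 8, 0, 0,
                     0, 0, 8, 8), 3, byrow = TRUE,
                   dimnames = list(c("same", "diff", "pad"),
                                   paste0("c", 1:4)))
  ds <- normalize_counts(expression_dataset(counts), scale = 10)
  de <- wilcoxon_de(ds, c("c1", "c2"), c("c3", "c4"))
  expect_equal(de$avg_log2fc[de$gene == "same"], 0)
  expect_gt(de$avg_log2fc[de$gene == "diff"], 0)
  # BH monotone in p rank
  set.seed(3)
  sim <- sep_ds(k = 2, cells = 20, n_genes = 100, seed = 23)
  de2 <- wilcoxon_de(sim$dataset,
                     sim$truth$cell_id[sim$truth$label == "A"],
                     sim$truth$cell_id[sim$truth$label == "B"])
  o <- order(de2$p)
  expect_true(all(diff(de2$p_adj[o]) >= -1e-12))
  expect_true(all(de2$p_adj >= de2$p - 1e-12))
  expect_error(wilcoxon_de(sim$dataset, character(0), "x"), "non-empty")
})

test_that("cluster markers recover planted genes and swap symmetrically", {
  hits <- vapply(1:10, function(s) {
    sim <- sep_ds(k = 2, cells = 60, n_genes = 300, seed = 800 + s,
                  log2fc = 2)
    mt <- cluster_markers(sim$dataset, sim$truth, top_n = 30)
    planted_a <- attr(sim$tree, "markers")[["A"]]
    mean(planted_a %in% mt$gene[mt$cluster == "A"])
  }, numeric(1))
  expect_gte(stats::median(hits), 1)

  sim <- sep_ds(k = 2, cells = 30, n_genes = 200, seed = 24)
  mt <- cluster_markers(sim$dataset, sim$truth, top_n = 20)
  swapped <- sim$truth
  swapped$label <- c(A = "B", B = "A")[swapped$label]
  mt2 <- cluster_markers(sim$dataset, swapped, top_n = 20)
  expect_setequal(mt$gene[mt$cluster == "A"], mt2$gene[mt2$cluster == "B"])

  # a cluster with no signal yields an empty set with a warning
  spec <- simulation_spec(cluster_tree = sim_hierarchy(list(1)),
                          n_datasets = 1, cells_per_cluster = 60,
                          n_genes = 150, batch_logfc_sd = 0, seed = 25)
  simn <- simulate_dataset(spec)
  dsn <- normalize_counts(simn$dataset)
  part <- simn$truth
  part$label <- rep(c("P", "Q"), length.out = nrow(part))
  w <- testthat::capture_warnings(mt0 <- cluster_markers(dsn, part,
                                                         top_n = 10))
  expect_true(any(grepl("no markers", w)))
  expect_equal(nrow(mt0), 0)
})

test_that("added-value rates follow the set arithmetic", {
  av <- added_value_rates(
    list(X = c("a", "b", "c", "d")),
    list(ds1 = list(X = c("a", "b", "e")))
  )
  expect_equal(av$recovered_pct, 50)
  expect_equal(av$fn_pct, 50)
  expect_equal(av$fp_pct, 100 / 3)

  same <- added_value_rates(list(X = letters[1:4]),
                            list(d = list(X = letters[1:4])))
  expect_equal(c(same$recovered_pct, same$fn_pct, same$fp_pct), c(100, 0, 0))
  disj <- added_value_rates(list(X = letters[1:4]),
                            list(d = list(X = letters[5:8])))
  expect_equal(c(disj$recovered_pct, disj$fn_pct, disj$fp_pct), c(0, 100, 100))
  emp <- added_value_rates(list(X = letters[1:4]),
                           list(d = list(X = character(0))))
  expect_equal(emp$fp_pct, 0)
  expect_true(emp$empty_single)
  expect_error(added_value_rates(list(X = "a"), list(d = list(Y = "a"))),
               "missing cluster")
})

test_that("jaccard matrices compare partitions symmetrically", {
  p1 <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                       label = c("u", "u", "u", "v"))
  p2 <- tibble::tibble(cell_id = c("b", "c", "d", "e"),
                       label = c("w", "w", "w", "w"))
  expect_message(j <- jaccard_matrix(p1, p2), "intersection")
  # on cells {b,c,d}: u = {b,c}, w = {b,c,d} -> 2/3
  expect_equal(j["u", "w"], 2 / 3)
  expect_equal(jaccard_matrix(p1, p1)["u", "u"], 1)
  expect_equal(jaccard_matrix(p1, p1)["u", "v"], 0)
  jt <- jaccard_matrix(p2, p1)
  expect_equal(t(jt), j[rownames(j), rownames(jt), drop = FALSE],
               ignore_attr = TRUE)
})

test_that("signature annotation picks the best-correlated reference", {
  sim <- sep_ds(k = 3, cells = 40, n_genes = 300, seed = 26)
  ds <- sim$dataset
  genes <- unique(cluster_markers(ds, sim$truth, top_n = 20)$gene)
  profiles <- build_reference_profiles(ds, sim$truth, genes)
  # a query equal to a profile recovers it with correlation 1
  q <- expression_dataset(
    matrix(1, length(genes), 2,
           dimnames = list(genes, c("q1", "q2"))))
  q$norm <- Matrix::Matrix(cbind(q1 = profiles[, "B"],
                                 q2 = profiles[, "C"]), sparse = TRUE)
  out <- signature_annotate(q, profiles)
  expect_equal(out$label, c("B", "C"))
  expect_equal(out$correlation, c(1, 1), tolerance = 1e-12)

  # fresh draws from the same generative model annotate correctly
  spec <- simulation_spec(
    cluster_tree = sim_hierarchy(list(3), n_markers = 20, log2fc = 3),
    n_datasets = 1, cells_per_cluster = 25, n_genes = 300, seed = 26
  )
  acc <- vapply(1:10, function(s) {
    sim2 <- simulate_dataset(spec, noise_seed = 900 + s)
    sim2$dataset <- normalize_counts(sim2$dataset)
    out2 <- signature_annotate(sim2$dataset, profiles)
    truth <- sim2$truth$label[match(out2$cell_id, sim2$truth$cell_id)]
    mean(out2$label == truth)
  }, numeric(1))
  expect_gte(stats::median(acc), 0.9)

  expect_error(signature_annotate(q[1:3, ], profiles), "half")
})

test_that("hypergeometric over-representation matches the closed form", {
  uni <- paste0("g", 1:20)
  o <- ora_hypergeometric(paste0("g", 1:5), paste0("g", 1:5), uni)
  expect_equal(o$p, 1 / choose(20, 5))
  expect_equal(o$fold_enrichment, 4)
  # overlap exactly at expectation (10 * 4 / 20 = 2) gives fold 1
  o2 <- ora_hypergeometric(paste0("g", 1:10),
                           paste0("g", c(1, 2, 11, 12)), uni)
  expect_equal(o2$fold_enrichment, 1)
  expect_error(ora_hypergeometric(character(0), "g1", uni), "Empty")
  expect_error(ora_hypergeometric("nope", "g1", uni), "outside")

  b <- ora_batch(paste0("g", 1:5),
                 list(s1 = paste0("g", 1:5), s2 = paste0("g", 6:10)), uni)
  expect_equal(nrow(b), 2)
  expect_true(all(b$p_adj >= b$p - 1e-15))
})

test_that("cluster mean expression summarises the norm layer", {
  sim <- sep_ds(k = 2, cells = 10, n_genes = 80, seed = 27)
  ds <- sim$dataset
  part <- sim$truth
  part$label[1] <- "solo"
  genes <- gene_ids(ds)[1:5]
  m <- cluster_mean_expression(ds, part, genes)
  expect_equal(m["solo", ], as.numeric(ds$norm[genes, part$cell_id[1]]),
               ignore_attr = TRUE)
  # permuting cells changes nothing
  perm <- part[sample(nrow(part)), ]
  expect_equal(cluster_mean_expression(ds, perm, genes), m)
  expect_warning(m2 <- cluster_mean_expression(ds, part,
                                               c(genes, "GHOST")),
                 "GHOST")
  expect_equal(colnames(m2), genes)
})
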