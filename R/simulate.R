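#' Describe a planted cluster hierarchy
#'
#' Builds a nested node specification for [simulation_spec()]. `branching`
#' gives, level by level, how many children each node of the previous level
#' has: e.g. `list(2, c(3, 3), c(2, 3, 2, 3, 2, 2))` is a 3-level hierarchy
#' whose two level-1 clusters each split in 3, and whose six level-2 clusters
#' split into 2/3/2/3/2/2 leaves (14 leaves). An entry of 1 leaves that node
#' unsplit. Node names follow the dotted convention used throughout the
#' package: level-1 clusters are "A", "B", ..., their children "A1", "A2",
#' and deeper levels append ".i" ("A2.1").
#'
#' Every node below the root carries `n_markers` marker genes up-regulated by
#' `log2fc` (log2 units) in all cells of its clade, so sibling separation is
#' present at every level of the hierarchy.
#'
#' @param branching list of integer vectors, one per level.
#' @param n_markers markers planted per node.
#' @param log2fc log2 fold-change of each planted marker.
#' @return nested list of nodes (`name`, `n_markers`, `log2fc`, `children`).
#' @export
sim_hierarchy <- function(branching, n_markers = 20, log2fc = 3) {
  stopifnot(length(branching) >= 1)
  make_children <- function(parent_name, level, idx_start, counts_by_level) {
    if (level > length(counts_by_level)) return(list())
    k <- counts_by_level[[level]][[idx_start]]
    lapply(seq_len(k), function(i) {
      name <- if (level == 1) {
        LETTERS[i]
      } else if (level == 2) {
        paste0(parent_name, i)
      } else {
        paste0(parent_name, ".", i)
      }
      name
    })
  }
  # recursive builder walking the per-level branching vectors in order
  counters <- integer(length(branching))
  build <- function(parent_name, level) {
    if (level > length(branching)) return(list())
    counters[level] <<- counters[level] + 1L
    k <- branching[[level]][counters[level]]
    if (is.na(k)) stop("`branching` level ", level, " is too short.")
    if (k <= 1) return(list())
    lapply(seq_len(k), function(i) {
      name <- if (level == 1) LETTERS[i]
      else if (level == 2) paste0(parent_name, i)
      else paste0(parent_name, ".", i)
      list(name = name, n_markers = n_markers, log2fc = log2fc,
           children = build(name, level + 1L))
    })
  }
  list(name = "root", n_markers = 0, log2fc = 0, children = build("", 1L))
}

#' Specify a synthetic multi-dataset single-cell experiment
#'
#' The generator draws counts from a negative binomial whose mean is a
#' per-gene baseline modulated by (a) planted marker fold-changes along the
#' cluster hierarchy and (b) per-gene, per-dataset batch shifts, and scales
#' designated mitochondrial / immunoglobulin genes per cell to hit target
#' content fractions — so QC filtering, integration, clustering, stability
#' and marker detection can all be exercised against known truth.
#'
#' @param cluster_tree [sim_hierarchy()] output defining the planted
#'   hierarchy and per-node markers.
#' @param n_datasets number of datasets (batches) of origin.
#' @param cells_per_cluster cells drawn per leaf cluster *per dataset*
#'   (scalar), or a tibble `cluster`/`dataset`/`n` for unbalanced designs
#'   (0 allowed, emulating populations missing from a dataset).
#' @param n_genes total genes, including flagged QC genes.
#' @param baseline_mean expected counts per gene per cell for background
#'   genes.
#' @param dispersion negative-binomial size parameter (shared across genes).
#' @param batch_logfc_sd sd (log2 units) of the per-gene, per-dataset batch
#'   shift; 0 disables batch effects.
#' @param n_mito,n_ig number of genes flagged mitochondrial ("mt-…") and
#'   immunoglobulin ("Igh…").
#' @param pct_mito,pct_ig list(mean, sd) of the per-cell Beta-distributed
#'   target content fraction for each flagged class.
#' @param seed integer seed; [simulate_dataset()] is fully reproducible
#'   given the spec.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(cluster_tree = sim_hierarchy(list(2, c(2, 2))),
                            n_datasets = 3,
                            cells_per_cluster = 60,
                            n_genes = 1000,
                            baseline_mean = 0.5,
                            dispersion = 2,
                            batch_logfc_sd = 0.25,
                            n_mito = 10, n_ig = 5,
                            pct_mito = list(mean = 0.03, sd = 0.015),
                            pct_ig = list(mean = 0.02, sd = 0.01),
                            seed = 1L) {
  stopifnot(dispersion > 0, baseline_mean > 0, batch_logfc_sd >= 0,
            n_genes > n_mito + n_ig)
  leaves <- hierarchy_leaves(cluster_tree)
  if (is.data.frame(cells_per_cluster)) {
    cells <- tibble::as_tibble(cells_per_cluster)
    stopifnot(all(c("cluster", "dataset", "n") %in% names(cells)))
    if (!all(cells$cluster %in% leaves)) {
      stop("Unknown cluster in `cells_per_cluster`: ",
           paste(setdiff(cells$cluster, leaves), collapse = ", "))
    }
  } else {
    cells <- tidyr::expand_grid(
      cluster = leaves,
      dataset = paste0("dataset", seq_len(n_datasets))
    )
    cells$n <- cells_per_cluster
  }
  if (any(cells$n < 0)) stop("Cell counts must be non-negative.")
  if (sum(cells$n) == 0) stop("Simulation spec yields zero cells.")
  all_fc <- unlist(node_field(cluster_tree, "log2fc"))
  if (any(!is.finite(all_fc))) stop("Marker fold-changes must be finite.")
  structure(
    list(cluster_tree = cluster_tree, n_datasets = n_datasets,
         cells = cells, n_genes = n_genes, baseline_mean = baseline_mean,
         dispersion = dispersion, batch_logfc_sd = batch_logfc_sd,
         n_mito = n_mito, n_ig = n_ig, pct_mito = pct_mito, pct_ig = pct_ig,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

hierarchy_leaves <- function(node) {
  if (length(node$children) == 0) return(node$name)
  unlist(lapply(node$children, hierarchy_leaves))
}

node_field <- function(node, field) {
  c(list(node[[field]]), unlist(lapply(node$children, node_field, field),
                                recursive = FALSE))
}

# depth-first list of all non-root nodes
collect_nodes <- function(node, acc = list()) {
  for (ch in node$children) {
    acc <- c(acc, list(ch))
    acc <- collect_nodes(ch, acc)
  }
  acc
}

# leaves under a node
clade_leaves <- function(node) hierarchy_leaves(node)

beta_params <- function(m, s) {
  v <- s^2
  v <- min(v, m * (1 - m) * 0.95)  # keep a proper Beta
  conc <- m * (1 - m) / v - 1
  c(shape1 = m * conc, shape2 = (1 - m) * conc)
}

#' Simulate a multi-dataset ExpressionDataset with known truth
#'
#' @param spec a [simulation_spec()].
#' @param noise_seed optional separate seed for the per-cell sampling stage
#'   (QC-gene fractions and count draws). The planted structure — marker
#'   gene positions and batch shifts — always derives from `spec$seed`, so
#'   two calls with different `noise_seed` are fresh draws from the *same*
#'   generative model.
#' @return list with `dataset` (an [expression_dataset()]), `truth` (tibble
#'   `cell_id`/`label`, the planted leaf partition), and `tree` (the planted
#'   hierarchy as a `cluster_tree` with per-node cell sets; its `"markers"`
#'   attribute maps each node to its planted marker genes).
#' @export
simulate_dataset <- function(spec, noise_seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)

  n_flag <- spec$n_mito + spec$n_ig
  gene_names <- c(
    if (spec$n_mito > 0) paste0("mt-Sim", seq_len(spec$n_mito)),
    if (spec$n_ig > 0) paste0("Igh-Sim", seq_len(spec$n_ig)),
    sprintf("Gene%04d", seq_len(spec$n_genes - n_flag))
  )
  is_mito <- startsWith(gene_names, "mt-")
  is_ig <- startsWith(gene_names, "Igh")
  bg_genes <- which(!is_mito & !is_ig)

  # assign disjoint marker genes to every non-root node
  nodes <- collect_nodes(spec$cluster_tree)
  need <- sum(vapply(nodes, function(n) n$n_markers, numeric(1)))
  if (need > length(bg_genes)) {
    stop("Not enough background genes for the requested markers.")
  }
  pool <- sample(bg_genes, need)
  offset <- 0L
  leaves <- hierarchy_leaves(spec$cluster_tree)
  # per-leaf log2 effect profile
  effect <- matrix(0, nrow = spec$n_genes, ncol = length(leaves),
                   dimnames = list(gene_names, leaves))
  marker_map <- list()
  for (nd in nodes) {
    if (nd$n_markers == 0) next
    gs <- pool[offset + seq_len(nd$n_markers)]
    offset <- offset + nd$n_markers
    marker_map[[nd$name]] <- gene_names[gs]
    effect[gs, clade_leaves(nd)] <- effect[gs, clade_leaves(nd)] + nd$log2fc
  }

  # cells
  cells <- spec$cells[spec$cells$n > 0, ]
  cell_tab <- tidyr::uncount(cells, .data$n)
  n_cells <- nrow(cell_tab)
  cell_tab$cell_id <- sprintf("cell%05d", seq_len(n_cells))

  # batch shifts (log2), background genes only
  datasets <- paste0("dataset", seq_len(spec$n_datasets))
  batch <- matrix(0, spec$n_genes, spec$n_datasets,
                  dimnames = list(gene_names, datasets))
  if (spec$batch_logfc_sd > 0) {
    batch[bg_genes, ] <- rnorm(length(bg_genes) * spec$n_datasets,
                               0, spec$batch_logfc_sd)
  }

  leaf_idx <- match(cell_tab$cluster, leaves)
  ds_idx <- match(cell_tab$dataset, datasets)

  if (!is.null(noise_seed)) set.seed(noise_seed)

  mu <- spec$baseline_mean * 2^(effect[, leaf_idx, drop = FALSE] +
                                  batch[, ds_idx, drop = FALSE])

  # per-cell flagged-gene content: scale flagged means so the expected
  # mito/ig fraction of each cell hits its Beta-drawn target
  bg_total <- colSums(mu[bg_genes, , drop = FALSE])
  if (spec$n_mito > 0) {
    bp <- beta_params(spec$pct_mito$mean, spec$pct_mito$sd)
    f <- rbeta(n_cells, bp[1], bp[2])
    mu[is_mito, ] <- rep(f / (1 - f) * bg_total / spec$n_mito,
                         each = spec$n_mito)
  }
  if (spec$n_ig > 0) {
    bp <- beta_params(spec$pct_ig$mean, spec$pct_ig$sd)
    f <- rbeta(n_cells, bp[1], bp[2])
    mu[is_ig, ] <- rep(f / (1 - f) * bg_total / spec$n_ig,
                       each = spec$n_ig)
  }

  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = spec$dispersion),
                   nrow = spec$n_genes,
                   dimnames = list(gene_names, cell_tab$cell_id))

  meta <- tibble::tibble(cell_id = cell_tab$cell_id,
                         dataset_id = cell_tab$dataset,
                         label = cell_tab$cluster)
  ds <- expression_dataset(counts, cell_meta = meta)
  truth <- tibble::tibble(cell_id = cell_tab$cell_id,
                          label = cell_tab$cluster)

  tree <- truth_tree(spec$cluster_tree, truth)
  attr(tree, "markers") <- marker_map
  list(dataset = ds, truth = truth, tree = tree)
}

# build a cluster_tree carrying the planted cell memberships
truth_tree <- function(spec_node, truth, level = 0L) {
  build <- function(nd, level) {
    if (length(nd$children) == 0) {
      cells <- truth$cell_id[truth$label == nd$name]
    } else {
      kids <- lapply(nd$children, build, level = level + 1L)
      cells <- unlist(lapply(kids, function(k) k$cell_ids), use.names = FALSE)
    }
    new_cluster_node(
      name = nd$name, cell_ids = cells, level = level,
      children = if (length(nd$children)) lapply(nd$children, build,
                                                 level = level + 1L)
                 else list(),
      termination_reason = if (length(nd$children) == 0) "highres_single"
                           else NA_character_
    )
  }
  new_cluster_tree(build(spec_node, 0L), params = list(source = "planted"))
}

#' Construct gene-set fixtures for cross-species conservation analysis
#'
#' Builds a mouse most-variable-gene (MVG) universe, a human MVG set with an
#' exactly controlled baseline overlap, and per-cluster mouse DEG lists with
#' exactly planted overlaps, so the conservation enrichment score can be
#' verified against closed-form expectations.
#'
#' Mouse symbols are title-case and map to human symbols by uppercasing (the
#' package's default ortholog rule).
#'
#' @param n_universe size of the mouse MVG universe.
#' @param n_human_mvg size of the human MVG set.
#' @param baseline_overlap fraction of the human MVG set that overlaps the
#'   (mapped) mouse universe; the realised count is
#'   `round(baseline_overlap * n_human_mvg)`.
#' @param cluster_degs tibble with columns `cluster`, `l` (number of mouse
#'   DEGs) and `overlap` (planted shared-gene count with the human set).
#' @param seed integer seed.
#' @return list with `mouse_mvg`, `human_mvg`, `cluster_degs` (named list of
#'   mouse gene vectors), `baseline_count`, and `expected` (per-cluster
#'   expected shared counts under the baseline rate).
#' @export
simulate_cross_species <- function(n_universe, n_human_mvg, baseline_overlap,
                                   cluster_degs, seed = 1L) {
  cluster_degs <- tibble::as_tibble(cluster_degs)
  stopifnot(all(c("cluster", "l", "overlap") %in% names(cluster_degs)))
  n_shared <- round(baseline_overlap * n_human_mvg)
  if (n_shared > n_universe || n_shared > n_human_mvg) {
    stop("Baseline overlap exceeds set sizes.")
  }
  bad <- cluster_degs$overlap > pmin(cluster_degs$l, n_shared) |
    (cluster_degs$l - cluster_degs$overlap) > (n_universe - n_shared)
  if (any(bad)) {
    stop("Impossible planted overlap for cluster(s): ",
         paste(cluster_degs$cluster[bad], collapse = ", "))
  }
  set.seed(seed)
  mouse_mvg <- sprintf("Mgene%05d", sample.int(10 * n_universe, n_universe))
  shared_mouse <- sample(mouse_mvg, n_shared)
  human_only <- sprintf("HSONLY%05d", seq_len(n_human_mvg - n_shared))
  human_mvg <- sample(c(toupper(shared_mouse), human_only))
  not_shared <- setdiff(mouse_mvg, shared_mouse)
  degs <- purrr::pmap(cluster_degs, function(cluster, l, overlap) {
    sample(c(sample(shared_mouse, overlap),
             sample(not_shared, l - overlap)))
  })
  names(degs) <- cluster_degs$cluster
  list(
    mouse_mvg = mouse_mvg,
    human_mvg = human_mvg,
    cluster_degs = degs,
    baseline_count = n_shared,
    expected = setNames(n_shared / n_universe * cluster_degs$l,
                        cluster_degs$cluster)
  )
}
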