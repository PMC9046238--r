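#' Map mouse gene symbols to human symbols
#'
#' Default rule: uppercase normalisation (mouse "Cxcl12" -> human "CXCL12"),
#' the convention under which cross-species symbol lists become directly
#' comparable. An explicit two-column ortholog table (`mouse`, `human`)
#' overrides the rule pair by pair; when the case rule is disabled, genes
#' absent from the table are dropped and reported in the `unmapped`
#' attribute.
#'
#' @param genes mouse gene symbols.
#' @param table optional data frame with columns `mouse` and `human`;
#'   duplicate mouse keys are an error.
#' @param use_case_rule fall back to uppercasing for genes not in the table.
#' @return character vector of human symbols (named by the input mouse
#'   symbols), with attribute `unmapped`.
#' @export
map_orthologs <- function(genes, table = NULL, use_case_rule = TRUE) {
  if (length(genes) == 0) stop("Empty gene list.")
  mapped <- rep(NA_character_, length(genes))
  if (!is.null(table)) {
    table <- tibble::as_tibble(table)
    stopifnot(all(c("mouse", "human") %in% names(table)))
    dup <- unique(table$mouse[duplicated(table$mouse)])
    if (length(dup)) {
      stop("Duplicate mouse keys in ortholog table: ",
           paste(head(dup, 5), collapse = ", "))
    }
    hit <- match(genes, table$mouse)
    mapped[!is.na(hit)] <- table$human[hit[!is.na(hit)]]
  }
  if (use_case_rule) {
    mapped[is.na(mapped)] <- toupper(genes[is.na(mapped)])
  }
  unmapped <- genes[is.na(mapped)]
  out <- mapped[!is.na(mapped)]
  names(out) <- genes[!is.na(mapped)]
  attr(out, "unmapped") <- unmapped
  out
}

#' Cross-species conservation enrichment score
#'
#' Compares a human most-variable-gene (MVG) set with each mouse cluster's
#' DEG list. With `l_i` the number of DEGs of mouse cluster `i`, the
#' expected shared count under the genome-wide baseline is
#' `(|MVG_human ∩ MVG_mouse| / |MVG_mouse|) * l_i` (mouse symbols mapped to
#' human before intersecting) and the enrichment score is
#' `ES_i = observed / expected`. `ES = 1` means the cluster shares genes
#' with the human set at exactly the baseline rate.
#'
#' @param human_mvg human MVG symbols.
#' @param mouse_mvg mouse MVG universe symbols.
#' @param mouse_cluster_degs named list of per-cluster mouse DEG vectors
#'   (subsets of `mouse_mvg`; violations are reported).
#' @param table optional ortholog table, see [map_orthologs()].
#' @param use_case_rule see [map_orthologs()].
#' @return `es_result` tibble: `cluster`, `l_i`, `observed`, `expected`,
#'   `es` (NA when expected is 0), and a `shared_genes` list-column.
#' @export
enrichment_score <- function(human_mvg, mouse_mvg, mouse_cluster_degs,
                             table = NULL, use_case_rule = TRUE) {
  stopifnot(length(mouse_mvg) > 0)
  human_mvg <- unique(human_mvg)
  mouse_mvg <- unique(mouse_mvg)
  outside <- unique(unlist(lapply(mouse_cluster_degs, setdiff, y = mouse_mvg)))
  if (length(outside)) {
    warning("DEG(s) outside the mouse MVG universe: ",
            paste(head(outside, 5), collapse = ", "))
  }
  mapped_universe <- map_orthologs(mouse_mvg, table, use_case_rule)
  baseline <- length(intersect(human_mvg, mapped_universe))
  rate <- baseline / length(mouse_mvg)
  rows <- lapply(names(mouse_cluster_degs), function(cl) {
    degs <- unique(mouse_cluster_degs[[cl]])
    if (length(degs) == 0) {
      warning("Cluster ", cl, " has no DEGs; ES is NA.")
      return(tibble::tibble(cluster = cl, l_i = 0L, observed = 0L,
                            expected = 0, es = NA_real_,
                            shared_genes = list(character(0))))
    }
    mapped <- map_orthologs(degs, table, use_case_rule)
    shared <- intersect(human_mvg, mapped)
    l_i <- length(degs)
    expected <- rate * l_i
    tibble::tibble(
      cluster = cl, l_i = l_i, observed = length(shared),
      expected = expected,
      es = if (expected > 0) length(shared) / expected else NA_real_,
      shared_genes = list(shared)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline_overlap") <- baseline
  attr(out, "baseline_rate") <- rate
  class(out) <- c("es_result", class(out))
  out
}

#' Permutation null for the enrichment score
#'
#' Draws `l_i` genes uniformly from the mouse MVG universe `n_perm` times
#' per cluster and recomputes the ES, giving a null distribution whose mean
#' is 1 by construction; the 2.5% / 97.5% quantiles provide an empirical
#' interval against which an observed ES can be judged.
#'
#' @param result an `es_result` from [enrichment_score()].
#' @param human_mvg,mouse_mvg,table,use_case_rule as in
#'   [enrichment_score()].
#' @param n_perm permutations per cluster.
#' @param seed integer seed.
#' @return tibble `cluster`, `es`, `null_mean`, `q025`, `q975`,
#'   `above_q975`.
#' @export
es_permutation_ci <- function(result, human_mvg, mouse_mvg,
                              table = NULL, use_case_rule = TRUE,
                              n_perm = 1000, seed = 1L) {
  stopifnot(inherits(result, "es_result"))
  human_mvg <- unique(human_mvg)
  mouse_mvg <- unique(mouse_mvg)
  mapped_universe <- map_orthologs(mouse_mvg, table, use_case_rule)
  in_human <- mapped_universe %in% human_mvg
  rate <- mean(in_human)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(result)), function(i) {
    l_i <- result$l_i[i]
    if (l_i == 0 || rate == 0) {
      return(tibble::tibble(cluster = result$cluster[i], es = result$es[i],
                            null_mean = NA_real_, q025 = NA_real_,
                            q975 = NA_real_, above_q975 = NA))
    }
    expected <- rate * l_i
    null_es <- vapply(seq_len(n_perm), function(...) {
      sum(in_human[sample.int(length(mouse_mvg), l_i)]) / expected
    }, numeric(1))
    q <- quantile(null_es, c(0.025, 0.975), names = FALSE, type = 7)
    tibble::tibble(
      cluster = result$cluster[i], es = result$es[i],
      null_mean = mean(null_es), q025 = q[1], q975 = q[2],
      above_q975 = result$es[i] > q[2]
    )
  })
  dplyr::bind_rows(rows)
}
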