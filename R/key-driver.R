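# Key driver analysis: candidate regulators within a module are ranked by
# how strongly their n-layer network neighborhood is enriched for module
# members, with the neighborhood depth n chosen per gene to maximize the
# enrichment statistic (-log10 hypergeometric p).

#' n-layer neighborhood of a gene in the network
#'
#' Breadth-first set of nodes at hop distance 1..n from `gene`, excluding
#' the gene itself; `n = 0` returns the empty set.
#'
#' @param network a `planar_network`.
#' @param gene a node id present in the network.
#' @param n neighborhood depth (>= 0).
#' @return character vector of gene ids (sorted).
#' @export
n_layer_neighborhood <- function(network, gene, n) {
  if (!gene %in% network$nodes) stop("gene not in network: ", gene)
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(character(0))
  adj <- network_adjacency(network)
  seen <- gene
  frontier <- gene
  for (layer in seq_len(n)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, gene))
}

#' Adjacency list of a planar_network
#' @noRd
network_adjacency <- function(network) {
  adj <- attr(network, "adjacency_cache")
  if (!is.null(adj)) return(adj)
  e <- network$edges
  adj <- split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
  missing <- setdiff(network$nodes, names(adj))
  if (length(missing)) {
    adj <- c(adj, stats::setNames(rep(list(character(0)), length(missing)), missing))
  }
  adj
}

#' Enrichment of a module in a neighborhood
#'
#' Fold enrichment `(|overlap| / |neighborhood|) / (|module| / |universe|)`
#' and the exact hypergeometric upper-tail p-value `P(X >= |overlap|)` with
#' population `|universe|`, successes `|module|`, draws `|neighborhood|`.
#'
#' @param neighborhood,module,universe character gene sets with
#'   `neighborhood, module <= universe`; neighborhood and module non-empty.
#' @return list with `overlap`, `fold_enrichment`, `p`.
#' @export
neighborhood_enrichment <- function(neighborhood, module, universe) {
  if (length(neighborhood) == 0) stop("empty neighborhood")
  if (length(module) == 0) stop("empty module")
  if (!all(neighborhood %in% universe) || !all(module %in% universe)) {
    stop("neighborhood and module must be subsets of the universe")
  }
  ov <- length(intersect(neighborhood, module))
  fold <- (ov / length(neighborhood)) / (length(module) / length(universe))
  p <- hypergeometric_tail(ov, length(module), length(neighborhood), length(universe))
  list(overlap = ov, fold_enrichment = fold, p = p)
}

#' Key driver analysis for one module
#'
#' For every candidate gene the neighborhood enrichment is evaluated at
#' depths `1..n_max`; the depth maximizing `-log10 p` is selected (ties:
#' smaller n). Selected p-values are BH-adjusted across the module's
#' candidates, and results are ranked by (q ascending, fold enrichment
#' descending, gene id).
#'
#' @param network a `planar_network`.
#' @param module_members character vector of module gene ids (must be
#'   network nodes).
#' @param module_id label used in the result.
#' @param universe background gene set (default: all network nodes).
#' @param n_max maximum neighborhood depth searched (>= 1).
#' @param candidates `"all"` module members (default) or `"high_degree"`
#'   (members with above-median degree within the module).
#' @return data.frame with `gene`, `module_id`, `optimal_n`,
#'   `neighborhood_size`, `overlap`, `fold_enrichment`, `p`, `q`, `rank`.
#' @export
key_driver_analysis <- function(network, module_members, module_id = "module",
                                universe = NULL, n_max = 5,
                                candidates = c("all", "high_degree")) {
  candidates <- match.arg(candidates)
  if (n_max < 1) stop("n_max must be >= 1")
  if (!all(module_members %in% network$nodes)) stop("module not contained in network")
  universe <- universe %||% network$nodes
  if (!all(module_members %in% universe)) stop("module must be within the universe")

  cand <- module_members
  if (candidates == "high_degree") {
    adj <- network_adjacency(network)
    degs <- lengths(adj[module_members])
    cand <- module_members[degs >= stats::median(degs)]
  }

  rows <- lapply(sort(cand), function(g) {
    best <- NULL
    for (n in seq_len(n_max)) {
      nb <- n_layer_neighborhood(network, g, n)
      nb <- intersect(nb, universe)
      if (length(nb) == 0) next
      enr <- neighborhood_enrichment(nb, module_members, universe)
      if (is.null(best) || enr$p < best$p - 1e-15) {
        best <- c(enr, list(optimal_n = n, neighborhood_size = length(nb)))
      }
    }
    if (is.null(best)) {
      return(data.frame(gene = g, module_id = module_id, optimal_n = NA_integer_,
                        neighborhood_size = 0L, overlap = 0L,
                        fold_enrichment = NA_real_, p = 1, stringsAsFactors = FALSE))
    }
    data.frame(gene = g, module_id = module_id, optimal_n = best$optimal_n,
               neighborhood_size = best$neighborhood_size, overlap = best$overlap,
               fold_enrichment = best$fold_enrichment, p = best$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, -out$fold_enrichment, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Key driver analysis for a whole module table
#'
#' Convenience wrapper running [key_driver_analysis()] for every module at
#' one scale of a [detect_modules_multiscale()] table.
#'
#' @param network a `planar_network`.
#' @param module_table data.frame with `gene`, `module_id` (one scale).
#' @param ... passed to [key_driver_analysis()].
#' @return row-bound data.frame of per-module results.
#' @export
key_driver_analysis_all <- function(network, module_table, ...) {
  parts <- lapply(split(module_table$gene, module_table$module_id), identity)
  out <- lapply(names(parts), function(mid) {
    key_driver_analysis(network, parts[[mid]], module_id = mid, ...)
  })
  do.call(rbind, out)
}
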