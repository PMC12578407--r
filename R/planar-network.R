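# Planar maximally filtered graph (PMFG) construction and multiscale module
# detection. The PMFG retains, among the significant coexpression edges, the
# strongest backbone that can still be drawn in the plane (at most
# 3(|V| - 2) edges), a classical filter for weighted similarity graphs.
# Modules are communities of the filtered graph found by modularity
# optimization at several resolution scales, each annotated with a
# scale-free topology fit diagnostic.

#' Planarity test for a simple undirected graph
#'
#' Demoucron's face-embedding algorithm run per biconnected component.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return TRUE if the graph is planar.
#' @export
is_planar <- function(nodes, edges) {
  if (nrow(edges) == 0) return(TRUE)
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  if (anyNA(ia) || anyNA(ib)) stop("edge endpoint not in node list")
  cpp_is_planar(length(nodes), cbind(as.integer(ia), as.integer(ib)))
}

#' Build a planar maximally filtered graph
#'
#' Greedy construction: iterate candidate edges by weight descending (ties
#' broken lexicographically on gene ids), insert each edge iff the graph
#' remains planar, and stop once `3 * (|V| - 2)` edges are accepted or the
#' candidates are exhausted. Every decision is recorded in the construction
#' log.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `weight` (finite); no
#'   duplicate undirected edges, no self-loops.
#' @param nodes node ids covering all edge endpoints (isolated nodes allowed).
#' @return an object of class `planar_network`: list with `nodes`, `edges`
#'   (accepted, with weights) and `log` (gene_a, gene_b, weight, accepted,
#'   reason).
#' @export
build_pmfg <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (length(nodes) == 0) stop("empty node list")
  if (any(!is.finite(edges$weight))) stop("edge weights must be finite")
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops not allowed")
  cp <- canonical_pair(edges$gene_a, edges$gene_b)
  edges$gene_a <- cp$a; edges$gene_b <- cp$b
  if (anyDuplicated(paste(edges$gene_a, edges$gene_b, sep = "\r"))) {
    stop("duplicate edges")
  }
  if (!all(c(edges$gene_a, edges$gene_b) %in% nodes)) {
    stop("edge endpoint missing from node list")
  }

  ord <- order(-edges$weight, edges$gene_a, edges$gene_b)
  edges <- edges[ord, , drop = FALSE]
  n <- length(nodes)
  max_edges <- if (n >= 3) 3L * (n - 2L) else if (n == 2) 1L else 0L

  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  accepted <- logical(nrow(edges))
  reason <- character(nrow(edges))
  acc <- matrix(0L, nrow = 0, ncol = 2)
  for (k in seq_len(nrow(edges))) {
    if (nrow(acc) >= max_edges) {
      reason[k] <- "edge_budget"
      next
    }
    cand <- rbind(acc, c(ia[k], ib[k]))
    if (cpp_is_planar(n, cand)) {
      acc <- cand
      accepted[k] <- TRUE
      reason[k] <- "planar"
    } else {
      reason[k] <- "nonplanar"
    }
  }

  net <- list(
    nodes = nodes,
    edges = data.frame(
      gene_a = edges$gene_a[accepted], gene_b = edges$gene_b[accepted],
      weight = edges$weight[accepted], row.names = NULL, stringsAsFactors = FALSE
    ),
    log = data.frame(
      gene_a = edges$gene_a, gene_b = edges$gene_b, weight = edges$weight,
      accepted = accepted, reason = reason, row.names = NULL, stringsAsFactors = FALSE
    )
  )
  class(net) <- "planar_network"
  stopifnot(is_planar(net$nodes, net$edges)) # invariant re-checked on the result
  net
}

#' @export
print.planar_network <- function(x, ...) {
  cat("planar_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(cap %d)\n", if (length(x$nodes) >= 3) 3 * (length(x$nodes) - 2) else 1))
  invisible(x)
}

#' igraph view of a planar_network
#' @noRd
network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Multiscale module detection on the planar network
#'
#' Modularity-based community detection (Louvain) on the filtered graph at
#' each resolution in `scales`. Communities with at least `min_size`
#' members are kept and annotated with the scale at which they were found
#' and the scale-free fit index of their induced subgraph degrees (NA when
#' the fit is undefined, e.g. all degrees equal).
#'
#' @param network a `planar_network`.
#' @param scales resolution parameters (larger = finer communities).
#' @param min_size minimum module size (>= 2).
#' @param seed integer seed for the community detection.
#' @return data.frame with `gene`, `module_id`, `scale`, `scale_free_r2`.
#'   Module ids are stable for a fixed seed: numbered per scale by
#'   decreasing size, ties by smallest member id.
#' @export
detect_modules_multiscale <- function(network, scales = c(0.5, 1, 2),
                                      min_size = 5, seed = 1) {
  if (!inherits(network, "planar_network")) stop("network must be a planar_network")
  if (length(scales) == 0) stop("scales must be non-empty")
  if (min_size < 2) stop("min_size must be >= 2")
  if (nrow(network$edges) == 0) stop("network has no edges")
  g <- network_igraph(network)
  out <- list()
  for (sc in scales) {
    set.seed(as.integer(seed))
    comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                    resolution = sc)
    memb <- igraph::membership(comm)
    sizes <- table(memb)
    keep <- names(sizes)[sizes >= min_size]
    if (length(keep) == 0) next
    first_member <- vapply(keep, function(k) min(names(memb)[memb == k]), "")
    ordk <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (i in seq_along(ordk)) {
      members <- sort(names(memb)[memb == ordk[i]])
      sub <- igraph::induced_subgraph(g, members)
      degs <- igraph::degree(sub)
      r2 <- tryCatch(scale_free_fit(degs), error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        gene = members,
        module_id = sprintf("scale%s_mod%02d", format(sc), i),
        scale = sc,
        scale_free_r2 = r2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), module_id = character(0),
                      scale = numeric(0), scale_free_r2 = numeric(0)))
  }
  do.call(rbind, out)
}

#' Scale-free topology fit index
#'
#' R-squared of the least-squares fit of `log10 P(k)` versus `log10 k` over
#' log-binned degrees: degrees are grouped into up to 10 geometrically
#' spaced bins, each non-empty bin contributes its mean degree and its
#' frequency density (count / (n * bin width)).
#'
#' @param degrees positive integer degrees (zeros are ignored).
#' @return R-squared in \code{[0, 1]}.
#' @export
scale_free_fit <- function(degrees) {
  k <- degrees[degrees > 0]
  if (length(unique(k)) < 2) stop("scale-free fit undefined: need >= 2 distinct positive degrees")
  nbin <- min(10L, length(unique(k)))
  breaks <- exp(seq(log(min(k)), log(max(k)), length.out = nbin + 1))
  breaks[1] <- breaks[1] * (1 - 1e-9)
  breaks[nbin + 1] <- breaks[nbin + 1] * (1 + 1e-9)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = nbin)
  keep <- cnt > 0
  kmean <- vapply(split(k, bin), function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))[keep]
  dens <- cnt[keep] / (length(k) * diff(breaks)[keep])
  if (sum(keep) < 2) stop("scale-free fit undefined: fewer than 2 occupied bins")
  fit <- stats::lm(log10(dens) ~ log10(kmean))
  summary(fit)$r.squared
}
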