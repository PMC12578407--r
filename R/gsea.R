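# Gene-set machinery: exact hypergeometric over-representation tests for
# module annotation, a weighted Kolmogorov-Smirnov GSEA engine with
# permutation significance, and the two-subset prognostic-signature status
# classifier (poor / intermediate / good) used to score perturbations
# against a reference condition.

#' Two-subset prognostic signature definition
#'
#' @param name signature label.
#' @param poor_genes,good_genes disjoint, non-empty gene id sets.
#' @return object of class `signature_definition`.
#' @export
signature_definition <- function(name, poor_genes, good_genes) {
  poor_genes <- unique(as.character(poor_genes))
  good_genes <- unique(as.character(good_genes))
  if (length(poor_genes) == 0 || length(good_genes) == 0) {
    stop("both signature subsets must be non-empty")
  }
  if (length(intersect(poor_genes, good_genes))) {
    stop("poor and good subsets must be disjoint")
  }
  structure(list(name = name, poor_genes = poor_genes, good_genes = good_genes),
            class = "signature_definition")
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= overlap)` for the overlap of a gene set of `set_size` with a draw
#' of `draw_size` from a universe of `universe_size` (exact via
#' [stats::phyper()], no normal approximation).
#'
#' @param overlap,set_size,draw_size,universe_size consistent counts.
#' @return probability.
#' @export
hypergeometric_tail <- function(overlap, set_size, draw_size, universe_size) {
  if (overlap > min(set_size, draw_size) || overlap < 0) stop("inconsistent overlap")
  if (set_size > universe_size || draw_size > universe_size) {
    stop("set or draw larger than universe")
  }
  phyper(overlap - 1, set_size, universe_size - set_size, draw_size,
         lower.tail = FALSE)
}

#' Hypergeometric annotation of modules against gene-set collections
#'
#' One exact over-representation test per (module, gene set) pair, with a
#' single BH adjustment across all tests. Gene sets are intersected with
#' the universe first.
#'
#' @param modules named list of module member vectors, or a
#'   [detect_modules_multiscale()] table (one scale).
#' @param collections list of gene sets as returned by [read_gmt()].
#' @param universe background gene ids.
#' @return data.frame `module_id`, `gene_set`, `module_size`, `set_size`,
#'   `overlap`, `p`, `q`, sorted by `q` then `p`.
#' @export
annotate_modules <- function(modules, collections, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (length(collections) == 0) stop("empty gene-set collection")
  if (is.data.frame(modules)) {
    modules <- split(modules$gene, modules$module_id)
  }
  rows <- list()
  for (mid in names(modules)) {
    mem <- intersect(modules[[mid]], universe)
    for (gs in collections) {
      set <- intersect(gs$genes, universe)
      ov <- length(intersect(mem, set))
      p <- if (length(set) == 0 || length(mem) == 0) 1 else {
        hypergeometric_tail(ov, length(set), length(mem), length(universe))
      }
      rows[[length(rows) + 1]] <- data.frame(
        module_id = mid, gene_set = gs$name, module_size = length(mem),
        set_size = length(set), overlap = ov, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$module_id, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by differential expression between two conditions
#'
#' Genes shared by both matrices are ordered by descending log2 mean
#' difference (test minus reference); exact ties fall back to gene-id
#' order. The ranking is invariant under any common per-sample additive
#' shift.
#'
#' @param test,reference genes-by-samples log2 matrices with >= 1 sample.
#' @param metric `"mean_diff"` (default) or `"s2n"` (signal-to-noise,
#'   requires >= 2 samples per group).
#' @return named numeric vector of scores, sorted for GSEA.
#' @export
rank_genes <- function(test, reference, metric = c("mean_diff", "s2n")) {
  metric <- match.arg(metric)
  validate_expression_matrix(test)
  validate_expression_matrix(reference)
  shared <- intersect(rownames(test), rownames(reference))
  if (length(shared) == 0) stop("no shared genes between test and reference")
  t_m <- rowMeans(test[shared, , drop = FALSE])
  r_m <- rowMeans(reference[shared, , drop = FALSE])
  if (metric == "mean_diff") {
    score <- t_m - r_m
  } else {
    if (ncol(test) < 2 || ncol(reference) < 2) stop("s2n needs >= 2 samples per group")
    t_s <- apply(test[shared, , drop = FALSE], 1, sd)
    r_s <- apply(reference[shared, , drop = FALSE], 1, sd)
    denom <- pmax(t_s + r_s, 1e-8)
    score <- (t_m - r_m) / denom
  }
  score[order(-score, shared)]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked, scored gene list: positions in the
#' set increment the sum by `|score|^weight_exponent` normalized over the
#' in-set total, positions outside decrement by `1 / (N - N_hit)`; the
#' enrichment score is the signed extreme of the running sum. When the
#' in-set weights sum to zero (all scores zero) equal hit weights are used.
#'
#' @param ranked named score vector as from [rank_genes()] (already ordered).
#' @param gene_set character gene ids; must intersect the ranking and must
#'   not equal the whole ranked universe.
#' @param weight_exponent weighting exponent (0 = classical unweighted KS).
#' @return list with `es` (in \code{[-1, 1]}) and `running_sum` (starts and
#'   ends at 0, position 0 implicit).
#' @export
gsea_enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set does not intersect the ranked list")
  if (n_hit == length(genes)) stop("gene set equals the whole ranked universe")
  w <- abs(ranked)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) {
    # an all-zero ranking carries no enrichment evidence
    return(list(es = 0, running_sum = rep(0, length(genes))))
  }
  inc <- w / sum(w)
  inc[!hit] <- -1 / (length(genes) - n_hit)
  running <- unname(cumsum(inc))
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running)
}

#' GSEA with permutation significance
#'
#' Observed enrichment scores per gene set, a permutation null, normalized
#' enrichment scores (ES divided by the mean |null ES| of matching sign, the
#' standard GSEA normalization), add-one empirical p-values and BH q-values
#' across sets. Sample (phenotype) permutation is used when both groups have
#' at least 3 samples; otherwise gene-set permutation is used and noted in
#' the `"permutation_type"` attribute.
#'
#' @param test,reference genes-by-samples log2 matrices.
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param weight_exponent passed to [gsea_enrichment_score()].
#' @param metric ranking metric, see [rank_genes()].
#' @return data.frame `gene_set`, `size`, `es`, `nes`, `p`, `q`,
#'   `direction` (`"induced"` iff `es > 0`).
#' @export
gsea_significance <- function(test, reference, gene_sets, n_perm = 1000,
                              seed = 1, weight_exponent = 1,
                              metric = "mean_diff") {
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (is.null(names(gene_sets))) names(gene_sets) <- sprintf("set_%d", seq_along(gene_sets))
  shared <- intersect(rownames(test), rownames(reference))
  ranked_obs <- rank_genes(test, reference, metric = metric)
  obs <- vapply(gene_sets, function(s) {
    gsea_enrichment_score(ranked_obs, s, weight_exponent)$es
  }, numeric(1))

  sample_perm <- ncol(test) >= 3 && ncol(reference) >= 3
  set.seed(as.integer(seed))
  null_es <- matrix(NA_real_, nrow = n_perm, ncol = length(gene_sets))
  if (sample_perm) {
    comb <- cbind(test[shared, , drop = FALSE], reference[shared, , drop = FALSE])
    colnames(comb) <- sprintf("s%03d", seq_len(ncol(comb))) # avoid duplicate ids
    n_t <- ncol(test)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(ncol(comb))
      rt <- comb[, idx[seq_len(n_t)], drop = FALSE]
      rr <- comb[, idx[-seq_len(n_t)], drop = FALSE]
      rk <- rank_genes(rt, rr, metric = metric)
      null_es[b, ] <- vapply(gene_sets, function(s) {
        gsea_enrichment_score(rk, s, weight_exponent)$es
      }, numeric(1))
    }
  } else {
    for (b in seq_len(n_perm)) {
      null_es[b, ] <- vapply(gene_sets, function(s) {
        sz <- length(intersect(s, names(ranked_obs)))
        rs <- sample(names(ranked_obs), sz)
        gsea_enrichment_score(ranked_obs, rs, weight_exponent)$es
      }, numeric(1))
    }
  }

  nes <- p <- numeric(length(gene_sets))
  for (j in seq_along(gene_sets)) {
    nulls <- null_es[, j]
    same_sign <- if (obs[j] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    nes[j] <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
      obs[j] / mean(abs(same_sign))
    } else NA_real_
    # standard GSEA convention: compare against the same-signed null side
    p[j] <- if (obs[j] >= 0) {
      (1 + sum(nulls >= obs[j] - 1e-12)) / (1 + sum(nulls >= -1e-12))
    } else {
      (1 + sum(nulls <= obs[j] + 1e-12)) / (1 + sum(nulls <= 1e-12))
    }
  }
  out <- data.frame(
    gene_set = names(gene_sets),
    size = vapply(gene_sets, function(s) length(intersect(s, shared)), integer(1)),
    es = unname(obs), nes = nes, p = p, q = bh_fdr(p),
    direction = ifelse(obs > 0, "induced", "suppressed"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "permutation_type") <- if (sample_perm) "sample" else "gene_set"
  out
}

#' Prognostic-signature status call
#'
#' Runs [gsea_significance()] for the poor- and good-prognosis subsets and
#' maps the pair of results to a categorical call: `"poor"` when the poor
#' subset is induced or the good subset suppressed at `q < fdr_cut` (and the
#' converse pattern is absent), `"good"` for the converse, and
#' `"intermediate"` otherwise -- including conflicting double-significant
#' patterns, which are noted in the `conflict` field.
#'
#' @param test,reference genes-by-samples log2 matrices.
#' @param signature a [signature_definition()]; both subsets must intersect
#'   the measured genes.
#' @param n_perm,seed,weight_exponent,metric passed to [gsea_significance()].
#' @param fdr_cut FDR threshold for a subset to count as significant
#'   (default 0.25, the customary GSEA exploration cutoff).
#' @return object of class `signature_status`: list with `poor`, `good`
#'   (one-row results), `call`, `conflict`.
#' @export
signature_status <- function(test, reference, signature, n_perm = 1000,
                             seed = 1, fdr_cut = 0.25, weight_exponent = 1,
                             metric = "mean_diff") {
  if (!inherits(signature, "signature_definition")) {
    stop("signature must be a signature_definition")
  }
  shared <- intersect(rownames(test), rownames(reference))
  if (length(intersect(signature$poor_genes, shared)) == 0 ||
      length(intersect(signature$good_genes, shared)) == 0) {
    stop("a signature subset is entirely unmeasured")
  }
  res <- gsea_significance(
    test, reference,
    gene_sets = list(poor = signature$poor_genes, good = signature$good_genes),
    n_perm = n_perm, seed = seed, weight_exponent = weight_exponent,
    metric = metric
  )
  poor <- res[res$gene_set == "poor", , drop = FALSE]
  good <- res[res$gene_set == "good", , drop = FALSE]
  poor_like <- (poor$direction == "induced" && poor$q < fdr_cut) ||
    (good$direction == "suppressed" && good$q < fdr_cut)
  good_like <- (good$direction == "induced" && good$q < fdr_cut) ||
    (poor$direction == "suppressed" && poor$q < fdr_cut)
  call <- if (poor_like && !good_like) "poor"
  else if (good_like && !poor_like) "good"
  else "intermediate"
  structure(
    list(poor = poor, good = good, call = call,
         conflict = poor_like && good_like,
         fdr_cut = fdr_cut,
         permutation_type = attr(res, "permutation_type")),
    class = "signature_status"
  )
}

#' @export
print.signature_status <- function(x, ...) {
  cat("signature status:", x$call,
      if (isTRUE(x$conflict)) "(conflicting enrichment patterns)" else "", "\n")
  cat(sprintf("  poor: es = %+.3f  nes = %+.3f  p = %.4g  q = %.4g  (%s)\n",
              x$poor$es, x$poor$nes, x$poor$p, x$poor$q, x$poor$direction))
  cat(sprintf("  good: es = %+.3f  nes = %+.3f  p = %.4g  q = %.4g  (%s)\n",
              x$good$es, x$good$nes, x$good$p, x$good$q, x$good$direction))
  invisible(x)
}

#' Housekeeping-normalized z-scores of log2 expression
#'
#' Per sample, the mean of the housekeeping genes is subtracted (absorbing
#' per-sample shifts); each gene is then z-scored across samples. Constant
#' genes map to all-zero rows with a warning.
#'
#' @param mat genes-by-samples log2 matrix.
#' @param housekeeping gene ids present in `mat`.
#' @return matrix of the same shape.
#' @export
zscore_log2_housekeeping <- function(mat, housekeeping) {
  validate_expression_matrix(mat, allow_na = FALSE)
  if (length(housekeeping) == 0) stop("empty housekeeping list")
  if (!all(housekeeping %in% rownames(mat))) stop("housekeeping genes missing from matrix")
  centered <- sweep(mat, 2, colMeans(mat[housekeeping, , drop = FALSE]), "-")
  mu <- rowMeans(centered)
  sdv <- apply(centered, 1, sd)
  flat <- sdv < 1e-12
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) mapped to zero rows")
    sdv[flat] <- 1
  }
  out <- sweep(sweep(centered, 1, mu, "-"), 1, sdv, "/")
  out[flat, ] <- 0
  out
}
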