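# Per-cohort permutation-based correlation testing and cross-cohort
# meta-analysis. Nominal per-cohort p-values are combined with Fisher's
# inverse chi-square statistic (ICS = -2 * sum(log p)); significance of the
# ICS is assessed against an empirical null built by iterative resampling of
# the observed nominal p-values, and adjusted by Benjamini-Hochberg FDR.

#' All permutations of 1..n (n <= 8)
#' @noRd
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    out[(r + 1):(r + nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided empirical p-value for the Pearson correlation of `x` and `y`.
#' With random permutations the add-one estimator
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)` is used, which never
#' returns 0 (so downstream log-combination is safe). With
#' `exhaustive = TRUE` (length <= 8) all `length(y)!` permutations are
#' enumerated and the exact fraction reaching `|r_obs|` is returned.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param n_perm number of random permutations.
#' @param seed optional integer seed for the permutation stream.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return a single p-value in (0, 1].
#' @export
permutation_correlation_pvalue <- function(x, y, n_perm = 1000, seed = NULL,
                                           exhaustive = FALSE) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values: subset to complete pairs first")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  n <- length(x)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to length <= 8")
    xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
    dot_obs <- abs(sum(xs * ys))
    perms <- all_permutations(n)
    dots <- abs(matrix(ys[perms], nrow = nrow(perms)) %*% xs)
    return(sum(dots >= dot_obs - 1e-9) / nrow(perms))
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  count <- cpp_perm_corr_count(as.numeric(x), as.numeric(y), as.integer(n_perm))
  (1 + count) / (n_perm + 1)
}

#' Permutation correlation p-values for all gene pairs
#'
#' One two-sided permutation p-value per unordered gene pair, each computed
#' with a per-pair sub-seed derived from `seed` and a stable hash of the
#' gene-id pair, so the table does not depend on evaluation order. Pairs
#' with fewer than 3 complete (non-missing) observations, or with a constant
#' gene over their complete observations, are omitted and recorded in the
#' `"dropped"` attribute.
#'
#' @param mat genes-by-samples matrix (log2 scale).
#' @param n_perm random permutations per pair.
#' @param seed integer master seed.
#' @param gene_subset optional gene ids to restrict to (>= 2 after subsetting).
#' @return data.frame with `gene_a`, `gene_b` (lexicographic canonical
#'   order), `n_obs`, `r`, `p`; attribute `"dropped"` lists omitted pairs.
#' @export
all_pairs_pvalues <- function(mat, n_perm = 1000, seed = 1, gene_subset = NULL) {
  validate_expression_matrix(mat)
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stop("empty gene subset")
    missing <- setdiff(gene_subset, rownames(mat))
    if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
    mat <- mat[gene_subset, , drop = FALSE]
  }
  genes <- sort(rownames(mat))
  if (length(genes) < 2) stop("need at least 2 genes")
  mat <- mat[genes, , drop = FALSE]
  pairs <- combn(genes, 2)
  np <- ncol(pairs)
  p <- r <- rep(NA_real_, np)
  n_obs <- integer(np)
  dropped <- character(0)
  for (k in seq_len(np)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- mat[a, ]; xb <- mat[b, ]
    ok <- !is.na(xa) & !is.na(xb)
    n_obs[k] <- sum(ok)
    if (n_obs[k] < 3 || sd(xa[ok]) == 0 || sd(xb[ok]) == 0) {
      dropped <- c(dropped, paste(a, b, sep = "--"))
      next
    }
    set.seed(pair_seed(seed, a, b))
    cnt <- cpp_perm_corr_count(xa[ok], xb[ok], as.integer(n_perm))
    p[k] <- (1 + cnt) / (n_perm + 1)
    r[k] <- cor(xa[ok], xb[ok])
  }
  keep <- !is.na(p)
  out <- data.frame(
    gene_a = pairs[1, keep], gene_b = pairs[2, keep],
    n_obs = n_obs[keep], r = r[keep], p = p[keep],
    stringsAsFactors = FALSE
  )
  if (length(dropped)) message(length(dropped), " pair(s) dropped (insufficient or constant data)")
  attr(out, "dropped") <- dropped
  out
}

#' Fisher's inverse chi-square statistic
#'
#' `ICS = -2 * sum(log(p))`. Under k independent uniform nulls the ICS is
#' chi-square distributed with 2k degrees of freedom; here its significance
#' is instead taken from [resampling_null_pvalue()]'s empirical null.
#'
#' @param pvals p-values in (0, 1].
#' @return non-negative statistic.
#' @export
fisher_ics <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  -2 * sum(log(pvals))
}

#' Empirical resampling p-value for an observed ICS
#'
#' Draws `k` p-values with replacement from the pool of observed nominal
#' p-values, forms the ICS of each draw (`n_resample` times), and returns
#' the add-one upper-tail fraction; ties count as exceedances.
#'
#' @param ics_obs observed statistic.
#' @param pvalue_pool pool of nominal per-cohort p-values (in (0, 1]).
#' @param k number of p-values combined per ICS (number of cohorts).
#' @param n_resample resampling iterations.
#' @param seed optional integer seed.
#' @return empirical p-value in (0, 1].
#' @export
resampling_null_pvalue <- function(ics_obs, pvalue_pool, k, n_resample = 10000,
                                   seed = NULL) {
  null_ics <- resampling_null_ics(pvalue_pool, k, n_resample, seed)
  (1 + sum(null_ics >= ics_obs - 1e-12)) / (n_resample + 1)
}

#' Null ICS draws by iterative resampling of a p-value pool
#'
#' The empirical null behind [resampling_null_pvalue()]: `n_resample` ICS
#' values, each formed from `k` p-values drawn with replacement from the
#' pool. For a Uniform(0,1) pool this converges to the chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param pvalue_pool pool of nominal p-values in (0, 1].
#' @param k p-values combined per draw.
#' @param n_resample number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n_resample` null ICS values.
#' @export
resampling_null_ics <- function(pvalue_pool, k, n_resample = 10000, seed = NULL) {
  if (length(pvalue_pool) == 0) stop("empty p-value pool")
  if (any(pvalue_pool <= 0 | pvalue_pool > 1)) stop("pool p-values must be in (0, 1]")
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- matrix(sample(pvalue_pool, k * n_resample, replace = TRUE), nrow = k)
  -2 * colSums(log(draws))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegated to [stats::p.adjust()]),
#' returned in input order.
#'
#' @param pvals p-values in \code{[0, 1]}.
#' @return adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) && any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Cross-cohort edge meta-analysis
#'
#' Runs [all_pairs_pvalues()] in every cohort on a shared gene subset,
#' combines per-cohort p-values per edge with [fisher_ics()], computes an
#' empirical meta p-value against a single resampling null (pool = all
#' observed nominal p-values across cohorts and pairs, drawn once since the
#' null distribution is shared by all edges with the same cohort count), and
#' BH-adjusts across edges.
#'
#' @param cohorts named list of genes-by-samples matrices sharing gene ids.
#' @param n_perm permutations per pair and cohort.
#' @param n_resample resampling iterations for the ICS null.
#' @param seed integer master seed.
#' @param gene_subset optional explicit gene subset.
#' @param top_var when `gene_subset` is NULL, restrict to this many genes by
#'   average variance across cohorts (all-pairs permutation testing at full
#'   genome scale is not desk-feasible).
#' @return data.frame with `gene_a`, `gene_b`, one `p_<cohort>` column per
#'   cohort, `ics`, `meta_p`, `q`.
#' @export
edge_meta_analysis <- function(cohorts, n_perm = 1000, n_resample = 10000,
                               seed = 1, gene_subset = NULL, top_var = 500) {
  if (length(cohorts) < 1) stop("need at least one cohort")
  if (is.null(names(cohorts))) names(cohorts) <- sprintf("cohort_%d", seq_along(cohorts))
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(common) < 2) stop("fewer than 2 genes shared across cohorts")
  if (is.null(gene_subset)) {
    v <- rowMeans(vapply(cohorts, function(m) {
      apply(m[common, , drop = FALSE], 1, var, na.rm = TRUE)
    }, numeric(length(common))))
    gene_subset <- common[order(-v, common)][seq_len(min(top_var, length(common)))]
  } else {
    missing <- setdiff(gene_subset, common)
    if (length(missing)) stop("subset genes absent from some cohort: ",
                              paste(missing, collapse = ", "))
  }

  tables <- lapply(seq_along(cohorts), function(ci) {
    all_pairs_pvalues(cohorts[[ci]], n_perm = n_perm,
                      seed = (seed + 131L * ci) %% 2147483647L,
                      gene_subset = gene_subset)
  })
  key <- function(tb) paste(tb$gene_a, tb$gene_b, sep = "\r")
  keys <- Reduce(intersect, lapply(tables, key))
  n_dropped <- length(unique(unlist(lapply(tables, key)))) - length(keys)
  if (n_dropped > 0) message(n_dropped, " edge(s) not testable in every cohort; omitted")

  pmat <- vapply(tables, function(tb) tb$p[match(keys, key(tb))],
                 numeric(length(keys)))
  pmat <- matrix(pmat, nrow = length(keys))
  colnames(pmat) <- paste0("p_", names(cohorts))
  ics <- -2 * rowSums(log(pmat))

  pool <- as.numeric(pmat)
  null_ics <- sort(resampling_null_ics(pool, k = ncol(pmat),
                                     n_resample = n_resample,
                                     seed = (seed + 9973L) %% 2147483647L))
  exceed <- n_resample - findInterval(ics - 1e-12, null_ics)
  meta_p <- (1 + exceed) / (n_resample + 1)

  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(gene_a = ab[, 1], gene_b = ab[, 2], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pmat))
  out$ics <- ics
  out$meta_p <- meta_p
  out$q <- bh_fdr(meta_p)
  out
}

#' Significant edges at an FDR threshold
#'
#' Keeps edges with `q < q_threshold`, weighted by their ICS (larger =
#' stronger evidence), sorted by weight descending with lexicographic
#' tie-break on (gene_a, gene_b).
#'
#' @param edge_stats output of [edge_meta_analysis()] (needs `q` and `ics`).
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame `gene_a`, `gene_b`, `weight`; possibly empty.
#' @export
significant_edges <- function(edge_stats, q_threshold = 0.05) {
  stopifnot(all(c("gene_a", "gene_b", "ics", "q") %in% names(edge_stats)))
  keep <- edge_stats[edge_stats$q < q_threshold, , drop = FALSE]
  keep <- keep[order(-keep$ics, keep$gene_a, keep$gene_b), , drop = FALSE]
  data.frame(gene_a = keep$gene_a, gene_b = keep$gene_b, weight = keep$ics,
             row.names = NULL, stringsAsFactors = FALSE)
}
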