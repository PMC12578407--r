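# Shared fixtures and independent oracles, built in code at test time.

# small labelled expression matrix
make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fast small study for smoke tests
tiny_spec <- function(seed = 1, ...) {
  synthetic_study_spec(
    n_cohorts = 2, samples_per_cohort = 30,
    modules = list(
      list(module_id = "M1", n_members = 8, rho = 0.7),
      list(module_id = "M2", n_members = 8, rho = 0.7)
    ),
    n_background_genes = 20, seed = seed, ...
  )
}

# edge data.frame from an integer edge matrix
edges_from_matrix <- function(em, weights = NULL) {
  data.frame(
    gene_a = sprintf("n%02d", em[, 1]),
    gene_b = sprintf("n%02d", em[, 2]),
    weight = weights %||% rep(1, nrow(em)),
    stringsAsFactors = FALSE
  )
}

complete_graph_edges <- function(n, weights = NULL) {
  em <- t(combn(n, 2))
  edges_from_matrix(em, weights %||% seq(nrow(em), 1))
}

# independent permutation enumerator (distinct from the package's):
# element-removal recursion, computing |cor| for every permutation of y
oracle_exhaustive_pvalue <- function(x, y) {
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (tail in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], tail)
    }
    out
  }
  rs <- vapply(perms_of(y), function(v) abs(cor(x, v)), numeric(1))
  mean(rs >= abs(cor(x, y)) - 1e-9)
}

# brute-force hypergeometric upper tail by enumerating all draws
oracle_hypergeom_tail <- function(overlap, set_size, draw_size, universe_size) {
  universe <- seq_len(universe_size)
  inset <- seq_len(set_size)
  draws <- combn(universe, draw_size)
  hits <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(hits >= overlap)
}

# step-by-step running-sum GSEA oracle (weight exponent 1)
oracle_gsea_es <- function(scores, hit) {
  n <- length(scores)
  nr <- sum(abs(scores[hit]))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + abs(scores[[i]]) / nr else run - 1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
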