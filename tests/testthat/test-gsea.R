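# Hypergeometric annotation, the weighted-KS GSEA engine and the
# prognostic-signature status classifier.

test_that("hypergeometric tail is exact against brute-force draw enumeration", {
  expect_equal(hypergeometric_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeometric_tail(3, 5, 3, 10), 10 / 120)
  expect_equal(hypergeometric_tail(2, 12, 5, 12), 1) # set = universe
  set.seed(41)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    m <- sample(2:(N - 1), 1)
    k <- sample(2:(N - 1), 1)
    ov <- sample(0:min(m, k), 1)
    expect_equal(hypergeometric_tail(ov, m, k, N),
                 oracle_hypergeom_tail(ov, m, k, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_tail(4, 3, 5, 10), "inconsistent")
})

test_that("module annotation covers trivial and extreme overlaps", {
  uni <- sprintf("u%02d", 1:20)
  sets <- list(
    A = list(name = "A", description = "", genes = uni[1:5]),
    B = list(name = "B", description = "", genes = uni[6:10])
  )
  # module disjoint from every set
  ann <- annotate_modules(list(mod1 = uni[11:15]), sets, uni)
  expect_true(all(ann$p == 1))
  # module identical to one set: p = 1 / C(N, m)
  ann2 <- annotate_modules(list(mod1 = uni[1:5]), sets, uni)
  expect_equal(ann2$p[ann2$gene_set == "A"], 1 / choose(20, 5))
  expect_error(annotate_modules(list(m = uni[1:2]), sets, character(0)), "universe")
})

test_that("gene ranking is by mean difference with documented tie handling", {
  t0 <- make_expr(matrix(1, 4, 3), genes = c("d", "b", "a", "c"))
  r0 <- make_expr(matrix(1, 4, 3), genes = c("d", "b", "a", "c"))
  rk <- rank_genes(t0, r0)
  expect_true(all(rk == 0))
  expect_identical(names(rk), c("a", "b", "c", "d")) # id tie-break
  t1 <- t0; t1["b", ] <- t1["b", ] + 2
  rk1 <- rank_genes(t1, r0)
  expect_identical(names(rk1)[1], "b")
  expect_equal(unname(rk1[1]), 2)
  # ranking order is invariant under common per-sample additive shifts
  set.seed(42)
  t2 <- make_expr(matrix(rnorm(40), 8, 5))
  r2 <- make_expr(matrix(rnorm(40), 8, 5))
  for (i in 1:3) {
    shifted <- sweep(t2, 2, runif(5, -3, 3), "+")
    expect_identical(names(rank_genes(shifted, r2)), names(rank_genes(t2, r2)))
  }
})

test_that("enrichment score matches the hand-tabulated running sum", {
  scores <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2, g6 = -3)
  res <- gsea_enrichment_score(scores, c("g1", "g3"))
  expect_equal(res$es, oracle_gsea_es(scores, names(scores) %in% c("g1", "g3")))
  expect_equal(res$es, 0.75)
  expect_equal(res$running_sum,
               c(0.75, 0.5, 0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  # extreme positions
  expect_equal(gsea_enrichment_score(scores, "g1")$es, 1)
  expect_equal(gsea_enrichment_score(scores, "g6")$es, -1)
  expect_error(gsea_enrichment_score(scores, "nope"), "intersect")
  expect_error(gsea_enrichment_score(scores, names(scores)), "universe")
})

test_that("weight exponent 0 reduces to the classical KS statistic", {
  set.seed(43)
  for (i in 1:5) {
    scores <- sort(rnorm(20), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:20)
    hit <- names(scores) %in% sample(names(scores), 6)
    res <- gsea_enrichment_score(scores, names(scores)[hit], weight_exponent = 0)
    # direct unweighted running sum
    inc <- ifelse(hit, 1 / sum(hit), -1 / sum(!hit))
    run <- cumsum(inc)
    expect_equal(res$es, run[which.max(abs(run))], tolerance = 1e-12)
  }
})

test_that("enrichment score stays in [-1, 1] and the running sum closes at 0", {
  set.seed(44)
  for (i in 1:10) {
    scores <- sort(rnorm(30), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:30)
    set_n <- sample(2:10, 1)
    res <- gsea_enrichment_score(scores, sample(names(scores), set_n),
                                 weight_exponent = sample(c(0, 1, 2), 1))
    expect_lte(abs(res$es), 1 + 1e-12)
    expect_equal(res$running_sum[length(res$running_sum)], 0, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(45)
  for (i in 1:5) {
    scores <- sort(rnorm(40), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:40)
    setg <- sample(names(scores), 8)
    mine <- gsea_enrichment_score(scores, setg, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(scores, selectedStats = which(names(scores) %in% setg),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("GSEA significance is degenerate-safe and detects a planted shift", {
  set.seed(46)
  base <- make_expr(matrix(rnorm(100 * 12), 100, 12))
  test <- base[, 1:6]; ref <- base[, 7:12]
  colnames(test) <- paste0("t", 1:6); colnames(ref) <- paste0("r", 1:6)
  # identical matrices: ties everywhere, p = 1
  same <- gsea_significance(test, test, list(s = rownames(base)[1:20]),
                            n_perm = 100, seed = 1)
  expect_equal(same$p, 1)
  # planted +2 shift on a 25-gene set
  hot <- rownames(base)[1:25]
  test2 <- test; test2[hot, ] <- test2[hot, ] + 2
  res <- gsea_significance(test2, ref, list(hot = hot, cold = rownames(base)[26:50]),
                           n_perm = 200, seed = 2)
  expect_identical(res$direction[res$gene_set == "hot"], "induced")
  expect_lt(res$q[res$gene_set == "hot"], 0.05)
  expect_identical(attr(res, "permutation_type"), "sample")
  # small groups fall back to gene-set permutation
  res2 <- gsea_significance(test2[, 1:2], ref[, 1:2], list(hot = hot),
                            n_perm = 100, seed = 3)
  expect_identical(attr(res2, "permutation_type"), "gene_set")
  expect_error(gsea_significance(test, ref, list(s = hot), n_perm = 5), "n_perm")
})

test_that("signature status calls poor, good and intermediate as constructed", {
  set.seed(47)
  genes <- sprintf("g%03d", 1:150)
  sig <- signature_definition("pls", poor_genes = genes[1:30],
                              good_genes = genes[31:60])
  base <- make_expr(matrix(rnorm(150 * 24), 150, 24), genes = genes)
  labels <- rep(c("injured", "reference"), each = 12)
  injured <- plant_signature_response(base, sig, labels, delta = 2)
  test <- injured[, labels == "injured"]
  ref <- injured[, labels == "reference"]
  st <- signature_status(test, ref, sig, n_perm = 200, seed = 1)
  expect_identical(st$call, "poor")
  # reversal: knock the planted effect back out of the injured samples
  reversed <- plant_signature_response(injured, sig, labels, delta = -4)
  st2 <- signature_status(reversed[, labels == "injured"], ref, sig,
                          n_perm = 200, seed = 1)
  expect_identical(st2$call, "good")
  # no perturbation: intermediate
  st3 <- signature_status(ref, ref, sig, n_perm = 200, seed = 1)
  expect_identical(st3$call, "intermediate")
})

test_that("housekeeping z-scoring normalizes rows and absorbs sample shifts", {
  set.seed(48)
  m <- make_expr(matrix(rnorm(8 * 10, mean = 8), 8, 10))
  hk <- c("g01", "g02")
  z <- zscore_log2_housekeeping(m, hk)
  expect_equal(unname(rowMeans(z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 8), tolerance = 1e-12)
  shifted <- m; shifted[, 3] <- shifted[, 3] + 5
  expect_equal(zscore_log2_housekeeping(shifted, hk), z, tolerance = 1e-12)
  m2 <- m # a row constant after housekeeping centering
  m2["g05", ] <- colMeans(m2[hk, , drop = FALSE]) + 1
  expect_warning(z2 <- zscore_log2_housekeeping(m2, hk), "constant")
  expect_true(all(z2["g05", ] == 0))
  expect_error(zscore_log2_housekeeping(m, character(0)), "empty")
})
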