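# Permutation correlation testing, Fisher ICS combination, resampling null
# and the significant-edge filter.

test_that("exhaustive permutation p matches brute-force enumeration", {
  # only the identity and the full reversal of 3 points reach |r| = 1
  expect_equal(permutation_correlation_pvalue(c(1, 2, 3), c(1, 2, 3),
                                              exhaustive = TRUE), 2 / 6)
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(
      permutation_correlation_pvalue(x, y, exhaustive = TRUE),
      oracle_exhaustive_pvalue(x, y)
    )
  }
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(permutation_correlation_pvalue(x, y, exhaustive = TRUE),
               oracle_exhaustive_pvalue(x, y))
})

test_that("random permutation p agrees with the exhaustive value up to the add-one convention", {
  set.seed(21)
  for (i in 1:3) {
    x <- rnorm(6); y <- rnorm(6)
    p_ex <- permutation_correlation_pvalue(x, y, exhaustive = TRUE)
    p_rand <- permutation_correlation_pvalue(x, y, n_perm = 4000, seed = i)
    expect_lt(abs(p_rand - p_ex), 0.05)
  }
})

test_that("degenerate correlation inputs raise explicit errors", {
  expect_error(permutation_correlation_pvalue(1:5, rep(2, 5)), "constant")
  expect_error(permutation_correlation_pvalue(1:5, 1:4), "mismatch")
  expect_error(permutation_correlation_pvalue(1:2, 2:1), "at least 3")
})

test_that("Fisher ICS matches its closed form", {
  expect_equal(fisher_ics(c(1, 1, 1)), 0)
  expect_equal(fisher_ics(exp(-1)), 2)
  expect_equal(fisher_ics(c(0.05, 0.01)), 15.2018049190844, tolerance = 1e-10)
  expect_error(fisher_ics(c(0.5, 0)), "0, 1")
  expect_error(fisher_ics(numeric(0)), "empty")
})

test_that("resampling null p-value handles degenerate cases as documented", {
  expect_equal(resampling_null_pvalue(0, runif(50), k = 3, n_resample = 200,
                                      seed = 1), 1)
  # single repeated pool value: every resampled ICS ties the observed one
  cval <- 0.3
  expect_equal(
    resampling_null_pvalue(-2 * 3 * log(cval), rep(cval, 10), k = 3,
                           n_resample = 500, seed = 1), 1)
  expect_error(resampling_null_pvalue(1, numeric(0), k = 2), "empty")
})

test_that("BH adjustment reproduces the step-up enumeration and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.05)), c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # raising any raw p never lowers any q
  set.seed(5)
  p <- runif(20)
  q0 <- bh_fdr(p)
  p2 <- p; p2[7] <- min(1, p2[7] + 0.2)
  expect_true(all(bh_fdr(p2) >= q0 - 1e-12))
  # invariant under input reordering (modulo order restoration)
  ord <- sample(20)
  expect_equal(bh_fdr(p[ord])[order(ord)], q0)
})

test_that("all-pairs table enumerates C(n,2) pairs deterministically", {
  set.seed(2)
  m <- make_expr(matrix(rnorm(4 * 12), 4, 12))
  t1 <- all_pairs_pvalues(m, n_perm = 100, seed = 9)
  t2 <- all_pairs_pvalues(m, n_perm = 100, seed = 9)
  expect_equal(nrow(t1), choose(4, 2))
  expect_identical(t1, t2)
  expect_true(all(t1$gene_a < t1$gene_b))
  expect_true(all(t1$p > 0 & t1$p <= 1))
})

test_that("pair p-values do not depend on which other genes are present", {
  set.seed(3)
  m <- make_expr(matrix(rnorm(5 * 15), 5, 15))
  full <- all_pairs_pvalues(m, n_perm = 200, seed = 4)
  sub <- all_pairs_pvalues(m, n_perm = 200, seed = 4, gene_subset = c("g01", "g03"))
  expect_equal(
    sub$p,
    full$p[full$gene_a == "g01" & full$gene_b == "g03"]
  )
})

test_that("a noise-free planted module attains the minimum achievable p", {
  spec <- synthetic_study_spec(
    n_cohorts = 1, samples_per_cohort = 25,
    modules = list(list(module_id = "M1", n_members = 5, rho = 0.9)),
    n_background_genes = 3, noise_sd = 1e-7, driver_loading = 1, seed = 6
  )
  sim <- generate_multi_cohort(spec)
  members <- names(sim$truth$module_assignment)[sim$truth$module_assignment == "M1"]
  tb <- all_pairs_pvalues(sim$cohorts[[1]], n_perm = 99, seed = 1,
                          gene_subset = members)
  expect_true(all(tb$p == 1 / 100))
})

test_that("pairs with too few complete observations are dropped and logged", {
  m <- make_expr(matrix(rnorm(3 * 10), 3, 10))
  m[1, 1:8] <- NA # only 2 complete obs against any other gene
  expect_message(tb <- all_pairs_pvalues(m, n_perm = 50, seed = 1), "dropped")
  expect_equal(nrow(tb), 1) # only g02--g03 testable
  expect_equal(length(attr(tb, "dropped")), 2)
})

test_that("significant_edges filters, weights and orders edges", {
  es <- data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    ics = c(10, 30, 30), q = c(0.2, 0.01, 0.01), stringsAsFactors = FALSE
  )
  expect_equal(nrow(significant_edges(es, q_threshold = 0.001)), 0)
  all_edges <- significant_edges(es, q_threshold = 1.0000001)
  expect_equal(nrow(all_edges), 3)
  kept <- significant_edges(es, q_threshold = 0.05)
  expect_equal(kept$gene_a, c("a", "b")) # equal weight: lexicographic tie-break
  expect_equal(kept$weight, c(30, 30))
})

test_that("meta-analysis combines cohorts and flags planted edges", {
  spec <- synthetic_study_spec(
    n_cohorts = 3, samples_per_cohort = 30,
    modules = list(
      list(module_id = "M1", n_members = 8, rho = 0.7),
      list(module_id = "M2", n_members = 8, rho = 0.7)
    ),
    n_background_genes = 20, seed = 12
  )
  sim <- generate_multi_cohort(spec)
  es <- edge_meta_analysis(sim$cohorts, n_perm = 100, n_resample = 2000, seed = 12)
  expect_named(es, c("gene_a", "gene_b", "p_cohort_1", "p_cohort_2", "p_cohort_3",
                     "ics", "meta_p", "q"))
  expect_equal(nrow(es), choose(36, 2))
  expect_equal(es$ics,
               -2 * (log(es$p_cohort_1) + log(es$p_cohort_2) + log(es$p_cohort_3)))
  truth <- sim$truth$module_assignment
  within <- truth[es$gene_a] != "background" & truth[es$gene_a] == truth[es$gene_b]
  sig <- es$q < 0.05
  expect_gt(mean(sig[within]), 0.95)
  expect_lt(mean(sig[!within]), 0.05)
})
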