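# Synthetic multi-cohort generator: determinism, planted correlation
# structure, signature planting and fixture serialization.

test_that("identical spec and seed reproduce byte-identical cohorts", {
  s1 <- generate_multi_cohort(tiny_spec(seed = 7))
  s2 <- generate_multi_cohort(tiny_spec(seed = 7))
  expect_identical(s1, s2)
  s3 <- generate_multi_cohort(tiny_spec(seed = 8))
  expect_false(identical(s1$cohorts, s3$cohorts))
})

test_that("adding a cohort does not perturb earlier cohorts", {
  spec2 <- tiny_spec(seed = 3)
  spec3 <- synthetic_study_spec(
    n_cohorts = 3, samples_per_cohort = 30,
    modules = spec2$modules, n_background_genes = 20, seed = 3
  )
  s2 <- generate_multi_cohort(spec2)
  s3 <- generate_multi_cohort(spec3)
  expect_identical(s2$cohorts$cohort_1, s3$cohorts$cohort_1)
  expect_identical(s2$cohorts$cohort_2, s3$cohorts$cohort_2)
})

test_that("noise-free limit with beta = 1 drives within-module correlations to 1", {
  spec <- synthetic_study_spec(
    n_cohorts = 1, samples_per_cohort = 40,
    modules = list(list(module_id = "M1", n_members = 6, rho = 0.5)),
    n_background_genes = 0, driver_loading = 1, noise_sd = 1e-7, seed = 2
  )
  m <- generate_multi_cohort(spec)$cohorts[[1]]
  cc <- cor(t(m))
  expect_true(all(cc[upper.tri(cc)] > 0.999))
})

test_that("within-module correlation clearly exceeds module-background correlation", {
  # Monte-Carlo over 20 seeds at rho = 0.7, 100 samples
  gaps <- vapply(1:20, function(s) {
    spec <- synthetic_study_spec(
      n_cohorts = 1, samples_per_cohort = 100,
      modules = list(list(module_id = "M1", n_members = 8, rho = 0.7)),
      n_background_genes = 12, batch_shift_sd = 0, seed = s
    )
    sim <- generate_multi_cohort(spec)
    m <- sim$cohorts[[1]]
    members <- names(sim$truth$module_assignment)[sim$truth$module_assignment == "M1"]
    bg <- setdiff(rownames(m), members)
    cc <- cor(t(m))
    within <- cc[members, members][upper.tri(diag(length(members)))]
    cross <- cc[members, bg]
    mean(within) - mean(abs(cross))
  }, numeric(1))
  expect_gt(mean(gaps), 0.4)
})

test_that("the driver is the member most correlated with the rest of its module", {
  for (s in 1:5) {
    spec <- synthetic_study_spec(
      n_cohorts = 1, samples_per_cohort = 80,
      modules = list(list(module_id = "M1", n_members = 10, rho = 0.6)),
      n_background_genes = 0, seed = s
    )
    sim <- generate_multi_cohort(spec)
    m <- sim$cohorts[[1]]
    cc <- abs(cor(t(m))); diag(cc) <- NA
    strongest <- rownames(m)[which.max(rowMeans(cc, na.rm = TRUE))]
    expect_identical(strongest, sim$truth$driver_genes$M1)
  }
})

test_that("signature planting is exactly additive and zero-delta is the identity", {
  set.seed(1)
  m <- make_expr(matrix(rnorm(200), 10, 20))
  sig <- signature_definition("toy", poor_genes = c("g01", "g02"),
                              good_genes = c("g03", "g04"))
  labels <- rep(c("injured", "reference"), each = 10)
  expect_identical(plant_signature_response(m, sig, labels, delta = 0), m)
  planted <- plant_signature_response(m, sig, labels, delta = 3)
  diff <- planted - m
  expect_equal(unname(rowMeans(diff[sig$poor_genes, labels == "injured"])), c(3, 3))
  expect_equal(unname(rowMeans(diff[sig$good_genes, labels == "injured"])), c(-3, -3))
  expect_true(all(diff[, labels == "reference"] == 0))
  expect_true(all(diff[c("g05", "g06"), ] == 0))
})

test_that("signature planting validates labels and gene membership", {
  m <- make_expr(matrix(0, 4, 4), genes = c("a", "b", "c", "d"))
  sig <- signature_definition("toy", "a", "b")
  expect_error(plant_signature_response(m, sig, rep("weird", 4), 1), "unknown")
  sig2 <- signature_definition("toy", "zz", "b")
  expect_error(plant_signature_response(m, sig2, rep("injured", 4), 1), "absent")
})

test_that("fixtures round-trip exactly and checksums track content", {
  sim <- generate_multi_cohort(tiny_spec(seed = 5))
  sig <- signature_definition("pls_like",
                              poor_genes = sprintf("P%03d", 1:73),
                              good_genes = sprintf("G%03d", 1:113))
  d1 <- withr::local_tempdir()
  man1 <- write_fixtures(sim$cohorts, sim$truth, d1, signature = sig)
  back <- read_expression_tsv(file.path(d1, "cohort_1.tsv"))
  expect_equal(back, sim$cohorts$cohort_1, tolerance = 1e-12)

  # identical content -> identical checksums; changed content -> changed checksum
  d2 <- withr::local_tempdir()
  man2 <- write_fixtures(sim$cohorts, sim$truth, d2, signature = sig)
  expect_identical(man1$md5, man2$md5)
  sim$cohorts$cohort_1[1, 1] <- sim$cohorts$cohort_1[1, 1] + 1
  d3 <- withr::local_tempdir()
  man3 <- write_fixtures(sim$cohorts, sim$truth, d3, signature = sig)
  expect_false(man3$md5[1] == man1$md5[1])
  expect_identical(man3$md5[2], man1$md5[2])

  # the two-subset signature GMT re-reads with subset sizes 73 and 113
  sets <- read_gmt(file.path(d1, "signature.gmt"))
  expect_identical(lengths(lapply(sets, `[[`, "genes")),
                   c(pls_like_POOR = 73L, pls_like_GOOD = 113L))
})

test_that("spec validation rejects impossible designs", {
  expect_error(synthetic_study_spec(modules = list(
    list(module_id = "M1", n_members = 5, rho = 1)
  )), "rho")
  expect_error(synthetic_study_spec(samples_per_cohort = 0))
  expect_error(synthetic_study_spec(noise_sd = 0))
})
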