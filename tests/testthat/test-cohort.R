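# A quick synthetic cohort from the analytic ground-truth oracle.
gt_cohort <- function(n = 30, seed = 200) {
  memo(paste0("gt_cohort_", n, "_", seed), {
    recs <- lapply(seq_len(n), function(i)
      ground_truth_traits(make_phantom_spec(seed + i, phantom_ranges("fruit"))))
    for (i in seq_along(recs)) recs[[i]]$sample_id <- sprintf("s%02d", i)
    trait_matrix(recs)
  })
}

test_that("Pearson matrix follows closed forms and is symmetric", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(1, 0, 1), d = c(5, 1, 4))
  pm <- pearson_matrix(m)
  expect_equal(diag(pm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(pm$p), rep(0, 4), ignore_attr = TRUE)
  expect_equal(pm$r["a", "b"], 1)
  expect_equal(pm$r["a", "c"], 0)
  expect_identical(pm$r, t(pm$r))
  expect_identical(pm$p, t(pm$p))
  expect_error(pearson_matrix(m[1:2, ]), "3 samples")
  expect_warning(pearson_matrix(cbind(m, e = c(2, 2, 2))), "zero-variance")
  # p-values agree with cor.test
  ct <- cor.test(m[, "a"], m[, "d"])
  expect_equal(pm$p["a", "d"], ct$p.value)
})

test_that("size traits of a phantom cohort correlate like real fruit", {
  m <- gt_cohort()
  pm <- pearson_matrix(m)
  expect_gt(pm$r["FW", "FV"], 0.9)   # planted size factor recovered
  expect_gt(pm$r["FL", "FV"], 0.7)
  expect_gt(pm$r["FV", "FSA"], 0.9)
  expect_true(pm$sig01["FW", "FV"])
})

test_that("PCA reproduces the correlation-matrix eigenstructure", {
  m <- gt_cohort()
  p <- trait_pca(m)
  expect_true(all(diff(p$evr_all) <= 1e-12))
  expect_equal(sum(p$evr_all), 1)
  ev <- eigen(cor(m), symmetric = TRUE)$values   # independent oracle
  expect_equal(p$evr_all, ev / ncol(m), tolerance = 1e-10)
  # orthonormal loadings, exact reconstruction at full rank
  expect_equal(crossprod(p$loadings), diag(ncol(m)), ignore_attr = TRUE)
  expect_equal(p$scores %*% t(p$loadings), scale(m), ignore_attr = TRUE,
               tolerance = 1e-8)
  # deterministic sign: dominant loading of every component positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # rank-1 data concentrates all variance in one component
  f <- rnorm(20)
  r1 <- sapply(1:14, function(j) f * j)
  colnames(r1) <- trait_names()
  expect_equal(trait_pca(r1)$evr_all[1], 1)
  expect_error(trait_pca(m, n_components = 15), "exceeds")
  expect_error(trait_pca(m[1:3, ]), "4 samples")
})

test_that("three planted latent factors concentrate 80% of the variance", {
  set.seed(5)
  n <- 60
  f <- matrix(rnorm(3 * n), n, 3)
  load <- matrix(rnorm(3 * 14), 3, 14)
  m <- f %*% load + 0.15 * matrix(rnorm(14 * n), n, 14)
  colnames(m) <- trait_names()
  p <- trait_pca(m)
  expect_gte(sum(p$evr_all[1:3]), 0.80)
})

test_that("composite scoring weights components by explained variance", {
  m <- gt_cohort()
  p <- trait_pca(m)
  s1 <- composite_score(p, n_dims = 1)
  expect_identical(s1$sample_id,
                   rownames(p$scores)[order(-p$scores[, 1], rownames(p$scores))])
  s3 <- composite_score(p, n_dims = 3)
  w <- p$explained_variance_ratio[1:3] / sum(p$explained_variance_ratio[1:3])
  expect_equal(s3$score[s3$sample_id == "s01"],
               sum(p$scores["s01", 1:3] * w))
  expect_error(composite_score(trait_pca(m, 2), n_dims = 3), "exceeds")
  # affine rescaling of one trait leaves the standardized ranking unchanged
  m2 <- m; m2[, "FV"] <- m2[, "FV"] * 3.7 + 100
  expect_identical(composite_score(trait_pca(m2), 3)$sample_id, s3$sample_id)
})

test_that("min-max normalization maps columns onto [0, 1]", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(0, 0.5, 1))
  rownames(m) <- c("x", "y", "z")
  expect_warning(nm <- minmax_normalize(m), "constant")
  expect_equal(unname(nm[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm[, "b"]), c(0, 0, 0))
  expect_equal(minmax_normalize(nm[, c("a", "c")]), nm[, c("a", "c")])
  expect_error(minmax_normalize(m, subset = "x"), "at least 2")
  sub <- minmax_normalize(m[, c("a", "c")], subset = c("x", "y"))
  expect_equal(unname(sub[, "a"]), c(0, 1))
})
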