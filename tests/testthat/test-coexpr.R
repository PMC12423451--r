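test_that("filter_low_expression rejects degenerate input", {
  expect_error(filter_low_expression(matrix(numeric(0), nrow = 0)), "empty")
  m <- matrix(c(0.1, 0.2, NA, 0.1), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  expect_error(filter_low_expression(m), "missing")
  m2 <- matrix(0.1, nrow = 2, ncol = 10,
               dimnames = list(c("a", "b"), NULL))
  expect_error(filter_low_expression(m2), "all genes removed")
})

test_that("expression_cv supports both conventions", {
  m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  cv <- expression_cv(m, coexpr_config())
  expect_equal(unname(cv["g1"]), sd(c(1, 2, 3, 4)) / 2.5)
  expect_equal(unname(cv["g2"]), 0)
  inv <- expression_cv(m, coexpr_config(cv_convention = "mean_over_sd"))
  expect_equal(unname(inv["g1"]), 2.5 / sd(c(1, 2, 3, 4)))
  expect_true(is.na(inv["g2"]))
})

test_that("module_eigengene is unit-norm and tracks the module profile", {
  set.seed(31)
  base <- sin(seq(0, 2 * pi, length.out = 24))
  mat <- t(replicate(15, 5 + 2 * base + rnorm(24, 0, 0.1)))
  rownames(mat) <- sprintf("g%02d", 1:15)
  e <- tfcoop:::module_eigengene(mat)
  expect_equal(sum(e^2), 1)
  expect_gt(cor(e, colMeans(mat)), 0.99)
})

test_that("detect_modules recovers planted structure and merges duplicates", {
  set.seed(32)
  ## two modules peaking in different thirds of the samples: in the
  ## unsigned network anti-correlated profiles would merge, so the
  ## planted profiles are only mildly correlated
  profiles <- list(rep(c(1, 0, 0), each = 10), rep(c(0, 1, 0), each = 10))
  mat <- do.call(rbind, lapply(1:2, function(m)
    t(replicate(25, 5 + 2 * scale(profiles[[m]])[, 1] + rnorm(30, 0, 0.3)))))
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  cfg <- coexpr_config(min_module_size = 10)
  tom <- compute_tom(mat, 6)
  ms <- detect_modules(tom, cfg, mat)
  expect_true(all(c("M1", "M2") %in% ms$modules))
  truth <- rep(c("A", "B"), each = 25)
  expect_gte(mclust::adjustedRandIndex(truth, ms$modules), 0.9)
  ## at most a couple of noisy genes may drop to the background
  expect_lte(sum(ms$modules == "grey"), 2L)
  ## eigengenes are one column per final module, one row per sample
  expect_identical(dim(ms$eigengenes), c(30L, 2L))

  ## tissue profiles: each planted module peaks in its own tissue half
  colnames(mat) <- sprintf("S%02d", 1:30)
  rownames(ms$eigengenes) <- colnames(mat)
  md <- data.frame(sample = colnames(mat),
                   tissue = rep(c("leaf", "peel", "seed"), each = 10))
  prof <- module_tissue_profile(ms, md)
  expect_identical(sort(colnames(prof$profile)), c("leaf", "peel", "seed"))
  expect_identical(sort(unname(prof$top_tissue)), c("leaf", "peel"))
})
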