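test_that("the printed ROC worked example is reproduced step by step", {
  ex <- roc_example()
  r <- auc_rank(as.matrix(ex[, c("i", "j")]), labels = ex$label,
                trace = TRUE)
  tr <- r$trace[[1]]
  # cumulative true/false-positive table after the descending sort
  expect_equal(tr$trace$value,
               c(3.4, 1.6, 0.8, 0.5, 0.1, -0.2, -0.3, -0.8, -1.4, -2.1))
  expect_equal(tr$trace$tp, c(0, 1, 1, 1, 2, 2, 3, 4, 4, 4) / 4)
  expect_equal(tr$trace$fp, c(1, 1, 2, 3, 3, 4, 4, 4, 5, 6) / 6)
  expect_equal(tr$Y, c(0.125, 0.25, 0.25, 0.375, 0.5, 0.625, 0.875, 1, 1))
  expect_equal(tr$X, c(0, 1, 1, 0, 1, 0, 0, 1, 1) / 6)
  expect_equal(tr$auc, 0, tolerance = 1e-12)
  # the second feature agrees with exhaustive pair counting
  expect_equal(r$trace[[2]]$auc, oracle_auc(ex$j, ex$label))
})

test_that("perfect separation reaches the maximal z-value", {
  y <- rep(c(TRUE, FALSE), c(4, 6))
  x <- c(10, 9, 8, 7, 1:6)
  expect_equal(auc_rank(cbind(x), labels = y)$auc, 0.5)
})

test_that("the control reference standardizes as specified", {
  set.seed(15)
  X <- cbind(a = rnorm(1000, 5, 2), b = runif(1000), c = rep(3, 1000))
  fm <- feature_matrix(X, data.frame(feature = colnames(X),
                                     channel = "Cz", band = "delta"),
                       data.frame(subject_id = sprintf("C%04d", 1:1000),
                                  condition = "EC", group = "control"))
  expect_warning(ref <- fit_reference(fm), "zero-variance")
  expect_equal(ref$features, c("a", "b"))
  expect_equal(ref$mu[["a"]], 5, tolerance = 5 * 2 / sqrt(1000))
  expect_equal(ref$sigma[["a"]], 2, tolerance = 0.2)
  # controls standardized by their own reference: mean 0, sd 1
  std <- standardize(fm, ref)
  expect_equal(unname(colMeans(std$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, sd)), c(1, 1),
               tolerance = 1e-12)
  # closed forms
  ref2 <- ref; ref2$mu[] <- 0; ref2$sigma[] <- 1
  expect_equal(standardize(fm, ref2)$values, fm$values[, 1:2])
  shifted <- fm
  shifted$values <- cbind(a = rep(ref$mu[["a"]] + 2 * ref$sigma[["a"]], 1000),
                          b = rep(ref$mu[["b"]] + 2 * ref$sigma[["b"]], 1000),
                          c = 3)
  expect_true(all(abs(standardize(shifted, ref)$values - 2) < 1e-12))
})

test_that("ranking is invariant to monotone transforms and antisymmetric", {
  set.seed(16)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rep(c(TRUE, FALSE), 20)
  r0 <- auc_rank(X, labels = y)
  r_mono <- auc_rank(exp(X / 2), labels = y)      # strictly increasing
  expect_identical(r_mono$auc, r0$auc)
  r_neg <- auc_rank(-X, labels = y)
  expect_equal(r_neg$auc, -r0$auc)
  expect_identical(r_neg$order, r0$order)
  expect_error(auc_rank(X, labels = rep(TRUE, 40)), "class")
})

test_that("correlation pruning keeps only the best-ranked of a redundant pair", {
  set.seed(17)
  x <- rnorm(60)
  y <- rep(c(TRUE, FALSE), 30)
  X <- cbind(f1 = x + y, f2 = x + y, f3 = rnorm(60), f4 = rnorm(60))
  r <- auc_rank(X, labels = y)
  pruned <- prune_correlated(r, X, r_max = 0.9)
  expect_true(sum(pruned$retained %in% c(1, 2)) == 1)
  expect_equal(pruned$retained[1], r$order[1])
  # independent columns all survive; r_max > 1 disables pruning entirely
  Xi <- matrix(rnorm(500 * 8), 500)
  ri <- auc_rank(Xi, labels = rep(c(TRUE, FALSE), 250))
  expect_length(prune_correlated(ri, Xi, r_max = 0.9)$retained, 8)
  expect_length(prune_correlated(r, X, r_max = 1 + 1e-9)$retained, 4)
})

test_that("take_top returns rank-ordered indices and enforces bounds", {
  set.seed(18)
  X <- matrix(rnorm(30 * 20), 30)
  r <- auc_rank(X, labels = rep(c(TRUE, FALSE), 15))
  expect_identical(take_top(r, 15), r$order[1:15])
  expect_length(take_top(r, 0), 0)
  expect_identical(take_top(r, 20), r$order)
  expect_error(take_top(r, 21), "exceeds")
})

test_that("mRMR prefers relevant, non-redundant features", {
  set.seed(19)
  y <- rep(c(TRUE, FALSE), 60)
  informative <- as.numeric(y) + rnorm(120, sd = 0.3)
  X <- cbind(label_copy = as.numeric(y),
             label_dup = as.numeric(y),
             indep = informative,
             noise = rnorm(120))
  sel <- mrmr_select(X, 3, labels = y)
  expect_equal(sel[1], 1)            # the label column is maximally relevant
  expect_false(sel[2] == 2)          # its duplicate is pure redundancy
  expect_identical(sort(mrmr_select(X, 4, labels = y)), 1:4)
  expect_error(mrmr_select(X, 9, labels = y), "exceeds")
})
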