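test_that("the KS gate accepts standard normal and rejects gross misfits", {
  set.seed(32)
  rejections <- sapply(1:100, function(k) ks_normality(rnorm(10000)))
  expect_gte(mean(rejections == 0), 0.9)       # nominal 5% level
  expect_identical(ks_normality(runif(500, 0, 10)), 1L)
  expect_warning(out <- ks_normality(rep(2, 20)), "constant")
  expect_identical(out, 1L)
  expect_error(ks_normality(rnorm(3)), "n >= 5")
})

test_that("identical groups produce an all-blue map", {
  X <- matrix(rep(rnorm(19), each = 20), 20, 19)   # same data both groups
  fm <- channel_fm(X, groups = rep(c("R", "NR"), 10))
  mp <- wilcoxon_channel_map(fm)
  expect_true(all(mp$H == 0))
  expect_true(all(mp$p == 1))
})

test_that("a planted single-channel shift is detected with high power", {
  set.seed(33)
  f7 <- match("F7", montage_1020())
  hits <- 0; off_rates <- numeric(100)
  for (k in 1:100) {
    X <- matrix(rnorm(34 * 19), 34, 19)
    groups <- rep(c("R", "NR"), 17)
    X[groups == "R", f7] <- X[groups == "R", f7] + 3
    mp <- wilcoxon_channel_map(channel_fm(X, groups))
    hits <- hits + mp$H[mp$channel == "F7"]
    off_rates[k] <- mean(mp$H[mp$channel != "F7"])
  }
  expect_gte(hits / 100, 0.95)
  expect_lt(median(off_rates), 0.12)   # off-channel rate near the 5% level
})

test_that("rank-sum p-values agree with exact enumeration at small n", {
  set.seed(34)
  for (k in 1:8) {
    n1 <- sample(4:6, 1); n2 <- sample(4:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = sample(c(0, 1.5), 1))
    p_pkg <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(p_pkg, oracle_ranksum_p(a, b), tolerance = 1e-12)
  }
  # the map uses the same statistic: monotone transforms change nothing
  X <- matrix(rnorm(20 * 19), 20, 19)
  fm1 <- channel_fm(X, rep(c("R", "NR"), 10))
  fm2 <- channel_fm(exp(X), rep(c("R", "NR"), 10))
  expect_equal(wilcoxon_channel_map(fm1)$p, wilcoxon_channel_map(fm2)$p)
})

test_that("stratification restricts instances and skips empty strata", {
  set.seed(35)
  X <- matrix(rnorm(40 * 19), 40, 19)
  fm <- channel_fm(X, groups = rep(c("R", "NR"), 20),
                   sexes = rep(c("F", "M"), each = 20),
                   conditions = rep(c("EC", "EO"), 20))
  mp_f <- wilcoxon_channel_map(fm, stratum_sex = "F")
  expect_s3_class(mp_f, "topo_map")
  expect_identical(unname(attr(mp_f, "stratum")["sex"]), "F")
  fm_f_only <- channel_fm(X[1:20, ], groups = rep(c("R", "NR"), 10),
                          sexes = rep("F", 20))
  expect_warning(out <- wilcoxon_channel_map(fm_f_only, stratum_sex = "M"),
                 "empty stratum")
  expect_null(out)
})

test_that("the interpolated field is exact at electrodes and on constants", {
  X <- matrix(rnorm(20 * 19), 20, 19)
  groups <- rep(c("R", "NR"), 10)
  mp <- wilcoxon_channel_map(channel_fm(X, groups))
  mp$H <- rep(0L, 19)
  f0 <- interpolate_topomap(mp)
  expect_true(all(f0$z[!is.na(f0$z)] == 0))
  mp$H <- rep(1L, 19)
  f1 <- interpolate_topomap(mp)
  expect_true(all(f1$z[!is.na(f1$z)] == 1))
  # nodal exactness: put the grid through an electrode coordinate
  mp$H <- sample(c(0L, 1L), 19, replace = TRUE)
  coords <- montage_coordinates()
  cz <- which(coords$channel == "Cz")            # Cz sits at the origin
  f <- interpolate_topomap(mp, grid_n = 41)      # odd grid contains (0, 0)
  i0 <- which(abs(f$x) < 1e-9)
  expect_equal(f$z[i0, i0], mp$H[mp$channel == "Cz"])
})

test_that("PCA scatter reports scores and variance fractions", {
  set.seed(36)
  # points on an exact 2-D plane embedded in 6 dimensions
  B <- matrix(rnorm(12), 6, 2)
  S <- matrix(rnorm(140), 70, 2)
  Xp <- S %*% t(B)
  p <- pca_scatter(Xp)
  expect_equal(sum(p$variance_explained[1:2]), 1, tolerance = 1e-9)
  # isotropic Gaussian in 15 dimensions: each share near 1/15
  Xi <- matrix(rnorm(3000 * 15), 3000, 15)
  pi_ <- pca_scatter(Xi)
  expect_lt(abs(pi_$variance_explained[1] - 1 / 15), 0.02)
  # 68 instances in, 68 coordinate pairs out, centered
  X68 <- matrix(rnorm(68 * 15), 68, 15)
  p68 <- pca_scatter(X68)
  expect_equal(dim(p68$scores), c(68L, 2L))
  expect_equal(unname(colMeans(p68$scores)), c(0, 0), tolerance = 1e-12)
  expect_error(pca_scatter(matrix(1, 10, 3)), "rank")
})
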