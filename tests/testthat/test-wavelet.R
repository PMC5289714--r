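# Single-level db4 coefficients of a fixed 50-sample signal, frozen from
# an independent reference implementation of the symmetric-extension
# transform (first five values of each block).
ref_cA5 <- c(1.52820083982, 1.02589200015, 0.324482786047,
             0.698673285853, 1.32270076067)
ref_cD5 <- c(0.0100691418643, 0.0157474497046, -0.0181821308651,
             -0.00242417963911, -0.00264143475143)

test_that("db4 analysis matches the reference coefficient convention", {
  n <- 50
  x <- sin(2 * pi * 6 * (0:(n - 1)) / 140) +
    0.25 * cos(2 * pi * 1.3 * (0:(n - 1)) / 140 + 0.4)
  d <- dwt_decompose(x, levels = 1, fs = 140)
  expect_equal(length(d$coeff_blocks$A1), 28)   # floor(49/2) + 4
  expect_equal(d$coeff_blocks$A1[1:5], ref_cA5, tolerance = 1e-9)
  expect_equal(d$coeff_blocks$D1[1:5], ref_cD5, tolerance = 1e-9)
})

test_that("block lengths follow the declared recurrence", {
  expect_equal(dwt_block_lengths(8400, 1), 4203)
  set.seed(4)
  for (n in sample(200:5000, 5)) {
    d <- dwt_decompose(rnorm(n), levels = 3, fs = 140)
    expect_equal(unname(sapply(d$coeff_blocks, length)[c("D1", "D2", "D3")]),
                 dwt_block_lengths(n, 3))
    expect_equal(length(d$coeff_blocks$A3), dwt_block_lengths(n, 3)[3])
  }
})

test_that("the inverse transform reconstructs the signal exactly", {
  set.seed(5)
  for (n in c(700, 701, 1203)) {
    x <- rnorm(n)
    d <- dwt_decompose(x, levels = 4, fs = 140)
    r <- dwt_reconstruct(d)
    expect_lt(sqrt(mean((r - x)^2)) / sqrt(mean(x^2)), 1e-8)
  }
})

test_that("in-band sinusoids concentrate energy in the mapped block", {
  x <- sine(6, 140, 20)
  d <- dwt_decompose(x, levels = 4, fs = 140)
  en <- sapply(d$coeff_blocks, function(b) sum(b^2))
  expect_gt(en[["D4"]] / sum(en), 0.8)          # 6 Hz -> theta block
  expect_equal(d$band_map$band[d$band_map$block == "D4"], "theta")
  x2 <- sine(2, 140, 20)
  d2 <- dwt_decompose(x2, levels = 4, fs = 140)
  en2 <- sapply(d2$coeff_blocks, function(b) sum(b^2))
  expect_gt(en2[["A4"]] / sum(en2), 0.8)        # 2 Hz -> delta block
})

test_that("coefficient energy matches signal energy on smooth signals", {
  # orthogonal filters: energy preserved within 1% away from boundaries
  x <- sine(3, 140, 120) + 0.5 * sine(11, 140, 120, phase = 1)
  d <- dwt_decompose(x, levels = 4, fs = 140)
  expect_equal(sum(sapply(d$coeff_blocks, function(b) sum(b^2))),
               sum(x^2), tolerance = 0.01)
})

test_that("band_coefficients concatenates and tags the requested blocks", {
  n <- 8400
  x <- rnorm(n)
  d <- dwt_decompose(x, levels = 4, fs = 140)
  all_bands <- band_coefficients(d, bands = d$band_map$band, channel = "F3")
  expect_equal(length(all_bands$values),
               sum(sapply(d$coeff_blocks, length)))
  dt <- band_coefficients(d, c("delta", "theta"), channel = "F3")
  lens <- dwt_block_lengths(n, 4)
  expect_equal(length(dt$values), 2 * lens[4])
  expect_setequal(unique(dt$meta$band), c("delta", "theta"))
  expect_true(all(dt$meta$channel == "F3"))
  empty <- band_coefficients(d, character(0))
  expect_length(empty$values, 0)
  expect_error(band_coefficients(d, "ripple"), "unknown band")
})

test_that("matrix decomposition equals per-column decomposition", {
  set.seed(6)
  X <- matrix(rnorm(600 * 3), 600, 3)
  dm <- dwt_decompose(X, levels = 2, fs = 140)
  for (j in 1:3) {
    dj <- dwt_decompose(X[, j], levels = 2, fs = 140)
    expect_equal(dm$coeff_blocks$A2[, j], dj$coeff_blocks$A2)
    expect_equal(dm$coeff_blocks$D1[, j], dj$coeff_blocks$D1)
  }
})

test_that("too-short signals are rejected", {
  expect_error(dwt_decompose(rnorm(100), levels = 4), "too short")
})
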