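test_that("psnr identities and formula hold", {
  a <- matrix(runif(64), 8)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(matrix(0, 5, 5), matrix(1, 5, 5), data_range = 1), 0)

  set.seed(2)
  ref <- matrix(runif(120, 0, 2), 10)
  tst <- ref + matrix(rnorm(120, sd = 0.1), 10)
  hand <- 10 * log10(max(ref)^2 / mean((ref - tst)^2))
  expect_equal(psnr(ref, tst), hand, tolerance = 1e-10)

  expect_error(psnr(ref, tst[, 1:6]), "shapes differ")
  expect_error(psnr(matrix(0, 4, 4), matrix(1, 4, 4)), "data_range")
})

# Independent brute-force SSIM: explicit double loop over window positions,
# written against the same published definition but sharing no code with
# the package implementation.
bruteSSIM <- function(ref, tst, w = 7L, L = max(ref)) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (i in seq_len(nrow(ref) - w + 1L))
    for (j in seq_len(ncol(ref) - w + 1L)) {
      x <- tst[i:(i + w - 1L), j:(j + w - 1L)]
      y <- ref[i:(i + w - 1L), j:(j + w - 1L)]
      mx <- mean(x); my <- mean(y)
      vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
      cxy <- mean(x * y) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

test_that("ssim matches the sliding-window oracle and its identities", {
  set.seed(5)
  ref <- matrix(runif(30 * 24), 30)
  tst <- pmax(ref + matrix(rnorm(30 * 24, sd = 0.15), 30), 0)

  expect_equal(ssim(ref, ref), 1)
  expect_equal(ssim(ref, tst, data_range = 1),
               ssim(tst, ref, data_range = 1), tolerance = 1e-12)
  expect_lte(ssim(ref, tst), 1)
  expect_equal(ssim(ref, tst), bruteSSIM(ref, tst), tolerance = 1e-8)

  # downscaled pair (2x coarser) against the same oracle
  half <- function(m) (m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
                         m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]) / 2
  expect_equal(ssim(half(ref), half(tst)),
               bruteSSIM(half(ref), half(tst)), tolerance = 1e-8)

  expect_error(ssim(ref, tst[, 1:6]), "shapes differ")
  expect_error(ssim(ref[1:5, 1:5], tst[1:5, 1:5]), "window")
})

test_that("ssim gradient agrees with finite differences", {
  set.seed(7)
  ref <- matrix(runif(15 * 12), 15)
  tst <- matrix(runif(15 * 12), 15)
  g <- XLCTsynth:::.ssimGrad(ref, tst, window = 7L, data_range = 1)
  eps <- 1e-6
  for (i in sample(length(tst), 10L)) {
    up <- tst; up[i] <- up[i] + eps
    dn <- tst; dn[i] <- dn[i] - eps
    num <- (ssim(ref, up, data_range = 1) -
              ssim(ref, dn, data_range = 1)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("composite loss identities hold across the alpha range", {
  set.seed(9)
  x <- matrix(runif(20 * 15), 20)
  for (a in c(0, 0.25, 0.8, 1))
    expect_equal(compositeLoss(x, x, a), 0)

  y <- matrix(runif(20 * 15), 20)
  expect_equal(compositeLoss(x, y, 0), mean(abs(x - y)))

  # alpha = 1 on constant images differing by the full data range:
  # loss = 1 - SSIM from the independent oracle
  c0 <- matrix(0, 12, 12); c1 <- matrix(1, 12, 12)
  expect_equal(compositeLoss(c1, c0, 1, data_range = 1),
               1 - bruteSSIM(c0, c1, L = 1), tolerance = 1e-12)

  expect_error(compositeLoss(x, y[, 1:5], 0.5), "shapes differ")
  expect_error(compositeLoss(x, y, 1.4), "alpha")
})

test_that("composite loss gradient agrees with finite differences", {
  set.seed(11)
  x <- matrix(runif(15 * 12), 15)
  y <- matrix(runif(15 * 12), 15)
  g <- XLCTsynth:::.compositeLossGrad(x, y, 0.8)
  eps <- 1e-6
  for (i in sample(length(x), 8L)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    num <- (compositeLoss(up, y, 0.8) - compositeLoss(dn, y, 0.8)) /
      (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})
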