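# Naive direct 3x3 "same" convolution, quadruple loop, as the oracle for
# the batched GEMM-based kernels.
naiveConv <- function(X, W, b, H, Wd, B) {
  C <- ncol(X); F <- ncol(W)
  Y <- matrix(rep(b, each = nrow(X)), nrow(X), F)
  for (bb in seq_len(B)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    row <- (bb - 1L) * H * Wd + (j - 1L) * H + i
    for (k in 0:8) {
      di <- k %% 3L - 1L; dj <- k %/% 3L - 1L
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > H || jj < 1L || jj > Wd) next
      src <- (bb - 1L) * H * Wd + (jj - 1L) * H + ii
      for (cc in seq_len(C))
        Y[row, ] <- Y[row, ] + X[src, cc] * W[k * C + cc, ]
    }
  }
  Y
}

test_that("the convolution kernel matches the naive oracle", {
  set.seed(3)
  H <- 5L; Wd <- 4L; C <- 3L; F <- 2L; B <- 2L
  X <- matrix(rnorm(B * H * Wd * C), B * H * Wd, C)
  W <- matrix(rnorm(9 * C * F), 9 * C, F)
  b <- rnorm(F)
  expect_equal(XLCTsynth:::.conv2d_fw(X, W, b, H, Wd, B),
               naiveConv(X, W, b, H, Wd, B), tolerance = 1e-12)
})

test_that("convolution gradients agree with finite differences", {
  set.seed(4)
  H <- 5L; Wd <- 4L; C <- 2L; F <- 3L; B <- 2L
  X <- matrix(rnorm(B * H * Wd * C), B * H * Wd, C)
  W <- matrix(rnorm(9 * C * F, sd = 0.3), 9 * C, F)
  b <- rnorm(F)
  R <- matrix(rnorm(B * H * Wd * F), B * H * Wd, F)  # random cotangent
  lossOf <- function(Xv, Wv, bv)
    sum(XLCTsynth:::.conv2d_fw(Xv, Wv, bv, H, Wd, B) * R)
  g <- XLCTsynth:::.conv2d_bw(X, W, R, H, Wd, B)
  eps <- 1e-6
  for (i in sample(length(X), 6L)) {
    up <- X; up[i] <- up[i] + eps; dn <- X; dn[i] <- dn[i] - eps
    expect_equal(g$dX[i], (lossOf(up, W, b) - lossOf(dn, W, b)) / (2 * eps),
                 tolerance = 1e-6)
  }
  for (i in sample(length(W), 6L)) {
    up <- W; up[i] <- up[i] + eps; dn <- W; dn[i] <- dn[i] - eps
    expect_equal(g$dW[i], (lossOf(X, up, b) - lossOf(X, dn, b)) / (2 * eps),
                 tolerance = 1e-6)
  }
  expect_equal(g$db, colSums(R), tolerance = 1e-12)
})

test_that("end-to-end network gradients agree with finite differences", {
  set.seed(5)
  H <- 12L; Wd <- 10L
  params <- XLCTsynth:::.netInit(3L)
  params[[17L]]$W <- matrix(rnorm(9 * 32, sd = 0.05), 9 * 32, 1L)
  U <- matrix(runif(H * Wd), ncol = 1L)
  Y <- matrix(runif(H * Wd), H, Wd)
  lossOf <- function(p) {
    fw <- XLCTsynth:::.netForward(p, U, H, Wd, 1L)
    compositeLoss(matrix(fw$pred, H, Wd), Y, 0.7)
  }
  fw <- XLCTsynth:::.netForward(params, U, H, Wd, 1L, keep = TRUE)
  dP <- matrix(as.vector(XLCTsynth:::.compositeLossGrad(
    matrix(fw$pred, H, Wd), Y, 0.7)), ncol = 1L)
  gr <- XLCTsynth:::.netBackward(params, fw, dP, H, Wd, 1L)
  eps <- 1e-6
  for (li in c(1L, 6L, 13L, 17L)) for (rep in 1:3) {
    i <- sample(length(params[[li]]$W), 1L)
    up <- params; up[[li]]$W[i] <- up[[li]]$W[i] + eps
    dn <- params; dn[[li]]$W[i] <- dn[[li]]$W[i] - eps
    num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    expect_equal(gr[[li]]$dW[i], num, tolerance = 1e-4)
  }
})

test_that("view upsampling preserves nodes and averages neighbors", {
  pair <- syntheticPair(1L, n_det = 2L)
  few <- pair$few
  up <- upsampleViews(few)
  expect_equal(viewAngles(up), seq(0, 174, by = 6))
  # measured angles preserved exactly
  expect_identical(sinoValues(up)[seq(1L, 30L, 2L), , ],
                   sinoValues(few))
  # inserted interior rows equal the mean of their angular neighbors
  for (k in 1:14) {
    direct <- (sinoValues(few)[k, , ] + sinoValues(few)[k + 1L, , ]) / 2
    expect_equal(sinoValues(up)[2L * k, , ], direct, tolerance = 1e-12)
  }
  # wrap row: mean of the last view and the translation-reversed first view
  flipped <- sinoValues(few)[1L, rev(seq_len(dim(few@values)[2L])), ]
  expect_equal(sinoValues(up)[30L, , ],
               (sinoValues(few)[15L, , ] + flipped) / 2, tolerance = 1e-12)

  # constant sinogram stays constant
  const <- few
  const@values[] <- 3
  expect_true(all(sinoValues(upsampleViews(const)) == 3))

  expect_error(upsampleViews(few, 37L), "not a superset")
})

test_that("forward mapping has the contract shape and residual identity", {
  ph <- deskPhantom(8L)
  few <- simulateScan(ph, beamSpec(n_views = 15L))
  fresh <- new("ViewSynthModel", params = XLCTsynth:::.netInit(2L),
               config = netConfig(), history = data.frame(),
               normalization = list(mode = "per-sinogram-max"),
               input_shape = c(15L, 50L))
  out <- predictSinogram(fresh, few)
  expect_identical(dim(sinoValues(out)), c(30L, 50L, 3L))
  expect_true(all(is.finite(sinoValues(out))))
  # zero-initialized correction branch reproduces the interpolation exactly
  expect_identical(sinoValues(out), sinoValues(upsampleViews(few)))

  # all-zero input stays finite with the right shape
  zfew <- few; zfew@values[] <- 0
  zout <- predictSinogram(fresh, zfew)
  expect_identical(dim(sinoValues(zout)), c(30L, 50L, 3L))
  expect_true(all(is.finite(sinoValues(zout))))

  short <- subsetViews(few, 1:10)
  expect_error(predictSinogram(fresh, short), "does not match")
})

test_that("training reduces the loss and is seed-deterministic", {
  pairs <- lapply(1:6, syntheticPair, n_trans = 12L)
  m1 <- trainViewSynth(pairs, netConfig(seed = 9L), epochs = 4L,
                       batch_size = 4L, warmup = 0L, adam_eps = 1e-8,
                       val_frac = 0, test_frac = 0)
  h1 <- trainingHistory(m1)
  expect_true(all(is.finite(h1$train_loss)))
  expect_lt(h1$train_loss[nrow(h1)], h1$train_loss[1L])

  m2 <- trainViewSynth(pairs, netConfig(seed = 9L), epochs = 4L,
                       batch_size = 4L, warmup = 0L, adam_eps = 1e-8,
                       val_frac = 0, test_frac = 0)
  expect_identical(trainingHistory(m2), h1)
})

test_that("the network can memorize two pairs", {
  pairs <- lapply(1:2, syntheticPair, n_trans = 10L)
  up <- upsampleViews(pairs[[1L]]$few)
  init_loss <- mean(vapply(1:2, function(i) {
    u <- upsampleViews(pairs[[i]]$few)
    sc <- max(sinoValues(pairs[[i]]$few))
    compositeLoss(sinoValues(u)[, , 1L] / sc,
                  sinoValues(pairs[[i]]$full)[, , 1L] / sc, 0.8)
  }, numeric(1L)))
  # two-stage schedule: the l1 term's sign gradient gives Adam an
  # oscillation floor proportional to the learning rate, so the tail of
  # the memorization runs at a decayed rate
  m <- trainViewSynth(pairs, netConfig(seed = 1L), epochs = 600L,
                      batch_size = 2L, adam_eps = 1e-8, warmup = 40L,
                      val_frac = 0, test_frac = 0)
  m <- trainViewSynth(pairs, netConfig(seed = 1L), epochs = 250L,
                      batch_size = 2L, lr = 1e-4, adam_eps = 1e-8,
                      warmup = 0L, val_frac = 0, test_frac = 0, init = m)
  m <- trainViewSynth(pairs, netConfig(seed = 1L), epochs = 150L,
                      batch_size = 2L, lr = 2e-5, adam_eps = 1e-8,
                      warmup = 0L, val_frac = 0, test_frac = 0, init = m)
  h <- trainingHistory(m)
  final <- h$train_loss[nrow(h)]
  expect_lt(final, 1e-3 * init_loss)
})

test_that("checkpoints round-trip the model", {
  pairs <- lapply(1:2, syntheticPair, n_trans = 10L)
  m <- trainViewSynth(pairs, netConfig(seed = 2L), epochs = 1L,
                      batch_size = 2L, val_frac = 0, test_frac = 0)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  back <- loadModel(f)
  expect_identical(back@params, m@params)
  expect_identical(trainingHistory(back), trainingHistory(m))
  expect_identical(back@input_shape, m@input_shape)
  expect_true(file.exists(paste0(f, ".json")))
  # resumed training appends history
  m2 <- trainViewSynth(pairs, netConfig(seed = 2L), epochs = 1L,
                       batch_size = 2L, val_frac = 0, test_frac = 0,
                       init = back)
  expect_identical(trainingHistory(m2)$epoch, c(1L, 2L))
})
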