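#' Construct a view-synthesis network configuration
#'
#' The architecture is fixed (stem 3x3/64, four residual blocks of three
#' 3x3/64 convolutions with an identity shortcut spanning the three layers,
#' then 3x3/64, 3x3/64, 3x3/32 and a single-filter 3x3 output convolution;
#' ReLU after every layer except the output). The network predicts a
#' residual correction added to the linearly view-interpolated sinogram, so
#' with zero output weights it reproduces the interpolation exactly; the
#' output convolution is initialized to zero for that reason.
#'
#' @param loss_alpha composite-loss weighting factor (see
#'   [compositeLoss()]).
#' @param upsample_mode pre-interpolation along the view axis ("linear").
#' @param seed integer seed for initialization, splitting and batching.
#' @return a [NetConfig-class] object.
#' @export
netConfig <- function(loss_alpha = 0.8, upsample_mode = "linear",
                      seed = 1L) {
  new("NetConfig", loss_alpha = loss_alpha, upsample_mode = upsample_mode,
      seed = as.integer(seed))
}

## Layer table: 1 stem, 4 blocks x 3 convs, 4 tail convs (last linear).
.netLayerDims <- function() {
  cin <- c(1, rep(64, 12), 64, 64, 64, 32)
  cout <- c(64, rep(64, 12), 64, 64, 32, 1)
  list(cin = cin, cout = cout, n = length(cin))
}

## He-normal initialization; the output convolution starts at zero so the
## untrained network is exactly the view interpolation.
.netInit <- function(seed) {
  dims <- .netLayerDims()
  withSeed(seed, lapply(seq_len(dims$n), function(i) {
    cin <- dims$cin[i]; cout <- dims$cout[i]
    W <- if (i == dims$n) matrix(0, 9 * cin, cout)
    else matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                9 * cin, cout)
    list(W = W, b = numeric(cout))
  }))
}

## Forward pass on a stacked batch U ((B*H*W) x 1). Returns the prediction
## and, when keep = TRUE, the activation cache needed by .netBackward.
.netForward <- function(params, U, H, W, B, keep = FALSE,
                        single = FALSE) {
  xin <- vector("list", 17L)   # input fed to each conv layer
  act <- vector("list", 17L)   # post-activation output of each layer
  conv <- function(i, x) .conv2d_fw(x, params[[i]]$W, params[[i]]$b,
                                    H, W, B, single)
  xin[[1L]] <- U
  h <- conv(1L, U); h[h < 0] <- 0
  act[[1L]] <- h
  for (blk in 0:3) {
    i <- 2L + 3L * blk
    xin[[i]] <- h
    a1 <- conv(i, h); a1[a1 < 0] <- 0; act[[i]] <- a1
    xin[[i + 1L]] <- a1
    a2 <- conv(i + 1L, a1); a2[a2 < 0] <- 0; act[[i + 1L]] <- a2
    xin[[i + 2L]] <- a2
    z3 <- conv(i + 2L, a2)
    h <- z3 + h; h[h < 0] <- 0
    act[[i + 2L]] <- h
  }
  for (i in 14:16) {
    xin[[i]] <- h
    h <- conv(i, h); h[h < 0] <- 0
    act[[i]] <- h
  }
  xin[[17L]] <- h
  corr <- conv(17L, h)
  pred <- U + corr
  if (keep) list(pred = pred, corr = corr, xin = xin, act = act)
  else list(pred = pred, corr = corr)
}

## Backward pass; dPred is the loss gradient at the prediction. Returns a
## list of per-layer gradients (dW, db).
.netBackward <- function(params, cache, dPred, H, W, B,
                         single = FALSE) {
  grads <- vector("list", 17L)
  bw <- function(i, dy) .conv2d_bw(cache$xin[[i]], params[[i]]$W, dy,
                                   H, W, B, single)
  g <- bw(17L, dPred)
  grads[[17L]] <- list(dW = g$dW, db = g$db)
  da <- g$dX
  for (i in 16:14) {
    dz <- da * (cache$act[[i]] > 0)
    g <- bw(i, dz)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    da <- g$dX
  }
  for (blk in 3:0) {
    i <- 2L + 3L * blk
    ds <- da * (cache$act[[i + 2L]] > 0)   # through the post-shortcut ReLU
    g3 <- bw(i + 2L, ds)
    grads[[i + 2L]] <- list(dW = g3$dW, db = g3$db)
    dz2 <- g3$dX * (cache$act[[i + 1L]] > 0)
    g2 <- bw(i + 1L, dz2)
    grads[[i + 1L]] <- list(dW = g2$dW, db = g2$db)
    dz1 <- g2$dX * (cache$act[[i]] > 0)
    g1 <- bw(i, dz1)
    grads[[i]] <- list(dW = g1$dW, db = g1$db)
    da <- g1$dX + ds                       # conv path + identity shortcut
  }
  dz <- da * (cache$act[[1L]] > 0)
  g <- bw(1L, dz)
  grads[[1L]] <- list(dW = g$dW, db = g$db)
  grads
}

#' Interpolate a sinogram to a denser view grid
#'
#' Linear interpolation along the view axis onto the full-view angle grid
#' (the measured angular span divided into \code{target_n_views} steps).
#' Original views are preserved exactly at their angles; for the default
#' doubling every inserted view is the mean of its two angular neighbors.
#' At the 180-degree wrap the neighbor beyond the last measured view is the
#' first view with the translation axis reversed (approximate parallel-beam
#' periodicity; see the package vignette).
#'
#' @param few a [Sinogram-class].
#' @param target_n_views target view count (default double the input).
#' @param mode interpolation mode ("linear").
#' @return a [Sinogram-class] with \code{target_n_views} views.
#' @examples
#' s <- simulateScan(makePhantom(targets = sphericalTarget(c(0, 0, 10), 2, 1)),
#'                   beamSpec(n_translations = 10L, n_views = 5L))
#' viewAngles(upsampleViews(s))
#' @export
upsampleViews <- function(few, target_n_views = 2L * length(few@angles),
                          mode = "linear") {
  mode <- match.arg(mode, "linear")
  a_few <- few@angles
  nv <- length(a_few)
  if (nv < 2L) stop("upsampleViews: at least two views are required")
  span <- (a_few[2L] - a_few[1L]) * nv
  a_new <- (seq_len(target_n_views) - 1L) * (span / target_n_views)
  pos <- match(round(a_few, 9L), round(a_new, 9L))
  if (any(is.na(pos)))
    stop("upsampleViews: target angle grid is not a superset of the ",
         "measured angles (", target_n_views, " views over ", span,
         " deg)")
  d <- dim(few@values)
  out <- array(0, dim = c(target_n_views, d[2L], d[3L]))
  out[pos, , ] <- few@values
  wrap_row <- few@values[1L, rev(seq_len(d[2L])), , drop = FALSE]
  for (t in seq_len(target_n_views)) {
    if (t %in% pos) next
    a <- a_new[t]
    i0 <- max(which(a_few < a))
    lower <- few@values[i0, , , drop = FALSE]
    if (i0 == nv) { upper <- wrap_row; a1 <- span }
    else { upper <- few@values[i0 + 1L, , , drop = FALSE]
           a1 <- a_few[i0 + 1L] }
    wt <- (a - a_few[i0]) / (a1 - a_few[i0])
    out[t, , ] <- (1 - wt) * lower[1L, , ] + wt * upper[1L, , ]
  }
  new("Sinogram", values = out, angles = a_new, offsets = few@offsets,
      detector_offsets = few@detector_offsets, noise = few@noise)
}

#' Deterministic train/validation/test split of phantom pairs
#'
#' Pairs are permuted with the given seed and partitioned into validation,
#' test and training sets by phantom, so all detector channels of a phantom
#' land in the same split. Used by [trainViewSynth()] and by the validation
#' pipeline to recover the held-out phantoms.
#'
#' @param n_pairs number of phantom pairs.
#' @param seed integer seed (the network seed).
#' @param val_frac,test_frac held-out fractions.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
splitPairs <- function(n_pairs, seed, val_frac = 0.1, test_frac = 0.1) {
  withSeed(seed, {
    perm <- sample(n_pairs)
    n_val <- floor(val_frac * n_pairs)
    n_test <- floor(test_frac * n_pairs)
    n_held <- n_val + n_test
    list(val = perm[seq_len(n_val)],
         test = perm[n_val + seq_len(n_test)],
         train = if (n_held) perm[-seq_len(n_held)] else perm)
  })
}

## Per-channel training samples from a few/full sinogram pair, both scaled
## by the few-view sinogram maximum.
.pairSamples <- function(few, full) {
  if (!isTRUE(all.equal(dim(few@values)[2:3], dim(full@values)[2:3])))
    stop("training pair has mismatched translations/detectors")
  if (!all(round(few@angles, 9L) %in% round(full@angles, 9L)))
    stop("training pair angle sets are not nested")
  up <- upsampleViews(few, length(full@angles))
  scale <- max(few@values)
  if (scale <= 0) scale <- 1
  lapply(seq_len(dim(few@values)[3L]), function(d)
    list(U = up@values[, , d] / scale, Y = full@values[, , d] / scale))
}

#' Train the view-synthesis network
#'
#' Gradient-based minimization of the composite SSIM + l1 loss between the
#' network output and the full-view target over paired few-view/full-view
#' sinograms, using Adam. Pairs are split by phantom into
#' train/validation/test fractions; the three detector channels of a pair
#' are independent single-channel samples sharing the network weights.
#' Training is deterministic given the seed in \code{config}.
#'
#' @param pairs list of pairs, each \code{list(few = , full = )} of
#'   [Sinogram-class] objects with nested angle grids.
#' @param config a [netConfig()] object.
#' @param epochs training epochs.
#' @param batch_size samples per gradient step.
#' @param lr Adam learning rate.
#' @param adam_eps Adam denominator constant. The default 1e-3 is larger
#'   than the textbook 1e-8 so that early steps stay proportional to the
#'   gradient: with a zero-initialized output convolution, sign-like Adam
#'   steps would otherwise inject a large random correction in the first
#'   epoch that short training runs never recover from.
#' @param warmup gradient steps over which the learning rate ramps
#'   linearly from zero (same motivation).
#' @param val_frac,test_frac phantom fractions held out for validation and
#'   testing (the test fraction is simply never trained on).
#' @param init optional [ViewSynthModel-class] to resume from; its history
#'   is appended to.
#' @param verbose print per-epoch losses.
#' @return a [ViewSynthModel-class]. When a validation split exists, the
#'   returned parameters are those of the epoch with the lowest validation
#'   loss (early-stopping checkpoint selection); the history still records
#'   every epoch.
#' @export
trainViewSynth <- function(pairs, config = netConfig(), epochs = 200L,
                           batch_size = 8L, lr = 1e-3, val_frac = 0.1,
                           test_frac = 0.1, adam_eps = 1e-3, warmup = 20L,
                           init = NULL, verbose = FALSE) {
  if (length(pairs) < 2L)
    stop("trainViewSynth: at least two training pairs are required")
  splits <- splitPairs(length(pairs), config@seed, val_frac, test_frac)
  samples <- lapply(pairs, function(p) .pairSamples(p$few, p$full))
  train_s <- do.call(c, samples[splits$train])
  val_s <- if (length(splits$val)) do.call(c, samples[splits$val]) else
    list()
  H <- nrow(train_s[[1L]]$U); W <- ncol(train_s[[1L]]$U)
  params <- if (is.null(init)) .netInit(config@seed) else init@params
  mstate <- lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
  alpha <- config@loss_alpha
  beta1 <- 0.9; beta2 <- 0.999; eps <- adam_eps
  step <- 0L
  batchLoss <- function(idx, learn) {
    B <- length(idx)
    U <- do.call(rbind, lapply(train_s[idx], function(s)
      matrix(s$U, ncol = 1L)))
    fw <- .net_fw_fast(params, U, H, W, B, keep = learn)
    loss <- 0
    dPred <- if (learn) matrix(0, nrow(U), 1L) else NULL
    for (b in seq_len(B)) {
      rows <- (b - 1L) * H * W + seq_len(H * W)
      P <- matrix(fw$pred[rows, 1L], H, W)
      Yb <- train_s[[idx[b]]]$Y
      loss <- loss + compositeLoss(P, Yb, alpha)
      if (learn)
        dPred[rows, 1L] <- as.vector(
          .compositeLossGrad(P, Yb, alpha)) / B
    }
    if (learn) {
      grads <- .net_bw_fast(fw$state, dPred)
      step <<- step + 1L
      lr_t <- if (step <= warmup) lr * step / (warmup + 1L) else lr
      corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
      for (i in seq_along(params)) {
        s <- mstate[[i]]; g <- grads[[i]]
        s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
        s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
        s$mb <- beta1 * s$mb + (1 - beta1) * g$db
        s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
        params[[i]]$W <<- params[[i]]$W -
          lr_t * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
        params[[i]]$b <<- params[[i]]$b -
          lr_t * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
        mstate[[i]] <<- s
      }
    }
    loss / B
  }
  evalLoss <- function(ss) {
    if (!length(ss)) return(NA_real_)
    tot <- 0
    for (s in ss) {
      fw <- .net_fw_fast(params, matrix(s$U, ncol = 1L), H, W, 1L,
                         keep = FALSE)
      tot <- tot + compositeLoss(matrix(fw$pred, H, W), s$Y, alpha)
    }
    tot / length(ss)
  }
  history <- if (!is.null(init)) init@history else
    data.frame(epoch = integer(), train_loss = numeric(),
               val_loss = numeric())
  epoch0 <- if (nrow(history)) max(history$epoch) else 0L
  best_params <- params
  best_val <- Inf
  withSeed(config@seed + 1L, for (ep in seq_len(epochs)) {
    ord <- sample(length(train_s))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- mean(vapply(batches, batchLoss, numeric(1L), learn = TRUE))
    if (!is.finite(ep_loss))
      stop("trainViewSynth: non-finite training loss at epoch ",
           epoch0 + ep, call. = FALSE)
    vl <- evalLoss(val_s)
    if (is.finite(vl) && vl < best_val) {
      best_val <- vl
      best_params <- params
    }
    history <- rbind(history,
                     data.frame(epoch = epoch0 + ep, train_loss = ep_loss,
                                val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.5g val %.5g", epoch0 + ep,
                      ep_loss, vl))
  })
  if (is.finite(best_val)) params <- best_params
  new("ViewSynthModel", params = params, config = config,
      history = history,
      normalization = list(mode = "per-sinogram-max"),
      input_shape = c(dim(pairs[[1L]]$few@values)[1L], W))
}

#' Synthesize a full-view sinogram from a few-view measurement
#'
#' Upsamples the few-view sinogram to the full view grid by linear angular
#' interpolation, normalizes by the sinogram maximum, applies the trained
#' residual correction to each detector channel independently, clips
#' negative values to zero and restores the original scale. The measured
#' views are data-consistent: the output rows at the measured angles are
#' the measured readings themselves, so the network only fills the
#' inserted views.
#'
#' @param model a trained [ViewSynthModel-class].
#' @param few a [Sinogram-class] matching the trained input shape.
#' @return a [Sinogram-class] with twice the views.
#' @export
predictSinogram <- function(model, few) {
  d <- dim(few@values)
  if (d[1L] != model@input_shape[1L] || d[2L] != model@input_shape[2L])
    stop("predictSinogram: input shape (", d[1L], ", ", d[2L],
         ") does not match the trained configuration (",
         model@input_shape[1L], ", ", model@input_shape[2L], ")")
  up <- upsampleViews(few, 2L * d[1L])
  scale <- max(few@values)
  if (scale <= 0) scale <- 1
  H <- dim(up@values)[1L]; W <- d[2L]
  out <- up@values
  meas <- match(round(few@angles, 9L), round(up@angles, 9L))
  for (k in seq_len(d[3L])) {
    U <- matrix(up@values[, , k] / scale, ncol = 1L)
    fw <- .netForward(model@params, U, H, W, 1L)
    synth <- pmax(up@values[, , k] + matrix(fw$corr, H, W) * scale, 0)
    synth[meas, ] <- few@values[, , k]
    out[, , k] <- synth
  }
  new("Sinogram", values = out, angles = up@angles, offsets = few@offsets,
      detector_offsets = few@detector_offsets, noise = few@noise)
}

#' Save and load view-synthesis model checkpoints
#'
#' The checkpoint is an RDS container holding the parameter state, the
#' network configuration, the normalization record and the training
#' history; a JSON sidecar (\code{<path>.json}) carries the human-readable
#' configuration and history.
#'
#' @param model a [ViewSynthModel-class].
#' @param path checkpoint path.
#' @return \code{loadModel} returns the [ViewSynthModel-class];
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = "XLCTsynth-model-1", params = model@params,
               config = list(loss_alpha = model@config@loss_alpha,
                             upsample_mode = model@config@upsample_mode,
                             seed = model@config@seed),
               history = model@history,
               normalization = model@normalization,
               input_shape = model@input_shape), path)
  jsonlite::write_json(
    list(format = "XLCTsynth-model-1",
         config = list(loss_alpha = model@config@loss_alpha,
                       upsample_mode = model@config@upsample_mode,
                       seed = model@config@seed),
         normalization = model@normalization,
         input_shape = model@input_shape,
         history = model@history),
    paste0(path, ".json"), digits = I(10), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "XLCTsynth-model-1"))
    stop("loadModel: '", path, "' is not a model checkpoint")
  new("ViewSynthModel", params = obj$params,
      config = netConfig(obj$config$loss_alpha, obj$config$upsample_mode,
                         obj$config$seed),
      history = obj$history, normalization = obj$normalization,
      input_shape = as.integer(obj$input_shape))
}
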