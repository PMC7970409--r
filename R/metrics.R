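#' Peak signal-to-noise ratio
#'
#' \eqn{PSNR = 10 \log_{10}(R^2 / MSE)} with data range R and mean squared
#' error between the two images. Identical images give \code{Inf}.
#'
#' @param reference,test numeric matrices (or arrays) of equal shape.
#' @param data_range dynamic range R; defaults to \code{max(reference)}
#'   (ground-truth maximum) and must be positive.
#' @return PSNR in decibels.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(1, 4, 4), data_range = 1)  # 0 dB
#' @export
psnr <- function(reference, test, data_range = max(reference)) {
  if (!all(dim(reference) == dim(test)))
    stop("psnr: image shapes differ")
  if (!is.finite(data_range) || data_range <= 0)
    stop("psnr: data_range must be positive (supply it explicitly for a ",
         "zero reference)")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

## Valid-mode sliding-window sums via two cumulative-sum passes.
.boxSumValid <- function(m, w) {
  cs <- rbind(0, apply(m, 2L, cumsum))
  rs <- cs[(w + 1L):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- cbind(0, t(apply(rs, 1L, cumsum)))
  cs2[, (w + 1L):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

## Adjoint of the valid-mode window sum: scatter each window value back
## over its w x w support.
.boxScatter <- function(m, w, outdim) {
  pad <- matrix(0, outdim[1L] + w - 1L, outdim[2L] + w - 1L)
  pad[w - 1L + seq_len(nrow(m)), w - 1L + seq_len(ncol(m))] <- m
  .boxSumValid(pad, w)
}

## Local SSIM ingredients shared by ssim() and .ssimGrad().
.ssimStats <- function(reference, test, window, data_range) {
  n <- window^2
  mux <- .boxSumValid(test, window) / n
  muy <- .boxSumValid(reference, window) / n
  p <- .boxSumValid(test^2, window) / n
  q <- .boxSumValid(reference^2, window) / n
  r <- .boxSumValid(test * reference, window) / n
  vx <- p - mux^2; vy <- q - muy^2; cxy <- r - mux * muy
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  A1 <- 2 * mux * muy + C1; B1 <- mux^2 + muy^2 + C1
  A2 <- 2 * cxy + C2; B2 <- vx + vy + C2
  list(mux = mux, muy = muy, A1 = A1, B1 = B1, A2 = A2, B2 = B2,
       S = (A1 * A2) / (B1 * B2), n = n)
}

#' Structural similarity index
#'
#' Mean local SSIM over uniform square windows (valid positions only),
#' using the standard stabilized form with constants
#' \eqn{C_1 = (0.01 R)^2}, \eqn{C_2 = (0.03 R)^2} from the data range R and
#' population-normalized local variances. Symmetric in its arguments, equal
#' to 1 iff the images are identical, and at most 1.
#'
#' @param reference,test numeric matrices of equal shape.
#' @param window odd window side length, smaller than either image
#'   dimension.
#' @param data_range dynamic range R; defaults to \code{max(reference)}
#'   with a fallback of 1 for an all-zero reference.
#' @return scalar SSIM value.
#' @examples
#' m <- matrix(runif(100), 10)
#' ssim(m, m)  # 1
#' @export
ssim <- function(reference, test, window = 7L,
                 data_range = NULL) {
  if (!all(dim(reference) == dim(test)))
    stop("ssim: image shapes differ")
  if (window >= min(dim(reference)))
    stop("ssim: window must be smaller than the image")
  if (is.null(data_range)) {
    data_range <- max(reference)
    if (data_range <= 0) data_range <- 1
  }
  st <- .ssimStats(reference, test, window, data_range)
  mean(st$S)
}

## Gradient of mean local SSIM with respect to `test`, same conventions as
## ssim(). Derived by chain rule through the window statistics; each window
## statistic is a window average, whose adjoint is .boxScatter / n.
.ssimGrad <- function(reference, test, window = 7L, data_range = 1) {
  st <- .ssimStats(reference, test, window, data_range)
  Nw <- length(st$S)
  with(st, {
    dS_dm1 <- 2 * muy * A2 / (B1 * B2) -
      2 * mux * A1 * A2 / (B1^2 * B2) +
      2 * mux * S / B2 -
      2 * muy * A1 / (B1 * B2)
    dS_dp <- -S / B2
    dS_dr <- 2 * A1 / (B1 * B2)
    outdim <- dim(test)
    g <- .boxScatter(dS_dm1, window, outdim) +
      2 * test * .boxScatter(dS_dp, window, outdim) +
      reference * .boxScatter(dS_dr, window, outdim)
    g / (n * Nw)
  })
}

#' Composite SSIM + l1 training loss
#'
#' \deqn{L = \alpha\,(1 - SSIM(p, t)) + (1 - \alpha)\,\overline{|p - t|},}
#' the similarity-weighted objective used to train the view-synthesis
#' network: zero iff prediction equals target, decreasing as structural
#' similarity rises, with \eqn{\alpha = 0} reducing to the mean absolute
#' error and \eqn{\alpha = 1} to the SSIM dissimilarity.
#'
#' @param prediction,target numeric matrices of equal shape.
#' @param alpha weighting factor in \[0, 1\].
#' @param data_range dynamic range for the SSIM constants (1 for
#'   max-normalized sinograms).
#' @param window SSIM window side length.
#' @return scalar loss.
#' @examples
#' m <- matrix(runif(200), 10)
#' compositeLoss(m, m, 0.8)  # 0
#' @export
compositeLoss <- function(prediction, target, alpha = 0.8,
                          data_range = 1, window = 7L) {
  if (!all(dim(prediction) == dim(target)))
    stop("compositeLoss: shapes differ")
  if (alpha < 0 || alpha > 1) stop("compositeLoss: alpha must be in [0, 1]")
  l1 <- mean(abs(prediction - target))
  if (alpha == 0) return(l1)
  s <- ssim(target, prediction, window = window, data_range = data_range)
  alpha * (1 - s) + (1 - alpha) * l1
}

## Gradient of compositeLoss with respect to `prediction`.
.compositeLossGrad <- function(prediction, target, alpha = 0.8,
                               data_range = 1, window = 7L) {
  g <- matrix(0, nrow(prediction), ncol(prediction))
  if (alpha > 0)
    g <- g - alpha * .ssimGrad(target, prediction, window = window,
                               data_range = data_range)
  if (alpha < 1)
    g <- g + (1 - alpha) * sign(prediction - target) /
      length(prediction)
  g
}
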