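## Forward differences with Neumann boundary (last row/column zero).
.gradX <- function(u) rbind(u[-1L, , drop = FALSE] -
                            u[-nrow(u), , drop = FALSE], 0)
.gradY <- function(u) cbind(u[, -1L, drop = FALSE] -
                            u[, -ncol(u), drop = FALSE], 0)

## Negative adjoint of the forward-difference gradient.
.divergence <- function(px, py) {
  n <- nrow(px); m <- ncol(px)
  dx <- px
  dx[2:n, ] <- px[2:n, ] - px[1:(n - 1L), ]
  dx[n, ] <- -px[n - 1L, ]
  dx[1L, ] <- px[1L, ]
  dy <- py
  dy[, 2:m] <- py[, 2:m] - py[, 1:(m - 1L)]
  dy[, m] <- -py[, m - 1L]
  dy[, 1L] <- py[, 1L]
  dx + dy
}

#' Isotropic total variation of an image
#'
#' Sum over pixels of the Euclidean norm of the forward-difference gradient.
#'
#' @param u numeric matrix.
#' @return nonnegative scalar.
#' @export
totalVariation <- function(u) sum(sqrt(.gradX(u)^2 + .gradY(u)^2))

## Chambolle dual projection for prox_{tau TV}(g):
## argmin_u ||u - g||^2 / 2 + tau TV(u). Runs in compiled code; the R
## stencils above define the gradient/divergence pair it uses.
.proxTV <- function(g, tau, iters = 20L, sigma = 0.25)
  .prox_tv_cpp(g, tau, as.integer(iters), sigma)

## Largest eigenvalue of t(A) %*% A by (deterministic) power iteration.
.operatorNormSq <- function(A, iters = 30L) {
  x <- rep(1, ncol(A))
  x <- x / sqrt(sum(x^2))
  lam <- 0
  for (i in seq_len(iters)) {
    y <- as.vector(Matrix::crossprod(A, A %*% x))
    lam <- sqrt(sum(y^2))
    if (lam == 0) return(0)
    x <- y / lam
  }
  lam
}

#' TV-regularized iterative reconstruction
#'
#' Reconstructs the scan-slice nanophosphor concentration by approximately
#' minimizing
#' \deqn{\tfrac12 \|A\rho - \Phi\|_2^2 + \lambda \, TV(\rho), \quad \rho \ge 0,}
#' with a monotone FISTA scheme (proximal-gradient steps with a Chambolle
#' inner solve for the isotropic-TV proximal map, nonnegativity projection,
#' and acceptance of an accelerated iterate only when it lowers the
#' objective, so the recorded objective is nonincreasing). Deterministic
#' given its configuration.
#'
#' Because the diffuse-light sensitivity decays exponentially with depth,
#' the columns of A span several orders of magnitude; by default the solver
#' works in sensitivity-normalized variables (each column of A scaled to
#' unit Euclidean norm, the matching voxel rescaling undone on output),
#' the standard preconditioning in diffuse optical reconstruction, without
#' which deep voxels converge impractically slowly. The recorded
#' diagnostics refer to the objective actually minimized (the normalized
#' system when \code{normalize = TRUE}).
#'
#' @param sinogram a [Sinogram-class] whose axis metadata matches \code{A}.
#' @param A a [WeightMatrix-class].
#' @param reg_weight TV regularization weight \eqn{\lambda}; default
#'   \code{1e-2 * max(abs(t(A) phi))} in the solved system (factor chosen
#'   by a logarithmic sweep on seeded phantoms; see the vignette), which
#'   scales
#'   with the data.
#' @param max_iter iteration cap.
#' @param tol relative objective-change stopping tolerance.
#' @param tv_iter Chambolle inner iterations per proximal step.
#' @param normalize apply sensitivity (column-norm) preconditioning.
#' @return a [ReconResult-class].
#' @examples
#' ph <- makePhantom(targets = sphericalTarget(c(3, 0, 10), 2, 1),
#'                   voxel_size = 1)
#' bm <- beamSpec(n_translations = 26L, n_views = 10L)
#' A <- buildWeightMatrix(ph, bm)
#' r <- reconstructTV(simulateScan(ph, bm), A, max_iter = 50L)
#' r
#' @export
reconstructTV <- function(sinogram, A, reg_weight = NULL,
                          max_iter = 500L, tol = 1e-6, tv_iter = 20L,
                          normalize = TRUE) {
  .checkScanCompatible(sinogram, A)
  b <- .flattenSino(sinogram@values)
  if (any(!is.finite(b)))
    stop("reconstructTV: non-finite measurement values", call. = FALSE)
  M <- A@A
  if (length(M@x) == 0L || all(M@x == 0))
    stop("reconstructTV: degenerate system, weight matrix has no nonzero ",
         "rows", call. = FALSE)
  cn <- rep(1, ncol(M))
  if (normalize) {
    cn <- sqrt(Matrix::colSums(M^2))
    cn[cn == 0] <- 1
    M <- M %*% Matrix::Diagonal(x = 1 / cn)
  }
  Atb <- as.vector(Matrix::crossprod(M, b))
  if (is.null(reg_weight)) reg_weight <- 1e-2 * max(abs(Atb))
  L <- .operatorNormSq(M) * 1.02
  if (L == 0) L <- 1
  nx <- A@grid_dim[1L]; ny <- A@grid_dim[2L]
  embed <- function(xv) {
    m <- matrix(0, nx, ny); m[A@col_index] <- xv; m
  }
  objective <- function(xv) {
    r <- as.vector(M %*% xv) - b
    data <- 0.5 * sum(r^2)
    tv <- totalVariation(embed(xv))
    c(data + reg_weight * tv, data, tv)
  }
  nvox <- ncol(M)
  x_prev <- x <- numeric(nvox)
  y <- x
  t_k <- 1
  Fx <- objective(x)
  obj <- dat <- tvv <- numeric(0)
  iters <- 0L
  for (k in seq_len(max_iter)) {
    grad <- as.vector(Matrix::crossprod(M, as.vector(M %*% y))) - Atb
    z <- y - grad / L
    z <- .proxTV(embed(z), reg_weight / L, iters = tv_iter)[A@col_index]
    z <- pmax(z, 0)
    Fz <- objective(z)
    accepted <- Fz[1L] <= Fx[1L]
    if (accepted) { x_new <- z; Fnew <- Fz }
    else { x_new <- x; Fnew <- Fx }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- x_new + (t_k / t_next) * (z - x_new) +
      ((t_k - 1) / t_next) * (x_new - x_prev)
    x_prev <- x
    x <- x_new
    rel <- abs(Fx[1L] - Fnew[1L]) / max(abs(Fx[1L]), 1e-12)
    Fx <- Fnew
    t_k <- t_next
    obj <- c(obj, Fx[1L]); dat <- c(dat, Fx[2L]); tvv <- c(tvv, Fx[3L])
    iters <- k
    if (k > 1L && accepted && rel < tol) break
  }
  map <- new("ConcentrationMap",
             values = array(embed(x / cn), dim = c(nx, ny, 1L)),
             origin = A@origin, voxel_size = A@voxel_size)
  new("ReconResult", map = map, iterations = iters, objective = obj,
      data_residual = dat, tv_value = tvv,
      config = list(reg_weight = reg_weight, lipschitz = L, tol = tol,
                    max_iter = as.integer(max_iter),
                    tv_iter = as.integer(tv_iter), normalize = normalize))
}

## 4-connected component labelling of a logical matrix (small BFS; the
## slices here are at most ~100 x 100).
.labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  n <- nrow(mask); m <- ncol(mask)
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      i <- (p - 1L) %% n + 1L; j <- (p - 1L) %/% n + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < n) p + 1L,
                  if (j > 1L) p - n, if (j < m) p + n))
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
    }
  }
  lab
}

#' Localize the dominant reconstructed target
#'
#' Thresholds the slice at a fraction of its maximum, labels connected
#' components (4-connectivity) and returns the intensity-weighted centroid
#' of the largest one, in physical coordinates.
#'
#' @param map a scan-plane [ConcentrationMap-class] (or matrix with
#'   \code{origin}/\code{voxel_size} supplied).
#' @param threshold_frac threshold as a fraction of the slice maximum.
#' @param origin,voxel_size grid metadata when \code{map} is a bare matrix.
#' @return list with \code{centroid} (x, y in mm) and \code{n_voxels}; both
#'   \code{NA} when the slice is identically zero.
#' @export
targetLocalization <- function(map, threshold_frac = 0.5, origin = NULL,
                               voxel_size = NULL) {
  if (is(map, "ConcentrationMap")) {
    m <- concValues(map)[, , 1L]
    origin <- gridOrigin(map); voxel_size <- voxelSize(map)
  } else m <- map
  mx <- max(m)
  if (mx <= 0) return(list(centroid = c(NA_real_, NA_real_),
                           n_voxels = 0L))
  lab <- .labelComponents(m >= threshold_frac * mx)
  sizes <- tabulate(lab)
  big <- which.max(sizes)
  sel <- which(lab == big)
  ij <- arrayInd(sel, dim(m))
  wts <- m[sel]
  cx <- origin[1L] + (sum((ij[, 1L] - 1L) * wts) / sum(wts)) * voxel_size
  cy <- origin[2L] + (sum((ij[, 2L] - 1L) * wts) / sum(wts)) * voxel_size
  list(centroid = c(cx, cy), n_voxels = length(sel))
}
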