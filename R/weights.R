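#' Build the discretized forward operator
#'
#' Assembles the sparse weight matrix A of the measurement model
#' \eqn{\Phi = A \rho}: row m collects, for one (view, translation,
#' detector) triple, the excitation-times-propagation weight
#' \eqn{\eta X_m(v) G(r_m, r_v) \Delta V a} of every slice voxel v inside
#' that beam's rasterized footprint. The noiseless forward simulation equals
#' \code{A \%*\% rho} on the masked slice voxels.
#'
#' Rows are ordered detector-fastest, then translation, then view, matching
#' the flattening used by [reconstructTV()]. Columns are the slice voxels
#' whose centers lie inside the cylinder cross-section; \code{col_index}
#' maps them back to the full grid.
#'
#' @param phantom a [Phantom-class] (geometry and background optics).
#' @param beam a [BeamSpec-class].
#' @param detectors a [DetectorSet-class].
#' @param eta luminescence yield.
#' @return a [WeightMatrix-class].
#' @examples
#' ph <- makePhantom(voxel_size = 1)
#' A <- buildWeightMatrix(ph, beamSpec(n_translations = 10L, n_views = 3L))
#' dim(weightEntries(A))
#' @export
buildWeightMatrix <- function(phantom, beam = beamSpec(),
                              detectors = detectorSet(), eta = 1) {
  g <- sliceGrid(phantom)
  nT <- beam@n_translations
  offsets <- (seq_len(nT) - (nT + 1) / 2) * beam@translation_step
  angles <- (seq_len(beam@n_views) - 1L) *
    (beam@angular_span / beam@n_views)
  nD <- length(detectors@angle_offsets)
  voxvol <- phantom@voxel_size^3
  mask_idx <- which(g$mask)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (v in seq_along(angles)) {
    vg <- .viewGeometry(phantom, beam, detectors, angles[v], g, offsets)
    if (!length(vg$voxel)) next
    base <- ((v - 1L) * nT + (vg$bin - 1L)) * nD
    for (k in seq_len(nD)) {
      w <- eta * vg$xray * vg$G[, k] * voxvol * detectors@aperture_area
      ii <- c(ii, base + k)
      jj <- c(jj, vg$col)
      xx <- c(xx, w)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(angles) * nT * nD,
                                     length(mask_idx)))
  new("WeightMatrix", A = methods::as(A, "CsparseMatrix"),
      angles = angles, offsets = offsets,
      detector_offsets = detectors@angle_offsets,
      grid_dim = c(g$n, g$n), voxel_size = phantom@voxel_size,
      origin = g$origin, col_index = mask_idx)
}

#' Forward-project a concentration map through a weight matrix
#'
#' @param A a [WeightMatrix-class].
#' @param rho a scan-plane [ConcentrationMap-class] (or an nx-by-ny matrix)
#'   on the same grid as \code{A}.
#' @return a [Sinogram-class] containing \code{A \%*\% rho}.
#' @export
forwardProject <- function(A, rho) {
  m <- if (is(rho, "ConcentrationMap")) concValues(rho)[, , 1L] else rho
  if (!all(dim(m) == A@grid_dim))
    stop("forwardProject: grid mismatch (map ",
         paste(dim(m), collapse = "x"), ", weight matrix ",
         paste(A@grid_dim, collapse = "x"), ")")
  phi <- as.vector(A@A %*% m[A@col_index])
  nD <- length(A@detector_offsets)
  nT <- length(A@offsets)
  vals <- aperm(array(phi, dim = c(nD, nT, length(A@angles))),
                c(3L, 2L, 1L))
  new("Sinogram", values = vals, angles = A@angles, offsets = A@offsets,
      detector_offsets = A@detector_offsets,
      noise = list(model = "none", level = 0, floor = 0,
                   seed = NA_integer_))
}

## Row-metadata compatibility between a sinogram and a weight matrix.
.checkScanCompatible <- function(sinogram, A) {
  if (!isTRUE(all.equal(sinogram@angles, A@angles)) ||
      !isTRUE(all.equal(sinogram@offsets, A@offsets)) ||
      !isTRUE(all.equal(sinogram@detector_offsets, A@detector_offsets)))
    stop("sinogram axis metadata does not match the weight matrix ",
         "(views/translations/detectors differ)", call. = FALSE)
  invisible(TRUE)
}
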