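#' Optical properties of a homogeneous turbid medium
#'
#' Absorption and reduced scattering coefficients of the phantom background,
#' plus its refractive index. These parameterize the diffusion-approximation
#' Green's function used to propagate luminescence to the surface: the
#' diffusion coefficient is \eqn{D = 1/[3(\mu_a + \mu_s')]} and the effective
#' attenuation \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}.
#'
#' @slot mu_a absorption coefficient, 1/cm; must be positive.
#' @slot mu_s_prime reduced scattering coefficient, 1/cm; must be positive.
#'   The diffusion approximation assumes scattering-dominated transport
#'   (\code{mu_s_prime} well above \code{mu_a}).
#' @slot refractive_index dimensionless, at least 1; sets the extrapolated
#'   boundary distance through the internal-reflection parameter.
#'
#' @seealso [opticalProperties()], [greensFunction()]
#' @exportClass OpticalProperties
setClass("OpticalProperties",
  representation(mu_a = "numeric", mu_s_prime = "numeric",
                 refractive_index = "numeric"))

setValidity("OpticalProperties", function(object) {
  msg <- character()
  if (length(object@mu_a) != 1L || !is.finite(object@mu_a) ||
      object@mu_a <= 0)
    msg <- c(msg, "mu_a must be a single positive number (1/cm)")
  if (length(object@mu_s_prime) != 1L || !is.finite(object@mu_s_prime) ||
      object@mu_s_prime <= 0)
    msg <- c(msg, "mu_s_prime must be a single positive number (1/cm)")
  if (length(object@refractive_index) != 1L ||
      !is.finite(object@refractive_index) || object@refractive_index < 1)
    msg <- c(msg, "refractive_index must be a single number >= 1")
  if (length(msg)) msg else TRUE
})

#' Digital cylindrical phantom
#'
#' A homogeneous cylinder (axis along z, base at z = 0, centered on the
#' origin in x-y) carrying spherical nanophosphor targets. The scan plane is
#' the transverse slice at half height. Targets are stored as a table with
#' columns \code{x}, \code{y}, \code{z} (center, mm), \code{radius} (mm) and
#' \code{concentration} (relative units).
#'
#' @slot radius cylinder radius, mm.
#' @slot height cylinder height, mm.
#' @slot voxel_size isotropic voxel edge used when rasterizing, mm.
#' @slot background an [OpticalProperties-class] object.
#' @slot targets data.frame of spherical targets (possibly zero rows).
#' @slot seed integer seed recorded for provenance (NA when hand-built).
#'
#' @seealso [makePhantom()], [randomPhantom()], [rasterizeConcentration()]
#' @exportClass Phantom
setClass("Phantom",
  representation(radius = "numeric", height = "numeric",
                 voxel_size = "numeric", background = "OpticalProperties",
                 targets = "data.frame", seed = "integer"))

setValidity("Phantom", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (object@height <= 0) msg <- c(msg, "height must be positive")
  if (object@voxel_size <= 0) msg <- c(msg, "voxel_size must be positive")
  tg <- object@targets
  need <- c("x", "y", "z", "radius", "concentration")
  if (!all(need %in% names(tg)))
    return(paste("targets must have columns", paste(need, collapse = ", ")))
  if (nrow(tg)) {
    if (any(tg$radius <= 0)) msg <- c(msg, "target radius must be positive")
    if (any(tg$concentration <= 0))
      msg <- c(msg, "target concentration must be positive")
    rho_xy <- sqrt(tg$x^2 + tg$y^2)
    bad <- which(rho_xy + tg$radius > object@radius + 1e-9 |
                 tg$z - tg$radius < -1e-9 |
                 tg$z + tg$radius > object@height + 1e-9)
    if (length(bad))
      msg <- c(msg, sprintf(
        "target(s) %s not contained in the cylinder (radius %g mm, height %g mm)",
        paste(bad, collapse = ", "), object@radius, object@height))
    if (nrow(tg) > 1L) {
      d <- as.matrix(dist(tg[, c("x", "y", "z")]))
      sums <- outer(tg$radius, tg$radius, `+`)
      ov <- which(d <= sums & upper.tri(d), arr.ind = TRUE)
      if (nrow(ov))
        msg <- c(msg, sprintf("target(s) overlap: pairs %s",
          paste(apply(ov, 1L, function(p)
            sprintf("(%d,%d)", p[1L], p[2L])), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Voxelized nanophosphor concentration map
#'
#' A nonnegative concentration value per voxel on a regular grid, either the
#' full 3D rasterization of a phantom or the 2D scan-plane slice (third
#' dimension of length one). Voxels outside the cylinder are exactly zero.
#'
#' @slot values numeric array, dim (nx, ny, nz).
#' @slot origin coordinates (mm) of the center of voxel (1, 1, 1).
#' @slot voxel_size isotropic voxel edge, mm.
#'
#' @seealso [rasterizeConcentration()], [scanSlice()]
#' @exportClass ConcentrationMap
setClass("ConcentrationMap",
  representation(values = "array", origin = "numeric",
                 voxel_size = "numeric"))

setValidity("ConcentrationMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array (use nz = 1 for a slice)")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and nonnegative")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (object@voxel_size <= 0) msg <- c(msg, "voxel_size must be positive")
  if (length(msg)) msg else TRUE
})

#' Pencil-beam scan geometry
#'
#' First-generation-CT style scan: at each projection view the focused x-ray
#' beam is translated across the object perpendicular to its direction, and
#' the view angle steps over the angular span.
#'
#' @slot diameter beam diameter, micrometers (50 by default).
#' @slot translation_step translation increment, mm.
#' @slot n_translations number of beam positions per view.
#' @slot n_views number of projection views.
#' @slot angular_span total angular coverage, degrees (views are spaced
#'   \code{angular_span / n_views} apart starting at 0).
#' @slot source_intensity x-ray intensity at the entry point, relative units.
#' @slot mu_x x-ray linear attenuation coefficient of the medium, 1/cm.
#'
#' @seealso [beamSpec()], [simulateScan()]
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(diameter = "numeric", translation_step = "numeric",
                 n_translations = "integer", n_views = "integer",
                 angular_span = "numeric", source_intensity = "numeric",
                 mu_x = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@diameter <= 0) msg <- c(msg, "diameter must be positive (um)")
  if (object@translation_step <= 0)
    msg <- c(msg, "translation_step must be positive (mm)")
  if (object@n_translations < 1L) msg <- c(msg, "n_translations must be >= 1")
  if (object@n_views < 1L) msg <- c(msg, "n_views must be >= 1")
  if (object@angular_span <= 0) msg <- c(msg, "angular_span must be positive")
  if (object@mu_x < 0) msg <- c(msg, "mu_x must be nonnegative")
  if (object@source_intensity <= 0)
    msg <- c(msg, "source_intensity must be positive")
  if (length(msg)) msg else TRUE
})

#' Fiber-bundle detector set
#'
#' Point-aperture detectors on the lateral surface of the phantom at the
#' scan-plane height. The detectors co-rotate with the scan: at view angle
#' \eqn{\theta} detector k sits at polar angle \eqn{\theta +} its offset, so
#' the measurement geometry is identical at every view.
#'
#' @slot angle_offsets polar offsets from the beam direction, degrees;
#'   default three bundles at 90, 210 and 330.
#' @slot aperture_area collection aperture, mm^2.
#'
#' @seealso [detectorSet()], [detectorPositions()]
#' @exportClass DetectorSet
setClass("DetectorSet",
  representation(angle_offsets = "numeric", aperture_area = "numeric"))

setValidity("DetectorSet", function(object) {
  msg <- character()
  if (length(object@angle_offsets) < 1L)
    msg <- c(msg, "at least one detector is required")
  if (object@aperture_area <= 0)
    msg <- c(msg, "aperture_area must be positive (mm^2)")
  if (length(msg)) msg else TRUE
})

#' Luminescence sinogram
#'
#' Fluence readings indexed by (view, translation, detector), together with
#' the axis metadata (view angles in degrees, translation offsets in mm,
#' detector angle offsets) and the noise record of the simulation.
#'
#' @slot values numeric array, dim (n_views, n_translations, n_detectors),
#'   all entries nonnegative.
#' @slot angles view angles, degrees.
#' @slot offsets translation offsets from the rotation axis, mm.
#' @slot detector_offsets detector polar offsets, degrees.
#' @slot noise list with elements \code{model}, \code{level}, \code{floor},
#'   \code{seed} describing the applied measurement noise ("none" when
#'   noiseless).
#'
#' @seealso [simulateScan()], [readSinogram()], [writeSinogram()]
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "array", angles = "numeric", offsets = "numeric",
                 detector_offsets = "numeric", noise = "list"))

setValidity("Sinogram", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    return("values must be a 3D array (views x translations x detectors)")
  if (d[1L] != length(object@angles))
    msg <- c(msg, "length(angles) must equal dim(values)[1]")
  if (d[2L] != length(object@offsets))
    msg <- c(msg, "length(offsets) must equal dim(values)[2]")
  if (d[3L] != length(object@detector_offsets))
    msg <- c(msg, "length(detector_offsets) must equal dim(values)[3]")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "sinogram values must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Discretized forward operator (weight matrix)
#'
#' Sparse matrix A linking the scan-slice voxel concentrations to the
#' sinogram readings, \eqn{\Phi = A \rho}. Rows are measurements ordered
#' detector-fastest, then translation, then view; columns are the slice
#' voxels whose centers lie inside the cylinder cross-section.
#'
#' @slot A a \code{dgCMatrix}; all entries nonnegative.
#' @slot angles,offsets,detector_offsets row metadata (as in
#'   [Sinogram-class]).
#' @slot grid_dim c(nx, ny) of the slice grid.
#' @slot voxel_size slice voxel edge, mm.
#' @slot origin coordinates of voxel (1,1,1) center, mm.
#' @slot col_index linear indices into the nx-by-ny grid for each column.
#'
#' @seealso [buildWeightMatrix()], [reconstructTV()]
#' @exportClass WeightMatrix
setClass("WeightMatrix",
  representation(A = "dgCMatrix", angles = "numeric", offsets = "numeric",
                 detector_offsets = "numeric", grid_dim = "integer",
                 voxel_size = "numeric", origin = "numeric",
                 col_index = "integer"))

setValidity("WeightMatrix", function(object) {
  msg <- character()
  nr <- length(object@angles) * length(object@offsets) *
    length(object@detector_offsets)
  if (nrow(object@A) != nr)
    msg <- c(msg, "nrow(A) must be n_views * n_translations * n_detectors")
  if (ncol(object@A) != length(object@col_index))
    msg <- c(msg, "ncol(A) must equal length(col_index)")
  if (any(object@A@x < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Result of a TV-regularized reconstruction
#'
#' @slot map reconstructed [ConcentrationMap-class] (scan-plane slice).
#' @slot iterations number of accepted iterations run.
#' @slot objective,data_residual,tv_value per-iteration diagnostics: the
#'   objective \eqn{\|A\rho - \Phi\|_2^2/2 + \lambda TV(\rho)} and its two
#'   terms. The objective is nonincreasing over accepted iterations.
#' @slot config echo of the solver configuration (regularization weight,
#'   Lipschitz constant, tolerance, iteration cap).
#'
#' @seealso [reconstructTV()]
#' @exportClass ReconResult
setClass("ReconResult",
  representation(map = "ConcentrationMap", iterations = "integer",
                 objective = "numeric", data_residual = "numeric",
                 tv_value = "numeric", config = "list"))

#' Residual view-synthesis network configuration
#'
#' Architecture (fixed, matching the published design): a stem convolution
#' with 64 filters of 3x3 kernels, four residual blocks of three 3x3/64
#' convolutions each with an identity shortcut spanning the three layers, two
#' 3x3/64 convolutions, one 3x3/32 convolution, and a single-filter 3x3
#' output convolution; ReLU after every layer except the output. The network
#' predicts a residual correction on top of linear angular interpolation of
#' the few-view sinogram.
#'
#' @slot loss_alpha weighting factor of the composite loss
#'   \eqn{\alpha (1 - SSIM) + (1 - \alpha) \ell_1}, in \[0, 1\].
#' @slot upsample_mode view-axis pre-interpolation method ("linear").
#' @slot seed integer seed for parameter initialization and batching.
#'
#' @seealso [netConfig()], [trainViewSynth()]
#' @exportClass NetConfig
setClass("NetConfig",
  representation(loss_alpha = "numeric", upsample_mode = "character",
                 seed = "integer"))

setValidity("NetConfig", function(object) {
  msg <- character()
  if (object@loss_alpha < 0 || object@loss_alpha > 1)
    msg <- c(msg, "loss_alpha must lie in [0, 1]")
  if (!object@upsample_mode %in% "linear")
    msg <- c(msg, "upsample_mode must be 'linear'")
  if (length(msg)) msg else TRUE
})

#' Trained view-synthesis model
#'
#' @slot params list of layer parameter matrices.
#' @slot config the [NetConfig-class] used.
#' @slot history data.frame with one row per epoch (epoch, train_loss,
#'   val_loss).
#' @slot normalization list describing input scaling (per-sinogram maximum);
#'   stored so that inference is self-contained.
#' @slot input_shape c(n_views_in, n_translations) expected at inference.
#'
#' @seealso [trainViewSynth()], [predictSinogram()]
#' @exportClass ViewSynthModel
setClass("ViewSynthModel",
  representation(params = "list", config = "NetConfig",
                 history = "data.frame", normalization = "list",
                 input_shape = "integer"))
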