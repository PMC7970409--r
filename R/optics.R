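#' X-ray excitation field for one beam position
#'
#' Slice-grid x-ray intensity deposited by the pencil beam at a single
#' (view angle, translation) position, attenuated along the chord by the
#' Beer-Lambert law. The beam is far thinner than a voxel, so its footprint
#' is rasterized with a triangular partial-volume weight of half-width one
#' voxel about the beam axis (an anti-aliased line projector; see the
#' vignette): \code{values = coverage * I(d)} where I is the axial
#' Beer-Lambert intensity and \code{coverage} the lateral coverage weight.
#'
#' @slot values nx-by-ny matrix of deposited intensities (relative units),
#'   nonzero only within one voxel of the beam axis.
#' @slot coverage nx-by-ny matrix of lateral coverage weights in \[0, 1\];
#'   \code{values / coverage} on the support is the pure axial intensity.
#' @slot origin,voxel_size slice grid metadata (mm).
#' @slot view_angle,translation beam position (degrees, mm).
#' @slot radius phantom cylinder radius, mm.
#' @exportClass XRayField
setClass("XRayField",
  representation(values = "matrix", coverage = "matrix", origin = "numeric",
                 voxel_size = "numeric", view_angle = "numeric",
                 translation = "numeric", radius = "numeric"))

#' Luminescence source distribution
#'
#' Emitted optical source power density \eqn{S = \eta X \rho} on the scan
#' slice for one beam position.
#'
#' @slot values nx-by-ny matrix (relative W/mm^3).
#' @slot yield luminescence yield eta.
#' @slot origin,voxel_size,view_angle,translation,radius as in
#'   [XRayField-class].
#' @exportClass LuminescenceSource
setClass("LuminescenceSource",
  representation(values = "matrix", yield = "numeric", origin = "numeric",
                 voxel_size = "numeric", view_angle = "numeric",
                 translation = "numeric", radius = "numeric"))

#' Construct a pencil-beam scan specification
#'
#' Defaults follow the validation scan protocol: a 50 um focused beam
#' translated 50 times in 0.5 mm increments at each of 15 views over 180
#' degrees. The full-view protocol doubles the views (30 over 180 degrees).
#'
#' @param diameter beam diameter, micrometers.
#' @param translation_step translation increment, mm.
#' @param n_translations beam positions per view.
#' @param n_views projection views.
#' @param angular_span angular coverage, degrees.
#' @param source_intensity entry intensity, relative units.
#' @param mu_x x-ray linear attenuation coefficient of the medium, 1/cm
#'   (soft-tissue-like default at ~40 keV).
#' @return a [BeamSpec-class] object.
#' @examples
#' beamSpec()                 # few-view protocol
#' beamSpec(n_views = 30L)    # full-view protocol
#' @export
beamSpec <- function(diameter = 50, translation_step = 0.5,
                     n_translations = 50L, n_views = 15L,
                     angular_span = 180, source_intensity = 1,
                     mu_x = 0.27) {
  new("BeamSpec", diameter = diameter, translation_step = translation_step,
      n_translations = as.integer(n_translations),
      n_views = as.integer(n_views), angular_span = angular_span,
      source_intensity = source_intensity, mu_x = mu_x)
}

#' Construct a detector set
#'
#' @param angle_offsets polar offsets of the fiber bundles from the beam
#'   direction, degrees; the default places three bundles equiangularly
#'   (120 degrees apart) starting at 90 degrees so none sits in the beam.
#' @param aperture_area collection aperture, mm^2.
#' @return a [DetectorSet-class] object.
#' @export
detectorSet <- function(angle_offsets = c(90, 210, 330),
                        aperture_area = 1) {
  if (length(angle_offsets) < 1L)
    stop("detectorSet: at least one detector is required")
  new("DetectorSet", angle_offsets = as.numeric(angle_offsets),
      aperture_area = aperture_area)
}

#' Detector positions at a view
#'
#' The fiber bundles co-rotate with the scan, so at view angle theta
#' detector k sits on the lateral surface at polar angle theta + offset_k,
#' at the scan-plane height.
#'
#' @param detectors a [DetectorSet-class].
#' @param phantom a [Phantom-class].
#' @param view_angle view angle, degrees.
#' @return a matrix with one row per detector, columns x, y, z (mm).
#' @export
detectorPositions <- function(detectors, phantom, view_angle = 0) {
  phi <- (view_angle + detectors@angle_offsets) * pi / 180
  cbind(x = phantom@radius * cos(phi), y = phantom@radius * sin(phi),
        z = phantom@height / 2)
}

## Diffusion parameters in cm units; zb is the extrapolated boundary
## distance 2 A D with A from the Groenhuis internal-reflection fit.
.diffusionParams <- function(props) {
  D <- 1 / (3 * (props@mu_a + props@mu_s_prime))
  mueff <- sqrt(3 * props@mu_a * (props@mu_a + props@mu_s_prime))
  n <- props@refractive_index
  A <- if (abs(n - 1) < 1e-12) 1 else {
    rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
    (1 + rd) / (1 - rd)
  }
  list(D = D, mueff = mueff, zb = 2 * A * D)
}

.ginf <- function(r_cm, dp) exp(-dp$mueff * r_cm) / (4 * pi * dp$D * r_cm)

#' Diffusion-approximation propagation kernel
#'
#' Fluence at a boundary point per unit isotropic source at an interior
#' point, for a homogeneous medium in the diffusion approximation with
#' diffusion coefficient \eqn{D = 1/[3(\mu_a + \mu_s')]} (cm) and effective
#' attenuation \eqn{\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}} (1/cm). The
#' default "extrapolated" boundary condition subtracts an image source
#' mirrored across the extrapolated plane \eqn{z_b = 2AD} outside the
#' boundary, using the plane tangent to the cylinder at the detector; the
#' "infinite" kernel is the bare point-source term
#' \eqn{e^{-\mu_{eff} r}/(4\pi D r)}.
#'
#' @param r_det detector position, length-3 (mm); for the extrapolated
#'   boundary it must lie on the lateral surface (\code{radius} given).
#' @param r_src source position(s): length-3 vector or n-by-3 matrix (mm),
#'   strictly inside the cylinder.
#' @param props an [OpticalProperties-class].
#' @param radius cylinder radius (mm), required for the extrapolated
#'   boundary.
#' @param boundary "extrapolated" (default) or "infinite".
#' @return fluence per unit source power, one value per source point
#'   (1/cm^2 scale, relative); strictly positive and strictly decreasing in
#'   source-detector distance for fixed properties.
#' @examples
#' pr <- opticalProperties(0.5, 15)
#' greensFunction(c(12.5, 0, 10), c(7.5, 0, 10), pr, radius = 12.5)
#' @export
greensFunction <- function(r_det, r_src, props, radius = NULL,
                           boundary = c("extrapolated", "infinite")) {
  boundary <- match.arg(boundary)
  if (props@mu_s_prime < 10 * props@mu_a)
    warning("greensFunction: mu_s_prime < 10 * mu_a, outside the ",
            "diffusion regime", call. = FALSE)
  if (is.null(dim(r_src))) r_src <- matrix(r_src, nrow = 1L)
  stopifnot(length(r_det) == 3L, ncol(r_src) == 3L)
  dp <- .diffusionParams(props)
  dvec <- sweep(r_src, 2L, r_det)
  r1 <- sqrt(rowSums(dvec^2)) / 10          # mm -> cm
  if (any(r1 <= 0))
    stop("greensFunction: source coincides with the detector")
  if (boundary == "infinite") return(.ginf(r1, dp))
  if (is.null(radius))
    stop("greensFunction: 'radius' is required for the extrapolated ",
         "boundary condition")
  rho_det <- sqrt(sum(r_det[1:2]^2))
  if (abs(rho_det - radius) > 1e-6 * radius)
    stop("greensFunction: r_det must lie on the lateral surface")
  if (any(sqrt(rowSums(r_src[, 1:2, drop = FALSE]^2)) >= radius - 1e-9))
    stop("greensFunction: source point(s) on or outside the boundary")
  nhat <- c(-r_det[1:2] / rho_det, 0)       # inward normal at the detector
  h <- (dvec %*% nhat)[, 1L] / 10           # source depth, cm
  tau2 <- pmax(r1^2 - h^2, 0)
  r2 <- sqrt(tau2 + (h + 2 * dp$zb)^2)
  .ginf(r1, dp) - .ginf(r2, dp)
}

## Half-width (mm) of the triangular lateral footprint used to rasterize
## the pencil beam: one voxel (or the beam radius, if ever larger). The
## triangular weight makes the discretized projector continuous in the
## beam offset, which keeps the sinogram consistent under rotations of the
## scene (a binary footprint is degenerate whenever voxel centers fall
## exactly on its edge, e.g. at axis-aligned views).
.beamHalfWidth <- function(beam, voxel_size)
  max(beam@diameter / 2000, voxel_size)

.lateralWeight <- function(d, hw) pmax(0, 1 - abs(d) / hw)

#' X-ray intensity field for one beam position
#'
#' The pencil beam travels in the scan plane along direction
#' (cos theta, sin theta), displaced by \code{translation} along the
#' perpendicular. Intensity at depth d inside the medium follows the
#' Beer-Lambert law \eqn{I(d) = I_0 e^{-\mu_x d}}; laterally the beam
#' footprint is rasterized with a triangular coverage weight of half-width
#' one voxel (stored in the \code{coverage} slot), so
#' \code{values = coverage * I(depth)}. A beam that misses the cylinder
#' yields the zero field.
#'
#' @param phantom a [Phantom-class].
#' @param beam a [BeamSpec-class].
#' @param view_angle view angle, degrees.
#' @param translation beam offset from the rotation axis, mm.
#' @return an [XRayField-class] on the scan-plane slice grid.
#' @export
xrayIntensity <- function(phantom, beam, view_angle, translation) {
  g <- sliceGrid(phantom)
  th <- view_angle * pi / 180
  u <- c(cos(th), sin(th)); w <- c(-sin(th), cos(th))
  vals <- cov <- matrix(0, g$n, g$n)
  if (abs(translation) < phantom@radius) {
    xs <- matrix(g$centers, g$n, g$n)
    ys <- matrix(g$centers, g$n, g$n, byrow = TRUE)
    pw <- xs * w[1L] + ys * w[2L]
    pu <- xs * u[1L] + ys * u[2L]
    hw <- .beamHalfWidth(beam, phantom@voxel_size)
    sel <- g$mask & abs(pw - translation) < hw
    d_mm <- pmax(pu[sel] + sqrt(phantom@radius^2 - translation^2), 0)
    cov[sel] <- .lateralWeight(pw[sel] - translation, hw)
    vals[sel] <- cov[sel] * beam@source_intensity *
      exp(-beam@mu_x * d_mm / 10)
  }
  new("XRayField", values = vals, coverage = cov, origin = g$origin,
      voxel_size = phantom@voxel_size, view_angle = view_angle,
      translation = translation, radius = phantom@radius)
}

#' Luminescence source formation
#'
#' Elementwise \eqn{S = \eta X \rho}: the emitted optical source is the
#' product of the x-ray excitation and the nanophosphor concentration,
#' scaled by the luminescence yield.
#'
#' @param x an [XRayField-class].
#' @param rho the scan-plane [ConcentrationMap-class] (see [scanSlice()]).
#' @param eta luminescence yield (optical power per unit x-ray intensity per
#'   unit concentration), relative units.
#' @return a [LuminescenceSource-class].
#' @export
luminescenceSource <- function(x, rho, eta = 1) {
  rv <- concValues(rho)
  if (dim(rv)[3L] != 1L || !all(dim(rv)[1:2] == dim(x@values)))
    stop("luminescenceSource: x-ray field and concentration map grids ",
         "do not match (", paste(dim(x@values), collapse = "x"), " vs ",
         paste(dim(rv)[1:2], collapse = "x"), ")")
  new("LuminescenceSource", values = eta * x@values * rv[, , 1L],
      yield = eta, origin = x@origin, voxel_size = x@voxel_size,
      view_angle = x@view_angle, translation = x@translation,
      radius = x@radius)
}

#' Detector fluence readings
#'
#' Discretized boundary fluence \eqn{\Phi_k = \sum_v G(r_k, r_v) S(r_v)
#' \Delta V \cdot a}: the propagation kernel summed against the source over
#' the slice voxels, times voxel volume and aperture area. Linear in the
#' source and nonnegative.
#'
#' @param source a [LuminescenceSource-class].
#' @param detectors a [DetectorSet-class].
#' @param props the background [OpticalProperties-class].
#' @return numeric vector, one reading per detector.
#' @export
detectorFluence <- function(source, detectors, props) {
  if (length(detectors@angle_offsets) < 1L)
    stop("detectorFluence: empty detector set")
  n <- nrow(source@values)
  centers <- source@origin[1L] + (seq_len(n) - 1L) * source@voxel_size
  sel <- which(source@values > 0)
  out <- numeric(length(detectors@angle_offsets))
  if (!length(sel)) return(out)
  ij <- arrayInd(sel, dim(source@values))
  src <- cbind(centers[ij[, 1L]], centers[ij[, 2L]], source@origin[3L])
  phi <- (source@view_angle + detectors@angle_offsets) * pi / 180
  voxvol <- source@voxel_size^3
  for (k in seq_along(phi)) {
    det <- c(source@radius * cos(phi[k]), source@radius * sin(phi[k]),
             source@origin[3L])
    G <- greensFunction(det, src, props, radius = source@radius)
    out[k] <- sum(G * source@values[sel]) * voxvol *
      detectors@aperture_area
  }
  out
}

#' Measurement noise configuration
#'
#' Shot-noise-like Gaussian model: a reading with value s receives zero-mean
#' Gaussian noise of standard deviation
#' \code{level * sqrt(s * peak) + floor}, where peak is the sinogram
#' maximum, so the noise is \code{level} of the peak at the peak and scales
#' with sqrt(signal) below it. Negative noisy readings are clipped to zero.
#'
#' @param level fractional noise level at the sinogram peak.
#' @param floor additive standard-deviation floor (signal units).
#' @param seed integer seed.
#' @return a list understood by [simulateScan()].
#' @export
noiseConfig <- function(level = 0.01, floor = 0, seed = 1L) {
  stopifnot(level >= 0, floor >= 0)
  list(model = if (level > 0 || floor > 0) "gaussian-sqrt" else "none",
       level = level, floor = floor, seed = as.integer(seed))
}

## Per-view geometry shared by the simulator and the weight matrix: one
## contribution row per (voxel, overlapping translation bin), carrying the
## Beer-Lambert x-ray deposition (axial attenuation times triangular
## lateral coverage) and the propagation kernel to each detector.
.viewGeometry <- function(phantom, beam, detectors, view_angle, grid,
                          offsets) {
  th <- view_angle * pi / 180
  u <- c(cos(th), sin(th)); w <- c(-sin(th), cos(th))
  idx <- which(grid$mask)
  ij <- arrayInd(idx, dim(grid$mask))
  xs <- grid$centers[ij[, 1L]]; ys <- grid$centers[ij[, 2L]]
  pu <- xs * u[1L] + ys * u[2L]
  pw <- xs * w[1L] + ys * w[2L]
  step <- beam@translation_step
  hw <- .beamHalfWidth(beam, phantom@voxel_size)
  t0 <- offsets[1L]
  kmin <- as.integer(ceiling((pw - hw - t0) / step + 1 - 1e-12))
  kmax <- as.integer(floor((pw + hw - t0) / step + 1 + 1e-12))
  vox_i <- integer(0); bin_i <- integer(0)
  for (j in 0L:max(0L, max(kmax - kmin))) {
    cand <- kmin + j
    ok <- which(cand <= kmax & cand >= 1L & cand <= length(offsets))
    vox_i <- c(vox_i, ok); bin_i <- c(bin_i, cand[ok])
  }
  wlat <- .lateralWeight(pw[vox_i] - offsets[bin_i], hw)
  keep <- wlat > 0 & abs(offsets[bin_i]) < phantom@radius
  vox_i <- vox_i[keep]; bin_i <- bin_i[keep]; wlat <- wlat[keep]
  if (!length(vox_i))
    return(list(voxel = integer(0), col = integer(0), bin = integer(0),
                xray = numeric(0),
                G = matrix(0, 0L, length(detectors@angle_offsets))))
  toff <- offsets[bin_i]
  d_mm <- pmax(pu[vox_i] + sqrt(phantom@radius^2 - toff^2), 0)
  xval <- wlat * beam@source_intensity * exp(-beam@mu_x * d_mm / 10)
  uvox <- sort(unique(vox_i))
  src <- cbind(xs[uvox], ys[uvox], phantom@height / 2)
  phi <- (view_angle + detectors@angle_offsets) * pi / 180
  Gu <- matrix(0, length(uvox), length(phi))
  for (k in seq_along(phi)) {
    det <- c(phantom@radius * cos(phi[k]), phantom@radius * sin(phi[k]),
             phantom@height / 2)
    Gu[, k] <- greensFunction(det, src, phantom@background,
                              radius = phantom@radius)
  }
  rowmap <- match(vox_i, uvox)
  list(voxel = idx[vox_i],      # linear index into the nx x ny grid
       col = vox_i,             # index into the masked-voxel column set
       bin = bin_i, xray = xval,
       G = Gu[rowmap, , drop = FALSE])
}

#' Simulate a full luminescence scan
#'
#' Loops views and translations, composing pencil-beam excitation
#' ([xrayIntensity()]), source formation ([luminescenceSource()]) and
#' boundary propagation ([detectorFluence()]) into a sinogram of shape
#' (views, translations, detectors). Translations are symmetric about the
#' rotation axis; view angles start at 0 and step
#' \code{angular_span / n_views}. Noiseless simulation is exactly linear in
#' the phantom concentrations.
#'
#' @param phantom a [Phantom-class].
#' @param beam a [BeamSpec-class].
#' @param detectors a [DetectorSet-class].
#' @param eta luminescence yield.
#' @param noise \code{NULL} for a noiseless scan, or a [noiseConfig()] list.
#' @return a [Sinogram-class].
#' @examples
#' ph <- makePhantom(targets = sphericalTarget(c(0, 0, 10), 2, 1))
#' s <- simulateScan(ph)
#' dim(sinoValues(s))
#' @export
simulateScan <- function(phantom, beam = beamSpec(),
                         detectors = detectorSet(), eta = 1,
                         noise = NULL) {
  g <- sliceGrid(phantom)
  rho <- concValues(scanSlice(phantom))[, , 1L]
  nT <- beam@n_translations
  offsets <- (seq_len(nT) - (nT + 1) / 2) * beam@translation_step
  angles <- (seq_len(beam@n_views) - 1L) *
    (beam@angular_span / beam@n_views)
  nD <- length(detectors@angle_offsets)
  voxvol <- phantom@voxel_size^3
  vals <- array(0, dim = c(beam@n_views, nT, nD))
  for (v in seq_along(angles)) {
    vg <- .viewGeometry(phantom, beam, detectors, angles[v], g, offsets)
    if (!length(vg$voxel)) next
    S <- eta * vg$xray * rho[vg$voxel]
    nz <- which(S > 0)
    if (!length(nz)) next
    for (k in seq_len(nD)) {
      contrib <- vg$G[nz, k] * S[nz] * voxvol * detectors@aperture_area
      agg <- rowsum(contrib, vg$bin[nz])
      vals[v, as.integer(rownames(agg)), k] <- agg[, 1L]
    }
  }
  nrec <- list(model = "none", level = 0, floor = 0, seed = NA_integer_)
  if (!is.null(noise) && noise$model != "none") {
    peak <- max(vals)
    if (peak > 0) {
      vals <- withSeed(noise$seed, {
        sd <- noise$level * sqrt(vals * peak) + noise$floor
        pmax(vals + rnorm(length(vals), sd = sd), 0)
      })
    }
    nrec <- noise
  }
  new("Sinogram", values = vals, angles = angles, offsets = offsets,
      detector_offsets = detectors@angle_offsets, noise = nrec)
}
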