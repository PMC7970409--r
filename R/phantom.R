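#' Construct optical properties
#'
#' @param mu_a absorption coefficient, 1/cm.
#' @param mu_s_prime reduced scattering coefficient, 1/cm.
#' @param refractive_index dimensionless refractive index (>= 1).
#'
#' @details A warning is emitted when \code{mu_s_prime < 10 * mu_a}: the
#' diffusion approximation used for light propagation assumes
#' scattering-dominated transport and degrades outside that regime.
#'
#' @return an [OpticalProperties-class] object.
#' @examples
#' opticalProperties(0.5, 15)
#' @export
opticalProperties <- function(mu_a = 0.5, mu_s_prime = 15,
                              refractive_index = 1.37) {
  obj <- new("OpticalProperties", mu_a = mu_a, mu_s_prime = mu_s_prime,
             refractive_index = refractive_index)
  if (mu_s_prime < 10 * mu_a)
    warning("mu_s_prime < 10 * mu_a: outside the diffusion regime, ",
            "the propagation kernel may be inaccurate", call. = FALSE)
  obj
}

#' Construct a spherical target row
#'
#' @param center numeric length-3 center (x, y, z) in mm, phantom frame
#'   (cylinder axis = z, base at z = 0).
#' @param radius sphere radius, mm.
#' @param concentration nanophosphor concentration, relative units.
#' @return a one-row data.frame suitable for [makePhantom()].
#' @examples
#' sphericalTarget(c(5, 0, 10), 1.5, 1)
#' @export
sphericalTarget <- function(center, radius, concentration) {
  stopifnot(length(center) == 3L, is.finite(center),
            radius > 0, concentration > 0)
  data.frame(x = center[1L], y = center[2L], z = center[3L],
             radius = radius, concentration = concentration)
}

#' Build a cylindrical phantom
#'
#' Assembles a digital cylindrical phantom from explicit targets and
#' background optical properties, validating that every target sphere lies
#' entirely inside the cylinder and that no two targets overlap.
#'
#' @param radius cylinder radius, mm.
#' @param height cylinder height, mm.
#' @param targets data.frame of targets (rbind of [sphericalTarget()] rows),
#'   or NULL for a target-free phantom.
#' @param background an [OpticalProperties-class] object.
#' @param voxel_size rasterization voxel edge, mm.
#' @param seed provenance seed to record (NA for hand-built phantoms).
#' @return a [Phantom-class] object.
#' @examples
#' ph <- makePhantom(targets = sphericalTarget(c(6, 0, 10), 1.5, 1))
#' ph
#' @export
makePhantom <- function(radius = 12.5, height = 20, targets = NULL,
                        background = opticalProperties(),
                        voxel_size = 0.25, seed = NA_integer_) {
  if (is.null(targets))
    targets <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric(), concentration = numeric())
  new("Phantom", radius = radius, height = height, voxel_size = voxel_size,
      background = background, targets = as.data.frame(targets),
      seed = as.integer(seed))
}

#' Default configuration for random phantom generation
#'
#' Ranges follow the training-set protocol: cylinders of varying size,
#' one to four spherical targets of varying radius and concentration placed
#' at random (rejection sampling until containment and non-overlap hold), and
#' background optical properties drawn uniformly from a +/-20% band around
#' mu_a = 0.5 /cm, mu_s' = 15 /cm.
#'
#' @param radius_range,height_range cylinder dimension ranges, mm.
#' @param n_targets_range integer range of target counts.
#' @param target_radius_range target sphere radius range, mm.
#' @param concentration_range target concentration range, relative units.
#' @param optical_perturbation fractional half-width of the uniform band
#'   around the nominal optical coefficients (0 fixes them exactly).
#' @param mu_a,mu_s_prime nominal background coefficients, 1/cm.
#' @param refractive_index background refractive index.
#' @param voxel_size rasterization voxel edge, mm.
#' @param target_plane "scan" to center targets on the scan plane
#'   (z = height/2), "random" for uniform z placement.
#' @param max_attempts rejection-sampling cap per target before a placement
#'   error is raised.
#' @return a named list understood by [randomPhantom()].
#' @export
phantomConfig <- function(radius_range = c(10, 12.5),
                          height_range = c(20, 20),
                          n_targets_range = c(1L, 4L),
                          target_radius_range = c(0.5, 2.5),
                          concentration_range = c(0.5, 2),
                          optical_perturbation = 0.2,
                          mu_a = 0.5, mu_s_prime = 15,
                          refractive_index = 1.37,
                          voxel_size = 0.25,
                          target_plane = c("scan", "random"),
                          max_attempts = 1000L) {
  target_plane <- match.arg(target_plane)
  cfg <- list(radius_range = radius_range, height_range = height_range,
              n_targets_range = as.integer(n_targets_range),
              target_radius_range = target_radius_range,
              concentration_range = concentration_range,
              optical_perturbation = optical_perturbation,
              mu_a = mu_a, mu_s_prime = mu_s_prime,
              refractive_index = refractive_index,
              voxel_size = voxel_size, target_plane = target_plane,
              max_attempts = as.integer(max_attempts))
  for (nm in c("radius_range", "height_range", "target_radius_range",
               "concentration_range"))
    if (length(cfg[[nm]]) != 2L || any(cfg[[nm]] <= 0) ||
        diff(cfg[[nm]]) < 0)
      stop("phantomConfig: ", nm, " must be a nondecreasing positive pair")
  if (cfg$optical_perturbation < 0 || cfg$optical_perturbation >= 1)
    stop("phantomConfig: optical_perturbation must lie in [0, 1)")
  cfg
}

## Run expr with a private RNG stream so callers' .Random.seed is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a seeded random phantom
#'
#' Draws cylinder dimensions, background optical properties and spherical
#' targets from the ranges in \code{config}. Target centers are
#' rejection-sampled (uniform over the admissible disk) until containment
#' and pairwise non-overlap hold; failure to place a target within
#' \code{config$max_attempts} attempts raises an error. Identical
#' \code{seed} and \code{config} reproduce the phantom field-by-field.
#'
#' @param seed integer seed.
#' @param config a [phantomConfig()] list.
#' @return a [Phantom-class] object.
#' @examples
#' identical(randomPhantom(7), randomPhantom(7))
#' @export
randomPhantom <- function(seed, config = phantomConfig()) {
  withSeed(seed, {
    runifr <- function(r) runif(1L, r[1L], r[2L])
    radius <- runifr(config$radius_range)
    height <- runifr(config$height_range)
    pert <- config$optical_perturbation
    props <- opticalProperties(
      mu_a = config$mu_a * runif(1L, 1 - pert, 1 + pert),
      mu_s_prime = config$mu_s_prime * runif(1L, 1 - pert, 1 + pert),
      refractive_index = config$refractive_index)
    n_t <- if (config$n_targets_range[1L] == config$n_targets_range[2L])
      config$n_targets_range[1L]
    else sample(seq(config$n_targets_range[1L],
                    config$n_targets_range[2L]), 1L)
    tg <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                     radius = numeric(), concentration = numeric())
    for (i in seq_len(n_t)) {
      placed <- FALSE
      for (att in seq_len(config$max_attempts)) {
        r_t <- runifr(config$target_radius_range)
        r_t <- min(r_t, height / 2)        # must fit axially as well
        rmax <- radius - r_t
        if (rmax <= 0) next
        rc <- rmax * sqrt(runif(1L))       # uniform over the disk
        th <- runif(1L, 0, 2 * pi)
        z <- if (config$target_plane == "scan") height / 2
             else runif(1L, r_t, height - r_t)
        cand <- c(rc * cos(th), rc * sin(th), z)
        ok <- TRUE
        if (nrow(tg)) {
          d <- sqrt((tg$x - cand[1L])^2 + (tg$y - cand[2L])^2 +
                    (tg$z - cand[3L])^2)
          ok <- all(d > tg$radius + r_t + 1e-9)
        }
        if (ok) {
          tg <- rbind(tg, sphericalTarget(cand, r_t,
                                          runifr(config$concentration_range)))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("randomPhantom: unable to place target ", i, " after ",
             config$max_attempts, " attempts")
    }
    makePhantom(radius = radius, height = height, targets = tg,
                background = props, voxel_size = config$voxel_size,
                seed = seed)
  })
}

## Slice grid covering the cylinder cross-section: n = ceiling(2R / voxel),
## centered on the axis. Returns centers and the in-cylinder mask.
sliceGrid <- function(phantom) {
  v <- phantom@voxel_size
  n <- as.integer(ceiling(2 * phantom@radius / v))
  centers <- (seq_len(n) - (n + 1) / 2) * v
  mask <- outer(centers^2, centers^2, `+`) <= phantom@radius^2
  list(n = n, centers = centers, mask = mask,
       origin = c(centers[1L], centers[1L], phantom@height / 2))
}

#' Rasterize a phantom's concentration distribution
#'
#' Each voxel takes the concentration of the target sphere containing its
#' center (0 for background). The grid covers the cylinder cross-section in
#' x-y and, for the 3D rasterization, the full height in z.
#'
#' @param phantom a [Phantom-class] object.
#' @return a [ConcentrationMap-class]; rasterization is exactly linear in the
#'   target concentrations.
#' @seealso [scanSlice()] for the 2D scan-plane slice.
#' @examples
#' m <- rasterizeConcentration(
#'   makePhantom(targets = sphericalTarget(c(0, 0, 10), 1, 1)))
#' sum(concValues(m) > 0)
#' @export
rasterizeConcentration <- function(phantom) {
  g <- sliceGrid(phantom)
  v <- phantom@voxel_size
  nz <- as.integer(ceiling(phantom@height / v))
  zc <- (seq_len(nz) - 0.5) * v
  vals <- array(0, dim = c(g$n, g$n, nz))
  tg <- phantom@targets
  for (i in seq_len(nrow(tg))) {
    ix <- which(abs(g$centers - tg$x[i]) <= tg$radius[i])
    iy <- which(abs(g$centers - tg$y[i]) <= tg$radius[i])
    iz <- which(abs(zc - tg$z[i]) <= tg$radius[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (g$centers[ix] - tg$x[i])^2
    dy2 <- (g$centers[iy] - tg$y[i])^2
    dz2 <- (zc[iz] - tg$z[i])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= tg$radius[i]^2
    sub <- vals[ix, iy, iz, drop = FALSE]
    sub[inside] <- tg$concentration[i]
    vals[ix, iy, iz] <- sub
  }
  new("ConcentrationMap", values = vals,
      origin = c(g$centers[1L], g$centers[1L], zc[1L]), voxel_size = v)
}

#' Scan-plane concentration slice
#'
#' The 2D rasterization of the phantom on the transverse plane at half
#' height (the plane swept by the pencil beam); this is the ground truth
#' against which reconstructions are scored.
#'
#' @param phantom a [Phantom-class] object.
#' @return a [ConcentrationMap-class] with a single z layer.
#' @export
scanSlice <- function(phantom) {
  g <- sliceGrid(phantom)
  vals <- matrix(0, g$n, g$n)
  tg <- phantom@targets
  z0 <- phantom@height / 2
  for (i in seq_len(nrow(tg))) {
    dz2 <- (z0 - tg$z[i])^2
    if (dz2 > tg$radius[i]^2) next
    r2 <- tg$radius[i]^2 - dz2
    inside <- outer((g$centers - tg$x[i])^2, (g$centers - tg$y[i])^2,
                    `+`) <= r2
    vals[inside] <- tg$concentration[i]
  }
  new("ConcentrationMap", values = array(vals, dim = c(g$n, g$n, 1L)),
      origin = g$origin, voxel_size = phantom@voxel_size)
}

## ---- serialization -------------------------------------------------------

.phantom_format <- "XLCTsynth-phantom-1"

#' Read and write phantoms
#'
#' Phantoms are stored one per file in a hierarchical JSON container holding
#' the scalars, the target table, the background optical properties, the
#' recorded seed, and the rasterized scan-plane slice, with numbers written
#' at 17 significant digits so the round trip is lossless. A companion
#' human-readable YAML summary can be written with [writePhantomSummary()].
#'
#' @param phantom a [Phantom-class] object.
#' @param path file path.
#' @return \code{readPhantom} returns the [Phantom-class];
#'   \code{writePhantom} returns \code{path} invisibly.
#' @export
writePhantom <- function(phantom, path) {
  g <- scanSlice(phantom)
  obj <- list(
    format = .phantom_format,
    radius = phantom@radius, height = phantom@height,
    voxel_size = phantom@voxel_size,
    background = list(mu_a = phantom@background@mu_a,
                      mu_s_prime = phantom@background@mu_s_prime,
                      refractive_index = phantom@background@refractive_index),
    targets = phantom@targets,
    seed = phantom@seed,
    slice = list(dim = dim(g@values)[1:2], values = as.vector(g@values)))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("readPhantom: malformed file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, .phantom_format))
    stop("readPhantom: '", path, "' is not a phantom container ",
         "(missing or wrong 'format' field)", call. = FALSE)
  for (f in c("radius", "height", "voxel_size", "background", "targets"))
    if (is.null(obj[[f]]))
      stop("readPhantom: field '", f, "' missing in '", path, "'",
           call. = FALSE)
  tg <- as.data.frame(obj$targets)
  if (!nrow(tg)) tg <- NULL
  makePhantom(radius = obj$radius, height = obj$height, targets = tg,
              background = opticalProperties(obj$background$mu_a,
                                             obj$background$mu_s_prime,
                                             obj$background$refractive_index),
              voxel_size = obj$voxel_size,
              seed = if (is.null(obj$seed)) NA_integer_ else obj$seed)
}

#' Write a human-readable phantom summary
#'
#' @param phantom a [Phantom-class] object.
#' @param path output path (YAML).
#' @return \code{path}, invisibly.
#' @export
writePhantomSummary <- function(phantom, path) {
  yaml::write_yaml(list(
    phantom = list(
      radius_mm = phantom@radius, height_mm = phantom@height,
      voxel_size_mm = phantom@voxel_size, seed = phantom@seed,
      background = list(mu_a_per_cm = phantom@background@mu_a,
                        mu_s_prime_per_cm = phantom@background@mu_s_prime,
                        refractive_index =
                          phantom@background@refractive_index),
      n_targets = nrow(phantom@targets),
      targets = if (nrow(phantom@targets))
        lapply(seq_len(nrow(phantom@targets)), function(i)
          as.list(phantom@targets[i, ])) else list())), path)
  invisible(path)
}
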