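#' Accessors for XLCTsynth data objects
#'
#' Small accessor generics in the Bioconductor style: values and metadata of
#' concentration maps, sinograms, weight matrices, reconstructions and
#' trained models are read through these rather than via direct slot access.
#'
#' @param object one of the package's S4 objects.
#' @return the requested component; see the class documentation pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concValues", function(object) standardGeneric("concValues"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("sinoValues", function(object) standardGeneric("sinoValues"))

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))

#' @rdname accessors
#' @export
setGeneric("translationOffsets",
           function(object) standardGeneric("translationOffsets"))

#' @rdname accessors
#' @export
setGeneric("nDetectors", function(object) standardGeneric("nDetectors"))

#' @rdname accessors
#' @export
setGeneric("targetTable", function(object) standardGeneric("targetTable"))

#' @rdname accessors
#' @export
setGeneric("background", function(object) standardGeneric("background"))

#' @rdname accessors
#' @export
setGeneric("weightEntries", function(object) standardGeneric("weightEntries"))

#' @rdname accessors
#' @export
setGeneric("reconMap", function(object) standardGeneric("reconMap"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("concValues", "ConcentrationMap", function(object) object@values)

#' @rdname accessors
setMethod("voxelSize", "ConcentrationMap", function(object) object@voxel_size)

#' @rdname accessors
setMethod("voxelSize", "Phantom", function(object) object@voxel_size)

#' @rdname accessors
setMethod("voxelSize", "WeightMatrix", function(object) object@voxel_size)

#' @rdname accessors
setMethod("gridOrigin", "ConcentrationMap", function(object) object@origin)

#' @rdname accessors
setMethod("gridOrigin", "WeightMatrix", function(object) object@origin)

#' @rdname accessors
setMethod("sinoValues", "Sinogram", function(object) object@values)

#' @rdname accessors
setMethod("viewAngles", "Sinogram", function(object) object@angles)

#' @rdname accessors
setMethod("viewAngles", "WeightMatrix", function(object) object@angles)

#' @rdname accessors
setMethod("translationOffsets", "Sinogram", function(object) object@offsets)

#' @rdname accessors
setMethod("translationOffsets", "WeightMatrix",
          function(object) object@offsets)

#' @rdname accessors
setMethod("nDetectors", "Sinogram",
          function(object) length(object@detector_offsets))

#' @rdname accessors
setMethod("nDetectors", "DetectorSet",
          function(object) length(object@angle_offsets))

#' @rdname accessors
setMethod("nDetectors", "WeightMatrix",
          function(object) length(object@detector_offsets))

#' @rdname accessors
setMethod("targetTable", "Phantom", function(object) object@targets)

#' @rdname accessors
setMethod("background", "Phantom", function(object) object@background)

#' @rdname accessors
setMethod("weightEntries", "WeightMatrix", function(object) object@A)

#' @rdname accessors
setMethod("reconMap", "ReconResult", function(object) object@map)

#' @rdname accessors
setMethod("trainingHistory", "ViewSynthModel",
          function(object) object@history)

## ---- show methods --------------------------------------------------------

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf(
    "OpticalProperties: mu_a = %g /cm, mu_s' = %g /cm, n = %g\n",
    object@mu_a, object@mu_s_prime, object@refractive_index))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf(
    "Phantom: cylinder radius %g mm, height %g mm, voxel %g mm, %d target(s)\n",
    object@radius, object@height, object@voxel_size, nrow(object@targets)))
  show(object@background)
  if (nrow(object@targets)) print(object@targets, row.names = FALSE)
})

setMethod("show", "ConcentrationMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ConcentrationMap: %d x %d x %d voxels of %g mm, max %g\n",
    d[1L], d[2L], d[3L], object@voxel_size, max(object@values)))
})

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf(
    "BeamSpec: %g um beam, %d x %g mm translations, %d views over %g deg, mu_x = %g /cm\n",
    object@diameter, object@n_translations, object@translation_step,
    object@n_views, object@angular_span, object@mu_x))
})

setMethod("show", "DetectorSet", function(object) {
  cat(sprintf(
    "DetectorSet: %d detector(s) at offsets %s deg, aperture %g mm^2\n",
    length(object@angle_offsets),
    paste(object@angle_offsets, collapse = ", "), object@aperture_area))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "Sinogram: %d views x %d translations x %d detectors (noise: %s)\n",
    d[1L], d[2L], d[3L], object@noise$model))
})

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf(
    "WeightMatrix: %d measurements x %d voxels, %d nonzeros\n",
    nrow(object@A), ncol(object@A), length(object@A@x)))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf(
    "ReconResult: %d iterations, final objective %.6g (lambda = %.3g)\n",
    object@iterations, object@objective[length(object@objective)],
    object@config$reg_weight))
})

setMethod("show", "NetConfig", function(object) {
  cat(sprintf(
    "NetConfig: stem 64, 4 residual blocks (3 x 64), tail 64-64-32-1, alpha = %g, seed = %d\n",
    object@loss_alpha, object@seed))
})

setMethod("show", "ViewSynthModel", function(object) {
  h <- object@history
  cat(sprintf(
    "ViewSynthModel: %d epochs trained, final train loss %.4g, input %d x %d views x translations\n",
    nrow(h), if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    object@input_shape[1L], object@input_shape[2L]))
})
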