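.sinogram_format <- "XLCTsynth-sinogram-1"

#' Read and write sinograms
#'
#' Sinograms are stored in a hierarchical JSON container with the value
#' array (views x translations x detectors, flattened view-fastest in
#' column-major order with its dimensions recorded), the axis metadata
#' (view angles, translation offsets, detector offsets) and the noise
#' record. Numbers are written at 17 significant digits so a write/read
#' round trip reproduces the values exactly. [sinogramTable()] gives a flat
#' delimited-text export for interoperability.
#'
#' @param sinogram a [Sinogram-class] object.
#' @param path file path.
#' @return \code{readSinogram} returns the [Sinogram-class];
#'   \code{writeSinogram} returns \code{path} invisibly.
#' @examples
#' s <- simulateScan(makePhantom(targets = sphericalTarget(c(0, 0, 10), 2, 1)),
#'                   beamSpec(n_translations = 10L, n_views = 3L))
#' f <- tempfile(fileext = ".json")
#' writeSinogram(s, f)
#' identical(sinoValues(readSinogram(f)), sinoValues(s))
#' @export
writeSinogram <- function(sinogram, path) {
  noise <- sinogram@noise
  if (is.null(noise$seed) || is.na(noise$seed)) noise$seed <- NULL
  obj <- list(
    format = .sinogram_format,
    dim = dim(sinogram@values),
    values = as.vector(sinogram@values),
    angles = sinogram@angles,
    offsets = sinogram@offsets,
    detector_offsets = sinogram@detector_offsets,
    noise = noise)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("readSinogram: malformed file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, .sinogram_format))
    stop("readSinogram: '", path, "' is not a sinogram container ",
         "(missing or wrong 'format' field)", call. = FALSE)
  for (f in c("dim", "values", "angles", "offsets", "detector_offsets"))
    if (is.null(obj[[f]]))
      stop("readSinogram: field '", f, "' missing in '", path, "'",
           call. = FALSE)
  d <- as.integer(obj$dim)
  if (length(obj$values) != prod(d))
    stop("readSinogram: field 'values' has length ", length(obj$values),
         ", expected ", prod(d), call. = FALSE)
  noise <- if (is.null(obj$noise))
    list(model = "none", level = 0, floor = 0, seed = NA_integer_)
  else obj$noise
  noise$seed <- if (is.null(noise$seed)) NA_integer_ else
    as.integer(noise$seed)
  new("Sinogram", values = array(obj$values, dim = d),
      angles = as.numeric(obj$angles), offsets = as.numeric(obj$offsets),
      detector_offsets = as.numeric(obj$detector_offsets), noise = noise)
}

#' Flat table export of a sinogram
#'
#' @param sinogram a [Sinogram-class].
#' @param path optional path; when given, the table is written as
#'   tab-separated text.
#' @return a data.frame with one row per reading (view, angle_deg,
#'   translation, offset_mm, detector, detector_offset_deg, value).
#' @export
sinogramTable <- function(sinogram, path = NULL) {
  d <- dim(sinogram@values)
  grid <- expand.grid(view = seq_len(d[1L]), translation = seq_len(d[2L]),
                      detector = seq_len(d[3L]))
  tab <- data.frame(
    view = grid$view,
    angle_deg = sinogram@angles[grid$view],
    translation = grid$translation,
    offset_mm = sinogram@offsets[grid$translation],
    detector = grid$detector,
    detector_offset_deg = sinogram@detector_offsets[grid$detector],
    value = as.vector(sinogram@values))
  if (!is.null(path))
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

## Flatten sinogram values in weight-matrix row order:
## detector fastest, then translation, then view.
.flattenSino <- function(values) as.vector(aperm(values, c(3L, 2L, 1L)))

#' Subset a sinogram to a set of views
#'
#' @param sinogram a [Sinogram-class].
#' @param views integer indices of the views to keep.
#' @return a [Sinogram-class] with the selected views and angles.
#' @export
subsetViews <- function(sinogram, views) {
  new("Sinogram", values = sinogram@values[views, , , drop = FALSE],
      angles = sinogram@angles[views], offsets = sinogram@offsets,
      detector_offsets = sinogram@detector_offsets,
      noise = sinogram@noise)
}
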