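#' Experiment configuration
#'
#' Bundles every stage's settings under a single root seed. The "desk"
#' profile (100 phantoms, 64x64 scan-slice grid, 6 training epochs) runs
#' the full pipeline at workstation scale; the "paper" profile uses the
#' published protocol sizes (400 phantoms, 0.25 mm voxels, 200 epochs).
#'
#' @param profile "desk" or "paper".
#' @param seed root integer seed; all stage seeds derive from it.
#' @param ... named overrides of individual fields.
#' @return a list of class \code{xlct_config}.
#' @examples
#' cfg <- experimentConfig("desk", seed = 1)
#' cfg$n_phantoms
#' @export
experimentConfig <- function(profile = c("desk", "paper"), seed = 1L,
                             ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    n_phantoms = if (profile == "desk") 100L else 400L,
    voxel_size = if (profile == "desk") 0.390625 else 0.25,
    few_views = 15L,
    full_views = 30L,
    n_translations = 50L,
    translation_step = 0.5,
    beam_diameter = 50,
    mu_x = 0.27,
    eta = 1,
    noise_level = 0.01,
    detector_offsets = c(90, 210, 330),
    aperture_area = 1,
    alpha = 0.8,
    epochs = if (profile == "desk") 10L else 200L,
    batch_size = if (profile == "desk") 4L else 8L,
    lr = 3e-4,
    warmup = 60L,
    adam_eps = 1e-8,
    val_frac = 0.1,
    test_frac = 0.1,
    recon_max_iter = if (profile == "desk") 3000L else 4000L,
    recon_tol = 1e-6)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("experimentConfig: unknown field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  class(cfg) <- "xlct_config"
  cfg
}

#' @export
print.xlct_config <- function(x, ...) {
  cat(sprintf(
    "XLCT experiment config ('%s' profile, seed %d): %d phantoms, voxel %g mm, %d/%d views, %d epochs\n",
    x$profile, x$seed, x$n_phantoms, x$voxel_size, x$few_views,
    x$full_views, x$epochs))
  invisible(x)
}

.cfgBeam <- function(cfg, n_views)
  beamSpec(diameter = cfg$beam_diameter,
           translation_step = cfg$translation_step,
           n_translations = cfg$n_translations, n_views = n_views,
           mu_x = cfg$mu_x)

.cfgDetectors <- function(cfg)
  detectorSet(cfg$detector_offsets, cfg$aperture_area)

#' The four-target validation phantom
#'
#' The fixed phantom used to validate the trained pipeline: a 12.5 mm
#' radius, 20 mm tall cylinder with background mu_a = 0.5 /cm,
#' mu_s' = 15 /cm, carrying four 1.5 mm radius targets of unit
#' concentration at (+-6, 0) and (0, +-6) mm on the scan plane.
#'
#' @param voxel_size rasterization voxel edge, mm.
#' @return a [Phantom-class].
#' @export
defaultValidationPhantom <- function(voxel_size = 0.390625) {
  makePhantom(
    radius = 12.5, height = 20,
    targets = rbind(sphericalTarget(c(6, 0, 10), 1.5, 1),
                    sphericalTarget(c(-6, 0, 10), 1.5, 1),
                    sphericalTarget(c(0, 6, 10), 1.5, 1),
                    sphericalTarget(c(0, -6, 10), 1.5, 1)),
    background = opticalProperties(0.5, 15),
    voxel_size = voxel_size)
}

.stageLog <- function(outdir, stage, cfg) {
  cfg_path <- file.path(outdir, paste0(stage, "-config.yaml"))
  yaml::write_yaml(unclass(cfg), cfg_path)
  message(sprintf("[%s] %s: config hash %s", format(Sys.time()), stage,
                  unname(tools::md5sum(cfg_path))))
  invisible(cfg_path)
}

#' Generate a phantom + sinogram dataset
#'
#' Draws seeded random phantoms, simulates each one's full-view sinogram
#' and subsets the odd views into the paired few-view sinogram (so the
#' few-view angles are exactly nested in the full-view grid), and writes
#' one JSON container per artifact plus a manifest table with per-phantom
#' seeds and checksums. Re-running with the same root seed reproduces the
#' phantom containers byte-for-byte.
#'
#' @param config an [experimentConfig()] list.
#' @param outdir writable output directory.
#' @return the manifest data.frame, invisibly.
#' @export
runGenerate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2L) != 0L)
    stop("runGenerate: output directory '", outdir, "' is not writable")
  .stageLog(outdir, "generate", config)
  pcfg <- phantomConfig(voxel_size = config$voxel_size)
  seeds <- withSeed(config$seed,
                    sample.int(.Machine$integer.max, config$n_phantoms))
  noise <- if (config$noise_level > 0)
    noiseConfig(level = config$noise_level, seed = config$seed) else NULL
  beam_full <- .cfgBeam(config, config$full_views)
  dets <- .cfgDetectors(config)
  rows <- vector("list", config$n_phantoms)
  for (i in seq_len(config$n_phantoms)) {
    ph <- randomPhantom(seeds[i], pcfg)
    full <- simulateScan(ph, beam_full, dets, eta = config$eta,
                         noise = noise)
    few <- subsetViews(full, seq(1L, config$full_views, by = 2L))
    pfile <- file.path(outdir, sprintf("phantom-%03d.json", i))
    ffile <- file.path(outdir, sprintf("sino-full-%03d.json", i))
    wfile <- file.path(outdir, sprintf("sino-few-%03d.json", i))
    writePhantom(ph, pfile)
    writeSinogram(full, ffile)
    writeSinogram(few, wfile)
    rows[[i]] <- data.frame(
      id = i, seed = seeds[i], phantom = basename(pfile),
      sino_few = basename(wfile), sino_full = basename(ffile),
      phantom_md5 = unname(tools::md5sum(pfile)))
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  message(sprintf("generated %d phantom/sinogram pairs in %s",
                  nrow(manifest), outdir))
  invisible(manifest)
}

.readManifest <- function(dataset_dir) {
  path <- file.path(dataset_dir, "manifest.tsv")
  if (!file.exists(path))
    stop("dataset manifest not found at '", path, "'", call. = FALSE)
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "seed", "phantom", "sino_few", "sino_full")
  if (!all(need %in% names(m)))
    stop("manifest at '", path, "' is missing column(s): ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  m
}

.loadPairs <- function(dataset_dir, manifest) {
  lapply(seq_len(nrow(manifest)), function(i)
    list(few = readSinogram(file.path(dataset_dir, manifest$sino_few[i])),
         full = readSinogram(file.path(dataset_dir,
                                       manifest$sino_full[i]))))
}

#' Train the view-synthesis network on a generated dataset
#'
#' @param config an [experimentConfig()] list (its seed fixes the split,
#'   initialization and batching).
#' @param dataset_dir directory written by [runGenerate()].
#' @param outdir output directory for the checkpoint and history table.
#' @param resume optional path to a previous checkpoint to continue from
#'   (history is appended).
#' @return the trained [ViewSynthModel-class], invisibly.
#' @export
runTrain <- function(config, dataset_dir, outdir, resume = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .stageLog(outdir, "train", config)
  manifest <- .readManifest(dataset_dir)
  pairs <- .loadPairs(dataset_dir, manifest)
  init <- if (!is.null(resume)) loadModel(resume) else NULL
  model <- trainViewSynth(
    pairs, netConfig(config$alpha, seed = config$seed),
    epochs = config$epochs, batch_size = config$batch_size,
    lr = config$lr, val_frac = config$val_frac,
    test_frac = config$test_frac, adam_eps = config$adam_eps,
    warmup = config$warmup, init = init, verbose = TRUE)
  ckpt <- file.path(outdir, "model.rds")
  saveModel(model, ckpt)
  write.table(trainingHistory(model), file.path(outdir, "history.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  message("checkpoint written to ", ckpt)
  invisible(model)
}

## Write a slice as an 8-bit grayscale PNG (runtime artifact).
writeSlicePNG <- function(map, path, data_range = NULL) {
  m <- if (is(map, "ConcentrationMap")) concValues(map)[, , 1L] else map
  if (is.null(data_range)) data_range <- max(m, 1e-12)
  img <- pmin(pmax(t(m[, rev(seq_len(ncol(m)))]) / data_range, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

.reconMetrics <- function(sino, A, gt, config) {
  rec <- reconstructTV(sino, A, max_iter = config$recon_max_iter,
                       tol = config$recon_tol)
  m <- concValues(reconMap(rec))[, , 1L]
  g <- concValues(gt)[, , 1L]
  list(recon = rec,
       psnr = psnr(g, m, data_range = max(g)),
       ssim = ssim(g, m, data_range = max(g)))
}

.validateOne <- function(ph, few, full, model, config) {
  gt <- scanSlice(ph)
  A15 <- buildWeightMatrix(ph, .cfgBeam(config, config$few_views),
                           .cfgDetectors(config), eta = config$eta)
  A30 <- buildWeightMatrix(ph, .cfgBeam(config, config$full_views),
                           .cfgDetectors(config), eta = config$eta)
  synth <- predictSinogram(model, few)
  list(few = .reconMetrics(few, A15, gt, config),
       synth = .reconMetrics(synth, A30, gt, config),
       full = .reconMetrics(full, A30, gt, config),
       gt = gt)
}

#' Validate a trained model
#'
#' For every held-out test phantom of the dataset and for the fixed
#' four-target validation phantom, reconstructs the scan slice from (a) the
#' raw 15-view sinogram, (b) the network-synthesized 30-view sinogram and
#' (c) the ground-truth 30-view sinogram, scores each against the
#' rasterized ground truth with PSNR and SSIM, and writes a machine- and a
#' human-readable report plus slice images for the validation phantom.
#'
#' @param config an [experimentConfig()] list.
#' @param dataset_dir directory written by [runGenerate()].
#' @param checkpoint path to a checkpoint from [runTrain()], or a
#'   [ViewSynthModel-class].
#' @param outdir report output directory.
#' @return list with elements \code{report} (per-phantom data.frame),
#'   \code{aggregate} (condition means) and \code{validation} (the
#'   four-target phantom metrics), invisibly.
#' @export
runValidate <- function(config, dataset_dir, checkpoint, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .stageLog(outdir, "validate", config)
  model <- if (is(checkpoint, "ViewSynthModel")) checkpoint else
    loadModel(checkpoint)
  if (model@input_shape[1L] != config$few_views ||
      model@input_shape[2L] != config$n_translations)
    stop("runValidate: checkpoint input shape (",
         paste(model@input_shape, collapse = ", "),
         ") is incompatible with the configuration")
  manifest <- .readManifest(dataset_dir)
  splits <- splitPairs(nrow(manifest), model@config@seed,
                       config$val_frac, config$test_frac)
  rows <- list()
  for (i in splits$test) {
    ph <- readPhantom(file.path(dataset_dir, manifest$phantom[i]))
    few <- readSinogram(file.path(dataset_dir, manifest$sino_few[i]))
    full <- readSinogram(file.path(dataset_dir, manifest$sino_full[i]))
    res <- .validateOne(ph, few, full, model, config)
    for (cond in c("few", "synth", "full"))
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = as.character(manifest$id[i]), condition = cond,
        psnr = res[[cond]]$psnr, ssim = res[[cond]]$ssim)
  }
  vph <- defaultValidationPhantom(config$voxel_size)
  dets <- .cfgDetectors(config)
  vnoise <- if (config$noise_level > 0)
    noiseConfig(level = config$noise_level, seed = config$seed + 1L) else
    NULL
  vfull <- simulateScan(vph, .cfgBeam(config, config$full_views), dets,
                        eta = config$eta, noise = vnoise)
  vfew <- subsetViews(vfull, seq(1L, config$full_views, by = 2L))
  vres <- .validateOne(vph, vfew, vfull, model, config)
  for (cond in c("few", "synth", "full"))
    rows[[length(rows) + 1L]] <- data.frame(
      phantom = "validation", condition = cond,
      psnr = vres[[cond]]$psnr, ssim = vres[[cond]]$ssim)
  report <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(report, report$condition), function(d)
    data.frame(condition = d$condition[1L], mean_psnr = mean(d$psnr),
               mean_ssim = mean(d$ssim), n = nrow(d))))
  write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(report = report, aggregate = agg,
         validation = list(
           psnr_few = vres$few$psnr, ssim_few = vres$few$ssim,
           psnr_synth = vres$synth$psnr, ssim_synth = vres$synth$ssim,
           psnr_full = vres$full$psnr, ssim_full = vres$full$ssim),
         provenance = list(
           package = as.character(utils::packageVersion("XLCTsynth")),
           seed = config$seed, profile = config$profile,
           timestamp = format(Sys.time(), tz = "UTC"))),
    file.path(outdir, "report.json"), digits = I(10), auto_unbox = TRUE)
  gtr <- max(concValues(vres$gt))
  writeSlicePNG(vres$gt, file.path(outdir, "validation-truth.png"), gtr)
  writeSlicePNG(reconMap(vres$few$recon),
                file.path(outdir, "validation-few.png"), gtr)
  writeSlicePNG(reconMap(vres$synth$recon),
                file.path(outdir, "validation-synth.png"), gtr)
  writeSlicePNG(reconMap(vres$full$recon),
                file.path(outdir, "validation-full.png"), gtr)
  message(sprintf(
    "validation phantom: few-view PSNR %.2f dB / SSIM %.4f; synthesized %.2f dB / %.4f; full %.2f dB / %.4f",
    vres$few$psnr, vres$few$ssim, vres$synth$psnr, vres$synth$ssim,
    vres$full$psnr, vres$full$ssim))
  invisible(list(report = report, aggregate = agg,
                 validation = list(
                   psnr_few = vres$few$psnr, ssim_few = vres$few$ssim,
                   psnr_synth = vres$synth$psnr,
                   ssim_synth = vres$synth$ssim,
                   psnr_full = vres$full$psnr,
                   ssim_full = vres$full$ssim)))
}

#' Print a validation report
#'
#' @param outdir directory containing \code{report.json} from
#'   [runValidate()].
#' @return the aggregate table, invisibly.
#' @export
runReport <- function(outdir) {
  path <- file.path(outdir, "report.json")
  if (!file.exists(path)) stop("runReport: no report at '", path, "'")
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat("Condition means (PSNR dB / SSIM):\n")
  print(rep$aggregate, row.names = FALSE)
  cat("\nFour-target validation phantom:\n")
  v <- rep$validation
  cat(sprintf("  few-view    : %.2f dB / %.4f\n", v$psnr_few, v$ssim_few))
  cat(sprintf("  synthesized : %.2f dB / %.4f\n", v$psnr_synth,
              v$ssim_synth))
  cat(sprintf("  true 30-view: %.2f dB / %.4f\n", v$psnr_full,
              v$ssim_full))
  invisible(rep$aggregate)
}
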