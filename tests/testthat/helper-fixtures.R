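# Small, fast fixtures shared across the suite. Everything is generated in
# code; no data files.

tinyPhantom <- function(targets = sphericalTarget(c(2, -1, 6), 1.5, 1),
                        radius = 6, height = 12, voxel = 0.5) {
  makePhantom(radius = radius, height = height, targets = targets,
              background = opticalProperties(0.5, 15),
              voxel_size = voxel)
}

tinyBeam <- function(n_views = 6L, n_translations = 13L,
                     step = 1, mu_x = 0.27)
  beamSpec(translation_step = step, n_translations = n_translations,
           n_views = n_views, mu_x = mu_x)

deskPhantom <- function(seed, n_targets = NULL) {
  cfg <- phantomConfig(voxel_size = 0.390625)
  if (!is.null(n_targets))
    cfg <- phantomConfig(voxel_size = 0.390625,
                         n_targets_range = c(n_targets, n_targets))
  randomPhantom(seed, cfg)
}

# Synthetic nested few/full sinogram pair with smooth structured values,
# for network tests that do not need the physics simulator.
syntheticPair <- function(seed, n_few = 15L, n_trans = 12L, n_det = 1L) {
  withr::with_seed(seed, {
    full_angles <- (0:(2L * n_few - 1L)) * (180 / (2L * n_few))
    offs <- (seq_len(n_trans) - (n_trans + 1) / 2) * 0.5
    vals <- array(0, dim = c(2L * n_few, n_trans, n_det))
    for (d in seq_len(n_det)) {
      amp <- runif(1L, 0.5, 2); ph <- runif(1L, 0, pi)
      cen <- runif(1L, 1.5, 2.5)   # wide sinusoid excursion
      vals[, , d] <- outer(full_angles, offs, function(a, t)
        amp * exp(-((t - cen * cos(a * pi / 90 + ph)) / 0.8)^2))
    }
    full <- new("Sinogram", values = vals, angles = full_angles,
                offsets = offs, detector_offsets = seq_len(n_det) * 120 - 30,
                noise = list(model = "none", level = 0, floor = 0,
                             seed = NA_integer_))
    list(few = subsetViews(full, seq(1L, 2L * n_few, by = 2L)),
         full = full)
  })
}

# Independent closed-form infinite-medium diffusion kernel (cm units),
# written separately from the package implementation.
oracleGreenInf <- function(d_mm, mu_a, mu_sp) {
  D <- 1 / (3 * (mu_a + mu_sp))
  mueff <- sqrt(3 * mu_a * (mu_a + mu_sp))
  r <- d_mm / 10
  exp(-mueff * r) / (4 * pi * D * r)
}
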