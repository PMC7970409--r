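test_that("makePhantom validates containment and overlap", {
  ph <- makePhantom(radius = 12.5, height = 20,
                    targets = rbind(sphericalTarget(c(6, 0, 10), 1.5, 1),
                                    sphericalTarget(c(-6, 0, 10), 1.5, 1),
                                    sphericalTarget(c(0, 6, 10), 1.5, 1),
                                    sphericalTarget(c(0, -6, 10), 1.5, 1)),
                    background = opticalProperties(0.5, 15))
  expect_s4_class(ph, "Phantom")
  expect_equal(nrow(targetTable(ph)), 4L)

  expect_error(
    makePhantom(radius = 5, targets = sphericalTarget(c(4.5, 0, 10), 1, 1)),
    "target\\(s\\) 1 not contained")
  expect_error(
    makePhantom(targets = rbind(sphericalTarget(c(0, 0, 10), 2, 1),
                                sphericalTarget(c(3, 0, 10), 2, 1))),
    "overlap.*\\(1,2\\)")
})

test_that("an empty phantom rasterizes to the zero map", {
  ph <- makePhantom(radius = 6, height = 8, voxel_size = 0.5)
  expect_true(all(concValues(rasterizeConcentration(ph)) == 0))
  expect_true(all(concValues(scanSlice(ph)) == 0))
})

test_that("rasterized sphere matches the brute-force voxel-center oracle", {
  ph <- makePhantom(radius = 6, height = 10, voxel_size = 0.25,
                    targets = sphericalTarget(c(1.3, -0.7, 5), 1, 1))
  m <- rasterizeConcentration(ph)
  count <- sum(concValues(m) > 0)

  # oracle: exhaustive center-in-sphere test over the same grid
  v <- voxelSize(m)
  o <- gridOrigin(m)
  d <- dim(concValues(m))
  oracle <- 0L
  for (k in seq_len(d[3L])) {
    z <- o[3L] + (k - 1L) * v
    dz2 <- (z - 5)^2
    if (dz2 > 1) next
    xs <- o[1L] + (seq_len(d[1L]) - 1L) * v
    ys <- o[2L] + (seq_len(d[2L]) - 1L) * v
    oracle <- oracle + sum(outer((xs - 1.3)^2, (ys + 0.7)^2, `+`) +
                             dz2 <= 1)
  }
  expect_identical(count, as.integer(oracle))
  # and the count is within 15% of the continuum sphere volume
  expect_lt(abs(count - (4 / 3) * pi * (1 / 0.25)^3),
            0.15 * (4 / 3) * pi * (1 / 0.25)^3)
})

test_that("rasterized mass matches analytic sphere volumes within 15%", {
  tg <- rbind(sphericalTarget(c(3, 2, 10), 1.2, 0.8),
              sphericalTarget(c(-4, -1, 10), 2, 1.6))
  ph <- makePhantom(targets = tg, voxel_size = 0.25)
  m <- concValues(rasterizeConcentration(ph))
  mass <- sum(m) * voxelSize(rasterizeConcentration(ph))^3
  analytic <- sum((4 / 3) * pi * tg$radius^3 * tg$concentration)
  expect_lt(abs(mass - analytic) / analytic, 0.15)
})

test_that("rasterization is exactly linear in concentration", {
  tg <- rbind(sphericalTarget(c(3, 2, 10), 1.2, 0.8),
              sphericalTarget(c(-4, -1, 10), 2, 1.6))
  ph1 <- makePhantom(targets = tg, voxel_size = 0.5)
  tg2 <- tg; tg2$concentration <- 2 * tg2$concentration
  ph2 <- makePhantom(targets = tg2, voxel_size = 0.5)
  expect_identical(2 * concValues(rasterizeConcentration(ph1)),
                   concValues(rasterizeConcentration(ph2)))
  expect_identical(2 * concValues(scanSlice(ph1)),
                   concValues(scanSlice(ph2)))
})

test_that("random phantoms are reproducible and respect all invariants", {
  expect_identical(randomPhantom(7L), randomPhantom(7L))

  cfg <- phantomConfig()
  for (seed in seq_len(400L)) {
    ph <- randomPhantom(seed, cfg)
    expect_true(validObject(ph))      # containment + overlap via validity
    tg <- targetTable(ph)
    expect_true(all(sqrt(tg$x^2 + tg$y^2) + tg$radius <=
                      ph@radius + 1e-9))
    expect_true(all(tg$z - tg$radius >= -1e-9 &
                      tg$z + tg$radius <= ph@height + 1e-9))
  }
})

test_that("zero optical perturbation pins the nominal coefficients", {
  cfg <- phantomConfig(optical_perturbation = 0)
  for (seed in c(1L, 9L, 33L)) {
    bg <- background(randomPhantom(seed, cfg))
    expect_equal(bg@mu_a, 0.5)
    expect_equal(bg@mu_s_prime, 15)
  }
})

test_that("impossible placement raises a placement error", {
  cfg <- phantomConfig(radius_range = c(5, 5),
                       n_targets_range = c(6L, 6L),
                       target_radius_range = c(2.4, 2.4),
                       max_attempts = 50L)
  expect_error(randomPhantom(1L, cfg), "unable to place target")
})

test_that("phantom serialization round-trips and rejects bad files", {
  ph <- randomPhantom(12L, phantomConfig(voxel_size = 0.5))
  f <- tempfile(fileext = ".json")
  writePhantom(ph, f)
  back <- readPhantom(f)
  expect_equal(back@radius, ph@radius)
  expect_equal(back@height, ph@height)
  expect_equal(targetTable(back), targetTable(ph))
  expect_equal(background(back)@mu_a, background(ph)@mu_a)
  expect_identical(concValues(scanSlice(back)), concValues(scanSlice(ph)))

  y <- tempfile(fileext = ".yaml")
  writePhantomSummary(ph, y)
  smry <- yaml::read_yaml(y)
  expect_equal(smry$phantom$n_targets, nrow(targetTable(ph)))

  bad <- tempfile(fileext = ".json")
  writeLines('{"not": "a phantom"}', bad)
  expect_error(readPhantom(bad), "not a phantom container")
})
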