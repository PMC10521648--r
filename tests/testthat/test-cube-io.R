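test_that("cube write/read round-trips values and metadata exactly", {
  dir <- withr::local_tempdir()
  cube <- spectral_cube(array(1, c(8, 8, 4)), c(220, 255, 280, 300))
  p <- file.path(dir, "ones.tiff")
  write_cube(cube, p, grid_position = c(2, 3))
  back <- read_cube(p)
  expect_identical(back$values, cube$values)
  expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
  expect_identical(back$domain, "transmission")
  expect_identical(attr(back, "grid_position"), c(2L, 3L))

  # random cube on the 16-bit storage grid: representable exactly
  set.seed(42)
  vals <- array(sample(0:65535, 32 * 32 * 4, replace = TRUE) / 65535,
                c(32, 32, 4))
  cube2 <- spectral_cube(vals, c(220, 255, 280, 300), 250, "absorbance")
  p2 <- file.path(dir, "rand.tiff")
  write_cube(cube2, p2)
  expect_identical(read_cube(p2)$values, vals)

  # values above 1 go through the sidecar value_scale
  v3 <- 4 * sample(0:65535, 64, TRUE) / 65535
  v3[1] <- 4                              # pin the scale to 4
  cube3 <- spectral_cube(array(v3, c(4, 4, 4)),
                         c(220, 255, 280, 300), 250, "absorbance")
  p3 <- file.path(dir, "scaled.tiff")
  write_cube(cube3, p3)
  expect_identical(read_cube(p3)$values, cube3$values)

  # storage is idempotent for arbitrary values: a second round trip is exact
  v4 <- array(runif(4 * 4 * 4, 0, 3), c(4, 4, 4))
  p4 <- file.path(dir, "arb.tiff")
  write_cube(spectral_cube(v4, c(220, 255, 280, 300), 250, "absorbance"), p4)
  once <- read_cube(p4)
  expect_lt(max(abs(once$values - v4)), 4 / 65535)  # quantization bound
  write_cube(once, p4)
  expect_identical(read_cube(p4)$values, once$values)
})

test_that("cube reader rejects inconsistent metadata", {
  dir <- withr::local_tempdir()
  cube <- spectral_cube(array(1, c(6, 6, 3)), c(220, 255, 280))
  p <- file.path(dir, "c.tiff")
  write_cube(cube, p)
  meta <- yaml::read_yaml(file.path(dir, "c.meta.yaml"))
  meta$wavelengths_nm <- c(220, 255, 280, 300)  # four listed, three stored
  yaml::write_yaml(meta, file.path(dir, "c.meta.yaml"))
  expect_error(read_cube(p), "mismatch")
  file.remove(file.path(dir, "c.meta.yaml"))
  expect_error(read_cube(p), "sidecar")
})

test_that("spectral_cube enforces its invariants", {
  expect_error(spectral_cube(array(1, c(4, 4, 3)), c(220, 255, 280, 300)),
               "channel count")
  expect_error(spectral_cube(array(1, c(4, 4, 2)), c(255, 220)), "increasing")
  expect_error(spectral_cube(array(-1, c(4, 4, 2)), c(220, 255)), "nonnegative")
})

test_that("absorbance conversion matches the Beer-Lambert oracle", {
  wl <- c(220, 255, 280, 300)
  ref <- spectral_cube(array(100, c(5, 5, 4)), wl)
  expect_equal(compute_absorbance(ref, ref)$values, array(0, c(5, 5, 4)))

  tenth <- spectral_cube(array(10, c(5, 5, 4)), wl)
  expect_equal(compute_absorbance(tenth, ref)$values, array(1, c(5, 5, 4)))

  set.seed(7)
  i <- array(runif(5 * 5 * 4, 1, 200), c(5, 5, 4))
  i0 <- array(runif(5 * 5 * 4, 100, 300), c(5, 5, 4))
  got <- compute_absorbance(spectral_cube(i, wl), spectral_cube(i0, wl))
  for (k in seq_along(i)) {
    expect_identical(got$values[k], max(-log10(i[k] / i0[k]), 0))
  }
  expect_identical(got$domain, "absorbance")
})

test_that("absorbance is order-preserving and clips negative OD to zero", {
  wl <- c(220, 255)
  ref <- spectral_cube(array(100, c(4, 4, 2)), wl)
  lo <- spectral_cube(array(20, c(4, 4, 2)), wl)
  hi <- spectral_cube(array(60, c(4, 4, 2)), wl)
  expect_true(all(compute_absorbance(lo, ref)$values >
                  compute_absorbance(hi, ref)$values))
  over <- spectral_cube(array(150, c(4, 4, 2)), wl)  # brighter than blank
  expect_equal(compute_absorbance(over, ref)$values, array(0, c(4, 4, 2)))
  expect_error(compute_absorbance(lo, spectral_cube(array(0, c(4, 4, 2)), wl)),
               "nonpositive")
  expect_error(compute_absorbance(lo, spectral_cube(array(1, c(3, 3, 2)), wl)),
               "shape")
})

test_that("channel registration recovers constructed integer shifts", {
  set.seed(11)
  base <- matrix(runif(48 * 40), 48, 40)
  same <- spectral_cube(array(rep(base, 3), c(48, 40, 3)), c(220, 255, 280))
  reg <- register_channels(same)
  expect_true(all(attr(reg, "shifts") == 0))
  expect_identical(dim(reg$values), c(48L, 40L, 3L))

  rolled <- base[c(46:48, 1:45), c(3:40, 1:2)]  # roll by (+3, -2)
  cube <- spectral_cube(array(c(base, rolled), c(48, 40, 2)), c(220, 255))
  reg <- register_channels(cube)
  expect_equal(unname(attr(reg, "shifts")[2, ]), c(-3, 2))
  expect_identical(reg$values[, , 1], reg$values[, , 2])

  # after registration the cross-correlation peak of every channel sits at
  # zero lag
  for (k in 2:dim(reg$values)[3]) {
    s <- uvstain:::cross_correlation_shift(reg$values[, , 1],
                                           reg$values[, , k])
    expect_equal(unname(s), c(0, 0))
  }

  flat <- spectral_cube(array(c(base, matrix(1, 48, 40)), c(48, 40, 2)),
                        c(220, 255))
  expect_error(register_channels(flat), "constant")
})

test_that("stitching reassembles a cut mosaic and respects size bounds", {
  set.seed(5)
  wl <- c(220, 255)
  img <- array(runif(64 * 120 * 2), c(64, 120, 2))
  cube <- spectral_cube(img, wl)

  one <- stitch_tiles(tile_grid(list(cube), 1, 1, 0))
  expect_equal(one$values, cube$values)
  expect_identical(attr(one, "tiles_consumed"), 1L)

  # 2x1 vertical cut at exact 15% overlap
  grid <- cut_into_tiles(cube, 2, 1, 0.15)
  mosaic <- stitch_tiles(grid)
  expect_identical(dim(mosaic$values), dim(cube$values))
  expect_lt(max(abs(mosaic$values - cube$values)), 1e-6)

  grid9 <- cut_into_tiles(spectral_cube(array(runif(76 * 76 * 2),
                                              c(76, 76, 2)), wl), 3, 3, 0.15)
  m9 <- stitch_tiles(grid9)
  expect_identical(attr(m9, "tiles_consumed"), 9L)
  d <- dim(m9$values)
  tile_d <- dim(grid9$tiles[[1]]$values)
  expect_gte(d[1], tile_d[1]); expect_gte(d[2], tile_d[2])
  expect_lte(d[1], 3 * tile_d[1]); expect_lte(d[2], 3 * tile_d[2])
  expect_error(tile_grid(grid9$tiles[1:8], 3, 3), "number of tiles")
})

test_that("diffraction resolution follows r = lambda / (2 NA)", {
  expect_identical(diffraction_resolution(250, 0.5), 250)
  for (lam in c(220, 255, 280, 300))
    expect_identical(diffraction_resolution(lam, 0.5), lam)
  expect_equal(diffraction_resolution(300, 0.8),
               diffraction_resolution(300, 0.4) / 2)
  expect_error(diffraction_resolution(-250, 0.5), "positive")
  expect_error(diffraction_resolution(250, 1.5), "aperture")
})
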