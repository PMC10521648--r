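# Build the two spherical maps the classifier consumes from per-class
# constant angles laid out in quadrant blocks.
blocks_sph <- function(az_by_class, el_by_class, n = 8) {
  classes <- c("stroma_cytoplasm", "luminal_fibroblast",
               "inflammation", "basal")
  az <- matrix(0, 2 * n, 2 * n); el <- az; r <- az
  rr <- list(1:n, 1:n, (n + 1):(2 * n), (n + 1):(2 * n))
  cc <- list(1:n, (n + 1):(2 * n), 1:n, (n + 1):(2 * n))
  rois <- list()
  for (i in 1:4) {
    az[rr[[i]], cc[[i]]] <- az_by_class[[classes[i]]]
    el[rr[[i]], cc[[i]]] <- el_by_class[[classes[i]]]
    r[rr[[i]], cc[[i]]] <- 1
    m <- matrix(FALSE, 2 * n, 2 * n); m[rr[[i]], cc[[i]]] <- TRUE
    rois[[classes[i]]] <- m
  }
  list(sph123 = synthetic_sph(az, el, r, c(1, 2, 3)),
       sph234 = synthetic_sph(az, el, r, c(2, 3, 4)),
       rois = rois)
}

deg <- function(x) x * pi / 180

test_that("calibration places boundaries at circular midpoints", {
  s <- blocks_sph(list(stroma_cytoplasm = deg(-90), luminal_fibroblast = deg(0),
                       inflammation = deg(90), basal = deg(180)),
                  list(stroma_cytoplasm = deg(-10), luminal_fibroblast = deg(20),
                       inflammation = deg(25), basal = deg(30)))
  iv <- calibrate_intervals(s$sph123, s$sph234, s$rois)
  bounds <- sort(sapply(iv$azimuth_intervals, function(v) v["lower"]))
  expect_equal(unname(sort(round(bounds * 180 / pi, 6))),
               c(-135, -45, 45, 135))
  # each interval contains its own class mean
  for (cl in names(iv$azimuth_intervals)) {
    v <- iv$azimuth_intervals[[cl]]
    m <- iv$class_mean_azimuth[[cl]]
    inside <- if (v[1] <= v[2]) m >= v[1] && m < v[2] else m >= v[1] || m < v[2]
    expect_true(inside)
  }
  # elevation gate covers nuclei elevations with a 5% margin
  expect_lt(iv$nuclei_elevation_interval[1], deg(20))
  expect_gt(iv$nuclei_elevation_interval[2], deg(30))
})

test_that("calibration handles single pixels and rejects degeneracies", {
  s <- blocks_sph(list(stroma_cytoplasm = deg(-120), luminal_fibroblast = deg(-20),
                       inflammation = deg(40), basal = deg(100)),
                  list(stroma_cytoplasm = deg(-5), luminal_fibroblast = deg(15),
                       inflammation = deg(18), basal = deg(22)), n = 1)
  iv <- calibrate_intervals(s$sph123, s$sph234, s$rois)
  expect_equal(unname(iv$class_mean_azimuth["basal"]), deg(100),
               tolerance = 1e-12)

  bad <- s$rois; bad$basal <- matrix(FALSE, 2, 2)
  expect_error(calibrate_intervals(s$sph123, s$sph234, bad), "no nonzero")
  s2 <- blocks_sph(list(stroma_cytoplasm = deg(10), luminal_fibroblast = deg(10),
                        inflammation = deg(40), basal = deg(100)),
                   list(stroma_cytoplasm = deg(-5), luminal_fibroblast = deg(15),
                        inflammation = deg(18), basal = deg(22)), n = 1)
  expect_error(calibrate_intervals(s2$sph123, s2$sph234, s2$rois), "identical")
})

test_that("two-step classification recovers a constructed scene exactly", {
  s <- blocks_sph(list(stroma_cytoplasm = deg(-120), luminal_fibroblast = deg(-20),
                       inflammation = deg(40), basal = deg(120)),
                  list(stroma_cytoplasm = deg(-6), luminal_fibroblast = deg(14),
                       inflammation = deg(17), basal = deg(21)))
  iv <- calibrate_intervals(s$sph123, s$sph234, s$rois)
  nuc <- segment_nuclei(s$sph123, iv)
  expect_false(any(nuc[s$rois$stroma_cytoplasm]))
  expect_true(all(nuc[s$rois$basal | s$rois$inflammation |
                      s$rois$luminal_fibroblast]))
  lm <- classify_nuclei(s$sph234, nuc, iv)
  expect_equal(sum(lm$labels == 4), sum(s$rois$basal))
  expect_equal(sum(lm$labels == 3), sum(s$rois$inflammation))
  expect_equal(sum(lm$labels == 2), sum(s$rois$luminal_fibroblast))
  expect_equal(sum(lm$labels == 1), sum(s$rois$stroma_cytoplasm))
  # exhaustive and exclusive by construction of the integer map
  expect_true(all(lm$labels %in% 0:4))

  # zero-radius pixel is never a nucleus regardless of angle
  s$sph123$radius[1, 1] <- 0
  expect_false(segment_nuclei(s$sph123, iv)[1, 1])
  # triplet mismatches are refused
  expect_error(segment_nuclei(s$sph234, iv), "1,2,3")
  expect_error(classify_nuclei(s$sph123, nuc, iv), "2,3,4")
})

test_that("classification depends only on angles, not on radius", {
  s <- blocks_sph(list(stroma_cytoplasm = deg(-120), luminal_fibroblast = deg(-20),
                       inflammation = deg(40), basal = deg(120)),
                  list(stroma_cytoplasm = deg(-6), luminal_fibroblast = deg(14),
                       inflammation = deg(17), basal = deg(21)))
  iv <- calibrate_intervals(s$sph123, s$sph234, s$rois)
  nuc <- segment_nuclei(s$sph123, iv)
  lm1 <- classify_nuclei(s$sph234, nuc, iv)
  s$sph234$radius <- s$sph234$radius * matrix(runif(256, 0.5, 3), 16, 16)
  lm2 <- classify_nuclei(s$sph234, nuc, iv)
  expect_identical(lm1$labels, lm2$labels)
})

test_that("zero-noise phantom is segmented with IoU 1 against ground truth", {
  ph <- small_phantom(seed = 6, snr = Inf)
  cube <- compute_absorbance(ph$transmission, ph$reference)
  basis <- fit_basis(sample_spectra(cube, masks = ph$labels$labels > 0,
                                    max_count = 3e4, seed = 1))
  sph123 <- to_spherical(project_cube(cube, basis, c(1, 2, 3)))
  sph234 <- to_spherical(project_cube(cube, basis, c(2, 3, 4)))
  iv <- calibrate_intervals(sph123, sph234, ph$rois)
  nuc <- segment_nuclei(sph123, iv)
  truth_nuc <- ph$labels$labels %in% 2:4
  expect_equal(sum(nuc & truth_nuc) / sum(nuc | truth_nuc), 1.0)
  lm <- classify_nuclei(sph234, nuc, iv, ph$labels$pixel_size_nm)
  expect_equal(mean(lm$labels == ph$labels$labels), 1.0)
})

test_that("despeckle matches the flood-fill oracle and is idempotent", {
  params <- morphology_params(min_component_area_px = 5)
  # single isolated basal pixel is relabeled to stroma
  lab <- matrix(1L, 9, 9); lab[5, 5] <- 4L
  out <- despeckle(label_map(lab), params)
  expect_identical(out$labels[5, 5], 1L)
  # a component of exactly the threshold area is retained
  lab2 <- matrix(1L, 9, 9); lab2[3, 3:7] <- 4L
  expect_identical(despeckle(label_map(lab2), params)$labels, lab2)

  for (rep in 1:25) {
    set.seed(200 + rep)
    lab <- matrix(sample(0:4, 32 * 32, TRUE, prob = c(.1, .45, .2, .15, .1)),
                  32, 32)
    for (conn in c(4L, 8L)) {
      p <- morphology_params(min_component_area_px = 6, connectivity = conn)
      got <- despeckle(label_map(lab), p)
      # oracle: flood-fill every nuclear class, relabel small components
      want <- lab
      for (code in c(2L, 3L, 4L)) {
        cc <- flood_fill_components(lab == code, conn)
        sizes <- tabulate(cc[cc > 0])
        want[cc %in% which(sizes < 6)] <- 1L
      }
      expect_identical(got$labels, want)
      expect_identical(despeckle(got, p)$labels, got$labels)  # idempotent
      # never adds pixels to a nuclear class
      for (code in c(2L, 3L, 4L))
        expect_true(all(which(got$labels == code) %in% which(lab == code)))
    }
  }
})

test_that("connected-component labeling agrees with flood fill", {
  for (rep in 1:20) {
    set.seed(300 + rep)
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4L, 8L)) {
      got <- label_components(mask, conn)
      want <- flood_fill_components(mask, conn)
      expect_identical(component_inventory(got), component_inventory(want))
    }
  }
})

test_that("Prewitt gradient matches naive convolution", {
  expect_equal(prewitt_gradient(matrix(3.7, 10, 10)), matrix(0, 10, 10))
  # vertical step edge: interior magnitude equals direct kernel convolution
  img <- cbind(matrix(0, 8, 4), matrix(2, 8, 4))
  got <- prewitt_gradient(img)
  expect_equal(got[4, 4], 6)   # 3 * step height on the edge column
  expect_equal(got, naive_prewitt(img), tolerance = 1e-12)
  for (rep in 1:10) {
    set.seed(400 + rep)
    img <- matrix(runif(16 * 16), 16, 16)
    expect_equal(prewitt_gradient(img), naive_prewitt(img), tolerance = 1e-12)
  }
  expect_error(prewitt_gradient(matrix(1, 2, 5)), "3x3")
})

test_that("the morphology filter keeps thin structures, drops round blobs", {
  lab <- matrix(1L, 96, 96)
  # thin elongated structure (3 px wide) with basal label
  lab[20:80, 30:32] <- 4L
  # large round cluster, also labeled basal but inflammation-shaped
  rows <- matrix(seq_len(96), 96, 96); cols <- t(rows)
  blob <- sqrt((rows - 60)^2 + (cols - 70)^2) < 14
  lab[blob] <- 4L
  lm <- basal_morphology_filter(label_map(lab))
  expect_true(all(lm$labels[20:80, 30:32] == 4L))        # thin ring kept
  expect_true(all(lm$labels[blob] == 3L))                # blob -> inflammation
  # basal output is a subset of basal input
  expect_true(all(which(lm$labels == 4L) %in% which(lab == 4L)))
  # untouched when no basal candidates exist
  lab0 <- matrix(1L, 20, 20); lab0[5:9, 5:9] <- 3L
  expect_identical(basal_morphology_filter(label_map(lab0))$labels, lab0)
  # all other labels unchanged
  expect_identical(lm$labels == 2L, lab == 2L)
})
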