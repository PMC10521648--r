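#' Run the full stain-free virtual-staining pipeline
#'
#' Orchestrates the complete chain on a transmission cube (or tile grid):
#' stitch (if tiles) -> absorbance -> channel registration -> projection
#' onto PC(1,2,3) and PC(2,3,4) -> spherical transform -> interval
#' calibration (or loading) -> nuclei segmentation -> subtype
#' classification -> despeckling -> basal morphology filter -> rendering
#' of the optical stains, virtual p63 and four-channel map.
#'
#' Either `intervals` or calibration `rois` must be supplied: the angular
#' decision thresholds are slide-calibrated quantities, not universal
#' constants, so the pipeline refuses to guess them (the check happens
#' before any computation).
#'
#' @param input a transmission- or absorbance-domain [spectral_cube()], or
#'   a [tile_grid()] to stitch first.
#' @param reference optional blank [spectral_cube()] for
#'   [compute_absorbance()]; when `NULL`, the per-channel 99.9th-percentile
#'   fallback is used.
#' @param rois named list of logical class masks for
#'   [calibrate_intervals()] (required unless `intervals` is given).
#' @param intervals a precomputed [calibrate_intervals()] result.
#' @param basis optional [fit_basis()] result; fitted fresh from the cube
#'   when `NULL`.
#' @param params [morphology_params()].
#' @param max_spectra cap on pooled spectra for basis fitting.
#' @param seed seed for the spectrum subsample.
#' @param register logical; run [register_channels()] (default `TRUE`).
#' @param output_dir optional directory; when given, the label map
#'   (`labels.tiff`), stain images (`p63.png`, `four_channel.png`,
#'   `optical_elevation.png`, `optical_azimuth.png`), basis, intervals and
#'   a JSON run report are written there.
#' @return Invisible list with `labels` ([label_map()]), `nuclei_mask`,
#'   `basis`, `intervals`, `sph123`, `sph234`, stain images (`p63`,
#'   `four_channel`, `optical_elevation`, `optical_azimuth`) and `report`.
#' @export
run_pipeline <- function(input, reference = NULL, rois = NULL,
                         intervals = NULL, basis = NULL,
                         params = morphology_params(),
                         max_spectra = 2e5, seed = 1L,
                         register = TRUE, output_dir = NULL) {
  if (is.null(rois) && is.null(intervals))
    stopf(paste("no calibration source: supply labeled 'rois' or a",
                "precomputed 'intervals' object"))
  cube <- if (inherits(input, "TileGrid")) stitch_tiles(input) else input
  stopifnot(inherits(cube, "SpectralCube"))
  if (cube$domain == "transmission")
    cube <- compute_absorbance(cube, reference)
  if (register) {
    cube <- register_channels(cube)
    cr <- attr(cube, "crop")
    if (!is.null(rois))
      rois <- lapply(rois, function(m) m[cr[1]:cr[2], cr[3]:cr[4], drop = FALSE])
  }
  if (is.null(basis)) {
    spectra <- sample_spectra(cube, max_count = max_spectra, seed = seed)
    basis <- fit_basis(spectra)
  }
  sph123 <- to_spherical(project_cube(cube, basis, c(1, 2, 3)))
  sph234 <- to_spherical(project_cube(cube, basis, c(2, 3, 4)))
  if (is.null(intervals))
    intervals <- calibrate_intervals(sph123, sph234, rois)
  nuclei <- segment_nuclei(sph123, intervals)
  lm <- classify_nuclei(sph234, nuclei, intervals, cube$pixel_size_nm)
  lm <- despeckle(lm, params)
  lm <- basal_morphology_filter(lm, params = params)
  out <- list(labels = lm,
              nuclei_mask = nuclei,
              basis = basis,
              intervals = intervals,
              sph123 = sph123,
              sph234 = sph234,
              p63 = render_p63(lm),
              four_channel = render_4channel(lm),
              optical_elevation = render_optical_stain(sph123, "elevation"),
              optical_azimuth = render_optical_stain(sph234, "azimuth"))
  counts <- tabulate(lm$labels + 1L, 5L)
  names(counts) <- uv_classes
  out$report <- list(
    package_version = as.character(utils::packageVersion("uvstain")),
    seed = seed,
    max_spectra = max_spectra,
    explained_variance_fraction = as.numeric(basis$explained_variance_fraction),
    morphology = unclass(params),
    class_pixel_counts = as.list(counts),
    total_pixels = sum(counts))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_label_map(lm, file.path(output_dir, "labels.tiff"))
    write_stain_image(out$p63, file.path(output_dir, "p63.png"))
    write_stain_image(out$four_channel, file.path(output_dir, "four_channel.png"))
    write_stain_image(out$optical_elevation,
                      file.path(output_dir, "optical_elevation.png"))
    write_stain_image(out$optical_azimuth,
                      file.path(output_dir, "optical_azimuth.png"))
    write_basis(basis, file.path(output_dir, "basis.yaml"))
    write_intervals(intervals, file.path(output_dir, "intervals.yaml"))
    jsonlite::write_json(out$report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Pixelwise agreement between two label maps
#'
#' Convenience scorer used to validate the pipeline against phantom ground
#' truth: overall pixel accuracy plus per-class precision, recall and F1.
#'
#' @param predicted,truth [label_map()]s of identical size.
#' @return List with `accuracy` and a per-class data frame `by_class`.
#' @export
score_labels <- function(predicted, truth) {
  stopifnot(inherits(predicted, "LabelMap"), inherits(truth, "LabelMap"))
  p <- predicted$labels; t <- truth$labels
  if (!identical(dim(p), dim(t))) stopf("label map shape mismatch")
  by_class <- do.call(rbind, lapply(0:4, function(code) {
    tp <- sum(p == code & t == code)
    fp <- sum(p == code & t != code)
    fn <- sum(p != code & t == code)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    data.frame(class = uv_classes[code + 1L], precision = prec,
               recall = rec, f1 = f1, support = tp + fn)
  }))
  list(accuracy = mean(p == t), by_class = by_class)
}
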