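#' Tissue class labels
#'
#' Integer label codes used throughout the package: `0 = background`,
#' `1 = stroma_cytoplasm`, `2 = luminal_fibroblast`, `3 = inflammation`,
#' `4 = basal`.  `uv_classes` maps code + 1 to class name; the three
#' nuclear classes are `luminal_fibroblast`, `inflammation` and `basal`.
#'
#' @format Character vector of length 5.
#' @export
uv_classes <- c("background", "stroma_cytoplasm", "luminal_fibroblast",
                "inflammation", "basal")

NUCLEI_CLASSES <- c("luminal_fibroblast", "inflammation", "basal")
AZIMUTH_CLASSES <- c("stroma_cytoplasm", "luminal_fibroblast",
                     "inflammation", "basal")

class_code <- function(name) match(name, uv_classes) - 1L

#' Construct a per-pixel tissue label map
#'
#' @param labels integer matrix with values in `0:4` (see [uv_classes]).
#' @param pixel_size_nm physical pixel pitch in nm.
#' @return An object of class `"LabelMap"`.
#' @export
label_map <- function(labels, pixel_size_nm = 250) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 4L))
    stopf("labels must be integer codes 0..4")
  structure(list(labels = labels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap: %d x %d px (%.0f nm/px)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_nm))
  counts <- tabulate(x$labels + 1L, 5L)
  for (i in 1:5) cat(sprintf("  %-18s %d\n", uv_classes[i], counts[i]))
  invisible(x)
}

#' Morphological post-processing parameters
#'
#' Defaults follow physical scales at the instrument's sampling: the
#' despeckle area threshold is the pixel area of a 2 micron diameter disk
#' (about 50 px at 250 nm/px -- smaller clusters cannot represent a cell
#' nucleus), the basal-filter Gaussian sigma is 2 px and the dilation
#' radius 8 px (about 2 microns).
#'
#' @param min_component_area_px connected components below this area are
#'   despeckled; `NULL` derives it from the label map's pixel size at use.
#' @param gradient_threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param gradient_threshold_value threshold when mode is `"fixed"`.
#' @param gaussian_sigma_px Gaussian smoothing sigma in the basal filter.
#' @param dilation_radius_px disc radius of the basal support dilation.
#' @param connectivity pixel connectivity for components: 4 or 8.
#' @return An object of class `"MorphologyParams"`.
#' @export
morphology_params <- function(min_component_area_px = NULL,
                              gradient_threshold_mode = c("otsu", "fixed"),
                              gradient_threshold_value = NULL,
                              gaussian_sigma_px = 2,
                              dilation_radius_px = 8L,
                              connectivity = 8L) {
  gradient_threshold_mode <- match.arg(gradient_threshold_mode)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  if (!is.null(min_component_area_px) && min_component_area_px <= 0)
    stopf("min_component_area_px must be positive")
  if (gaussian_sigma_px <= 0 || dilation_radius_px <= 0)
    stopf("morphology scales must be positive")
  if (gradient_threshold_mode == "fixed" &&
      (is.null(gradient_threshold_value) || gradient_threshold_value <= 0))
    stopf("fixed gradient threshold requires a positive value")
  structure(list(min_component_area_px = min_component_area_px,
                 gradient_threshold_mode = gradient_threshold_mode,
                 gradient_threshold_value = gradient_threshold_value,
                 gaussian_sigma_px = gaussian_sigma_px,
                 dilation_radius_px = as.integer(dilation_radius_px),
                 connectivity = as.integer(connectivity)),
            class = "MorphologyParams")
}

default_min_area <- function(pixel_size_nm) {
  max(1L, as.integer(round(pi * (1000 / pixel_size_nm)^2)))
}

#' Calibrate class decision intervals from labeled regions
#'
#' For each tissue class the circular mean azimuth in the PC(2,3,4)
#' spherical domain is computed over its labeled region; decision
#' boundaries are then placed at the circular midpoints between angularly
#' adjacent class means, so the four azimuth intervals are disjoint and
#' cover the circle.  The nuclei elevation gate in the PC(1,2,3) domain is
#' the `[min, max]` elevation over all nuclear-class regions, expanded by
#' `elevation_margin` of its width on each side to avoid knife-edge
#' exclusion of in-class pixels.  Zero-radius pixels are excluded.
#'
#' @param sph123 [to_spherical()] map of the PC(1,2,3) projection.
#' @param sph234 [to_spherical()] map of the PC(2,3,4) projection.
#' @param labeled_rois named list of logical masks, one per class in
#'   [uv_classes] (background excluded): `stroma_cytoplasm`,
#'   `luminal_fibroblast`, `inflammation`, `basal`.
#' @param elevation_margin fractional expansion of the elevation gate.
#' @return An object of class `"ClassIntervals"`: `class_mean_azimuth`
#'   (named, radians), `azimuth_intervals` (named list of `c(lower, upper)`
#'   half-open circular intervals) and `nuclei_elevation_interval`.
#' @export
calibrate_intervals <- function(sph123, sph234, labeled_rois,
                                elevation_margin = 0.05) {
  stopifnot(inherits(sph123, "SphericalMap"), inherits(sph234, "SphericalMap"))
  if (!identical(sph123$triplet, c(1L, 2L, 3L)))
    stopf("sph123 must come from triplet (1,2,3)")
  if (!identical(sph234$triplet, c(2L, 3L, 4L)))
    stopf("sph234 must come from triplet (2,3,4)")
  missing_cls <- setdiff(AZIMUTH_CLASSES, names(labeled_rois))
  if (length(missing_cls))
    stopf("labeled_rois lacks classes: %s", paste(missing_cls, collapse = ", "))
  mean_az <- vapply(AZIMUTH_CLASSES, function(cl) {
    sel <- labeled_rois[[cl]] & sph234$radius > 0
    if (!any(sel)) stopf("class '%s' has no nonzero-radius labeled pixels", cl)
    circular_mean(sph234$azimuth[sel])
  }, numeric(1))
  if (anyNA(mean_az)) stopf("degenerate circular mean in calibration")
  if (min(abs(wrap_angle(outer(mean_az, mean_az, "-")))[
        upper.tri(matrix(0, 4, 4))]) < 1e-9)
    stopf("two classes have identical mean azimuth; calibration is degenerate")
  ord <- order(mean_az)
  # boundary i sits at the circular midpoint between adjacent means i, i+1
  bounds <- vapply(seq_len(4), function(i) {
    a <- mean_az[ord[i]]; b <- mean_az[ord[(i %% 4) + 1]]
    wrap_angle(a + ((b - a) %% (2 * pi)) / 2)
  }, numeric(1))
  intervals <- vector("list", 4)
  names(intervals) <- AZIMUTH_CLASSES[ord]
  for (i in seq_len(4)) {
    lower <- bounds[((i - 2) %% 4) + 1]  # boundary preceding class ord[i]
    upper <- bounds[i]
    intervals[[AZIMUTH_CLASSES[ord[i]]]] <- c(lower = lower, upper = upper)
  }
  intervals <- intervals[AZIMUTH_CLASSES]
  nuc_sel <- Reduce(`|`, labeled_rois[NUCLEI_CLASSES]) & sph123$radius > 0
  if (!any(nuc_sel)) stopf("no nonzero-radius nuclei pixels in the ROIs")
  el <- range(sph123$elevation[nuc_sel])
  el <- el + c(-1, 1) * elevation_margin * diff(el)
  structure(list(class_mean_azimuth = mean_az,
                 azimuth_intervals = intervals,
                 nuclei_elevation_interval = el),
            class = "ClassIntervals")
}

#' @export
print.ClassIntervals <- function(x, ...) {
  cat("ClassIntervals\n")
  cat(sprintf("  nuclei elevation gate: [%.2f, %.2f] deg\n",
              180 / pi * x$nuclei_elevation_interval[1],
              180 / pi * x$nuclei_elevation_interval[2]))
  for (cl in names(x$azimuth_intervals)) {
    iv <- x$azimuth_intervals[[cl]]
    cat(sprintf("  %-20s mean %7.1f deg, interval [%7.1f, %7.1f) deg\n", cl,
                180 / pi * x$class_mean_azimuth[[cl]],
                180 / pi * iv[1], 180 / pi * iv[2]))
  }
  invisible(x)
}

#' Write / read calibrated class intervals as YAML
#' @param intervals a [calibrate_intervals()] result.
#' @param path YAML file path.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(inherits(intervals, "ClassIntervals"))
  yaml::write_yaml(list(
    class_mean_azimuth = as.list(intervals$class_mean_azimuth),
    azimuth_intervals = lapply(intervals$azimuth_intervals, as.numeric),
    nuclei_elevation_interval = as.numeric(intervals$nuclei_elevation_interval)),
    path)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  y <- yaml::read_yaml(path)
  iv <- lapply(y$azimuth_intervals, function(v) {
    v <- as.numeric(v); names(v) <- c("lower", "upper"); v
  })
  structure(list(class_mean_azimuth = unlist(y$class_mean_azimuth),
                 azimuth_intervals = iv,
                 nuclei_elevation_interval = as.numeric(y$nuclei_elevation_interval)),
            class = "ClassIntervals")
}

#' Step 1: separate nuclei from stroma/cytoplasm by elevation
#'
#' A pixel is a nucleus candidate when its PC(1,2,3) elevation falls inside
#' the calibrated nuclei gate and its radius is positive.
#'
#' @param sph123 [to_spherical()] map of the PC(1,2,3) projection.
#' @param intervals a [calibrate_intervals()] result.
#' @return Logical matrix mask.
#' @export
segment_nuclei <- function(sph123, intervals) {
  stopifnot(inherits(sph123, "SphericalMap"), inherits(intervals, "ClassIntervals"))
  if (!identical(sph123$triplet, c(1L, 2L, 3L)))
    stopf("segment_nuclei needs the PC(1,2,3) spherical map")
  el <- intervals$nuclei_elevation_interval
  sph123$elevation >= el[1] & sph123$elevation <= el[2] & sph123$radius > 0
}

#' Step 2: classify nuclei subtypes by PC(2,3,4) azimuth
#'
#' Pixels outside the nuclei mask are `stroma_cytoplasm` where the radius is
#' positive and `background` otherwise.  Pixels inside the mask take the
#' nuclear class whose circular azimuth interval contains their azimuth;
#' nuclei-mask pixels whose azimuth falls in the stroma interval are
#' labeled `luminal_fibroblast` (the step-1 nuclei decision wins -- the
#' two-step order exists precisely because the azimuth domain has some
#' stroma/nuclei overlap).
#'
#' @param sph234 [to_spherical()] map of the PC(2,3,4) projection.
#' @param nuclei_mask logical matrix from [segment_nuclei()].
#' @param intervals a [calibrate_intervals()] result.
#' @param pixel_size_nm pixel pitch recorded in the output map.
#' @return A [label_map()].
#' @export
classify_nuclei <- function(sph234, nuclei_mask, intervals, pixel_size_nm = 250) {
  stopifnot(inherits(sph234, "SphericalMap"), inherits(intervals, "ClassIntervals"))
  if (!identical(sph234$triplet, c(2L, 3L, 4L)))
    stopf("classify_nuclei needs the PC(2,3,4) spherical map")
  if (!identical(dim(nuclei_mask), dim(sph234$azimuth)))
    stopf("nuclei_mask shape mismatch")
  labels <- matrix(0L, nrow(nuclei_mask), ncol(nuclei_mask))
  labels[sph234$radius > 0] <- class_code("stroma_cytoplasm")
  th <- sph234$azimuth[nuclei_mask]
  sub <- rep(class_code("luminal_fibroblast"), length(th))
  for (cl in c("luminal_fibroblast", "inflammation", "basal")) {
    iv <- intervals$azimuth_intervals[[cl]]
    sub[in_circular_interval(th, iv[1], iv[2])] <- class_code(cl)
  }
  labels[nuclei_mask] <- sub
  label_map(labels, pixel_size_nm)
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connectivity component labeling.  The 4-connected pass is
#' delegated to `EBImage::bwlabel`; 8-connectivity is obtained by merging
#' 4-components that touch diagonally (union-find over component ids).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  l4 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(l4) <- "integer"
  if (connectivity == 4L) return(relabel_sequential(l4))
  nl <- max(l4)
  parent <- seq_len(nl)
  find_root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  n1 <- nrow(mask); n2 <- ncol(mask)
  for (dc in c(1L, -1L)) {
    a <- l4[1:(n1 - 1), if (dc == 1L) 1:(n2 - 1) else 2:n2]
    b <- l4[2:n1, if (dc == 1L) 2:n2 else 1:(n2 - 1)]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[i, 1]); rb <- find_root(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nl), find_root, integer(1))
  out <- matrix(0L, n1, n2)
  nz <- l4 > 0L
  out[nz] <- roots[l4[nz]]
  relabel_sequential(out)
}

relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
  nz <- lab > 0L
  lab[nz] <- lut[lab[nz]]
  lab
}

#' Remove small nuclear clusters ("salt and pepper" despeckling)
#'
#' Slight spectral overlap between stroma, cytoplasm and nuclei produces
#' scattered single-pixel nuclear labels that cannot physically represent
#' cell nuclei.  For each nuclear class independently, connected components
#' smaller than `min_component_area_px` are relabeled to
#' `stroma_cytoplasm`; components at or above the threshold are kept
#' unchanged, and no pixel is ever *added* to a nuclear class.  The
#' operation is idempotent.
#'
#' @param lm a [label_map()].
#' @param params a [morphology_params()]; a `NULL` area threshold is derived
#'   from the map's pixel size (2 micron diameter disk).
#' @return The despeckled [label_map()].
#' @export
despeckle <- function(lm, params = morphology_params()) {
  stopifnot(inherits(lm, "LabelMap"), inherits(params, "MorphologyParams"))
  min_area <- params$min_component_area_px %||% default_min_area(lm$pixel_size_nm)
  labels <- lm$labels
  for (cl in NUCLEI_CLASSES) {
    code <- class_code(cl)
    cc <- label_components(labels == code, params$connectivity)
    if (max(cc) == 0L) next
    sizes <- tabulate(cc[cc > 0L])
    drop_ids <- which(sizes < min_area)
    if (length(drop_ids))
      labels[matrix(cc %in% drop_ids, nrow(cc), ncol(cc))] <-
        class_code("stroma_cytoplasm")
  }
  label_map(labels, lm$pixel_size_nm)
}

#' Prewitt gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` with the standard 3x3 Prewitt kernels; the border is
#' handled by edge replication.
#'
#' @param image numeric matrix, at least 3x3.
#' @return Matrix of gradient magnitudes, same size as `image`.
#' @export
prewitt_gradient <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stopf("image must be a matrix of at least 3x3")
  p <- rbind(image[1, ], image, image[nrow(image), ])
  p <- cbind(p[, 1], p, p[, ncol(p)])
  ir <- 2:(nrow(p) - 1); ic <- 2:(ncol(p) - 1)
  gx <- (p[ir - 1, ic + 1] + p[ir, ic + 1] + p[ir + 1, ic + 1]) -
        (p[ir - 1, ic - 1] + p[ir, ic - 1] + p[ir + 1, ic - 1])
  gy <- (p[ir + 1, ic - 1] + p[ir + 1, ic] + p[ir + 1, ic + 1]) -
        (p[ir - 1, ic - 1] + p[ir - 1, ic] + p[ir - 1, ic + 1])
  sqrt(gx^2 + gy^2)
}

#' Morphological separation of basal cells from inflammation
#'
#' Basal and inflammatory cells overlap spectrally, but their shapes
#' differ: basal cells form thin elongated structures at the gland
#' periphery while inflammatory cells cluster in compact blobs.  The filter
#' builds a basal support mask from the nuclei map geometry:
#' (1) Prewitt gradient magnitude of the binary nuclei map;
#' (2) intensity threshold (Otsu by default) giving the high-gradient mask;
#' (3) Gaussian smoothing (`gaussian_sigma_px`) re-binarized at 0.5 -- for a
#' thin structure the gradient bands of its two sides merge and survive,
#' while the single band of an isolated blob edge is diluted below 0.5;
#' (4) dilation by a disc of `dilation_radius_px`.
#' Basal-labeled pixels outside the support are relabeled `inflammation`;
#' the output basal set is always a subset of the input basal set and all
#' other labels are unchanged.
#'
#' @param lm a [label_map()] containing basal candidates.
#' @param nuclei_mask logical matrix; defaults to the union of the map's
#'   nuclear classes.
#' @param params a [morphology_params()].
#' @return The filtered [label_map()].
#' @export
basal_morphology_filter <- function(lm, nuclei_mask = NULL,
                                    params = morphology_params()) {
  stopifnot(inherits(lm, "LabelMap"), inherits(params, "MorphologyParams"))
  basal <- lm$labels == class_code("basal")
  if (!any(basal)) return(lm)
  if (is.null(nuclei_mask))
    nuclei_mask <- matrix(lm$labels %in% class_code(NUCLEI_CLASSES),
                          nrow(lm$labels), ncol(lm$labels))
  g <- prewitt_gradient(nuclei_mask * 1)
  gmax <- max(g)
  if (gmax == 0) {
    support <- matrix(FALSE, nrow(g), ncol(g))
  } else {
    thr <- if (params$gradient_threshold_mode == "otsu")
      EBImage::otsu(EBImage::Image(g / gmax), range = c(0, 1)) * gmax
    else params$gradient_threshold_value
    hi <- g > thr
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(hi * 1),
                                            sigma = params$gaussian_sigma_px))
    core <- sm >= 0.5
    support <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(core * 1),
      EBImage::makeBrush(2L * params$dilation_radius_px + 1L, "disc"))) > 0.5
  }
  labels <- lm$labels
  labels[basal & !support] <- class_code("inflammation")
  label_map(labels, lm$pixel_size_nm)
}

#' Write / read a label map as an 8-bit TIFF with a JSON class sidecar
#'
#' Codes are stored as `code/255` in an 8-bit grayscale TIFF (lossless for
#' codes 0..4) with a `<name>.classes.json` sidecar listing the class names
#' and pixel size.
#'
#' @param lm a [label_map()].
#' @param path TIFF path.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "LabelMap"))
  tiff::writeTIFF(lm$labels / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  jsonlite::write_json(list(classes = uv_classes,
                            pixel_size_nm = lm$pixel_size_nm),
                       paste0(tools::file_path_sans_ext(path), ".classes.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(
    paste0(tools::file_path_sans_ext(path), ".classes.json"))
  label_map(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
            meta$pixel_size_nm)
}
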