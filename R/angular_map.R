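#' Convert a projection field to spherical coordinates
#'
#' For projection coordinates `(x, y, z)` of each pixel:
#' radius `I = sqrt(x^2 + y^2 + z^2)`, azimuth `theta = atan2(y, x)` and
#' elevation `phi = atan2(z, sqrt(x^2 + y^2))` (elevation measured from the
#' xy-plane).  The two angles encode the *shape* of the pixel spectrum
#' (composition) while the radius scales with overall optical density and
#' so acts as a relative concentration measure.  Pixels with zero radius
#' have both angles set to 0 by convention; they are treated as background
#' downstream and excluded from histograms and calibration.
#'
#' @param field a [project_cube()] result with finite coordinates.
#' @return An object of class `"SphericalMap"`: list with matrices
#'   `azimuth` (in `(-pi, pi]`), `elevation` (in `[-pi/2, pi/2]`),
#'   `radius` (`>= 0`) and the `triplet` of origin.
#' @export
to_spherical <- function(field) {
  stopifnot(inherits(field, "ProjectionField"))
  d <- dim(field$coords)
  x <- matrix(field$coords[, , 1], d[1], d[2])
  y <- matrix(field$coords[, , 2], d[1], d[2])
  z <- matrix(field$coords[, , 3], d[1], d[2])
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stopf("projection field contains non-finite values")
  rxy <- sqrt(x^2 + y^2)
  radius <- sqrt(rxy^2 + z^2)
  azimuth <- atan2(y, x)
  elevation <- atan2(z, rxy)
  zero <- radius == 0
  azimuth[zero] <- 0
  elevation[zero] <- 0
  structure(list(azimuth = azimuth, elevation = elevation, radius = radius,
                 triplet = field$triplet),
            class = "SphericalMap")
}

#' @export
print.SphericalMap <- function(x, ...) {
  cat(sprintf("SphericalMap over PC(%s): %d x %d px, %.1f%% nonzero radius\n",
              paste(x$triplet, collapse = ","), nrow(x$radius), ncol(x$radius),
              100 * mean(x$radius > 0)))
  invisible(x)
}

#' Render an HSV "optical stain" image from a spherical map
#'
#' Hue is an affine map of the chosen angular coordinate from `hue_range`
#' onto `[0, 1)` (clipped), saturation is 1, and value is the radius
#' normalized by its `value_norm`-th percentile (clipped to `[0, 1]`), so
#' color encodes composition and brightness encodes concentration.
#'
#' @param sph a [to_spherical()] result.
#' @param hue_source `"elevation"` or `"azimuth"`.
#' @param hue_range length-2 increasing angle interval (radians) mapped onto
#'   the hue circle; defaults to the full valid range of the chosen angle.
#' @param value_norm percentile (0-100] of the radius used as the brightness
#'   ceiling; 99 by default to resist outliers.
#' @return An object of class `"StainImage"`: list with `rgb`
#'   (rows x cols x 3 in `[0, 1]`) and a `legend` describing the encoding.
#' @export
render_optical_stain <- function(sph, hue_source = c("elevation", "azimuth"),
                                 hue_range = NULL, value_norm = 99) {
  stopifnot(inherits(sph, "SphericalMap"))
  hue_source <- match.arg(hue_source)
  ang <- if (hue_source == "elevation") sph$elevation else sph$azimuth
  if (is.null(hue_range))
    hue_range <- if (hue_source == "elevation") c(-pi / 2, pi / 2) else c(-pi, pi)
  if (length(hue_range) != 2 || !(hue_range[1] < hue_range[2]))
    stopf("hue_range must be a nonempty increasing interval")
  if (value_norm <= 0 || value_norm > 100)
    stopf("value_norm must be a percentile in (0, 100]")
  h <- (ang - hue_range[1]) / (hue_range[2] - hue_range[1])
  h <- pmin(pmax(h, 0), 1 - 1e-9)
  rmax <- if (any(sph$radius > 0))
    quantile(sph$radius[sph$radius > 0], value_norm / 100, names = FALSE) else 0
  v <- if (rmax > 0) pmin(sph$radius / rmax, 1) else sph$radius * 0
  cols <- col2rgb(hsv(as.vector(h), 1, as.vector(v))) / 255
  rgb <- array(0, c(nrow(ang), ncol(ang), 3))
  for (k in 1:3) rgb[, , k] <- matrix(cols[k, ], nrow(ang), ncol(ang))
  out <- structure(list(rgb = rgb,
                 legend = list(hue_source = hue_source, hue_range = hue_range,
                               value = sprintf("radius / %gth percentile", value_norm),
                               triplet = sph$triplet)),
            class = "StainImage")
  attr(out, "hue") <- h
  attr(out, "value") <- v
  out
}

#' @export
print.StainImage <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("StainImage: %d x %d px RGB\n", d[1], d[2]))
  invisible(x)
}

#' Two-dimensional angular histogram of a spherical map
#'
#' Counts nonzero-radius pixels over an (azimuth, elevation) grid, together
#' with the elevation-integrated azimuth histogram used to read off class
#' modes.  Counts are raw (no density normalization) and invariant to any
#' positive rescaling of the radius.
#'
#' @param sph a [to_spherical()] result.
#' @param bins length-2 integer vector: bins along azimuth and elevation.
#' @return List with `counts` (azimuth bins x elevation bins),
#'   `azimuth_breaks`, `elevation_breaks`, `azimuth_counts`
#'   (elevation integral) and `n` (total counted pixels).
#' @export
angular_histogram <- function(sph, bins = c(72, 36)) {
  stopifnot(inherits(sph, "SphericalMap"))
  bins <- as.integer(bins)
  if (length(bins) == 1) bins <- c(bins, bins)
  if (any(bins < 1)) stopf("bins must be >= 1 per axis")
  keep <- sph$radius > 0
  th <- sph$azimuth[keep]; ph <- sph$elevation[keep]
  az_br <- seq(-pi, pi, length.out = bins[1] + 1)
  el_br <- seq(-pi / 2, pi / 2, length.out = bins[2] + 1)
  ia <- findInterval(th, az_br, rightmost.closed = TRUE, all.inside = TRUE)
  ie <- findInterval(ph, el_br, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  tab <- table(factor(ia, levels = seq_len(bins[1])),
               factor(ie, levels = seq_len(bins[2])))
  counts[] <- as.integer(tab)
  list(counts = counts, azimuth_breaks = az_br, elevation_breaks = el_br,
       azimuth_counts = rowSums(counts), n = sum(keep))
}
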