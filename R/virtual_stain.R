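#' Stain color palettes
#'
#' Two colorization schemes for label maps.  `"p63"` mimics a p63
#' immunohistochemistry stain: basal cells dark brown, all other nuclei
#' dark blue, stroma/cytoplasm light gray, background white.
#' `"four_channel"` is the detailed molecular map: basal red, inflammation
#' yellow, luminal/fibroblast green, stroma/cytoplasm blue, background
#' black.  Exact RGB values are package defaults and can be overridden by
#' passing a modified palette to the renderers.
#'
#' @param scheme `"p63"` or `"four_channel"`.
#' @return Named list of RGB triples in `[0, 1]^3`, class `"StainPalette"`,
#'   with the scheme recorded as an attribute.
#' @export
stain_palette <- function(scheme = c("p63", "four_channel")) {
  scheme <- match.arg(scheme)
  pal <- switch(scheme,
    p63 = list(basal        = c(0.42, 0.26, 0.14),
               other_nuclei = c(0.16, 0.18, 0.45),
               stroma       = c(0.88, 0.88, 0.88),
               background   = c(1, 1, 1)),
    four_channel = list(basal              = c(1, 0, 0),
                        inflammation       = c(1, 1, 0),
                        luminal_fibroblast = c(0, 1, 0),
                        stroma_cytoplasm   = c(0, 0, 1),
                        background         = c(0, 0, 0)))
  structure(pal, class = "StainPalette", scheme = scheme)
}

render_lookup <- function(labels, colors) {
  rgb <- array(0, c(nrow(labels), ncol(labels), 3))
  for (code in sort(unique(as.vector(labels)))) {
    sel <- labels == code
    col <- colors[[code + 1L]]
    for (k in 1:3) {
      pl <- rgb[, , k]; pl[sel] <- col[k]; rgb[, , k] <- pl
    }
  }
  rgb
}

#' Render a virtual p63 immunohistochemistry image
#'
#' Pure per-pixel color lookup: basal pixels take the brown `basal` color,
#' inflammation and luminal/fibroblast pixels the dark blue
#' `other_nuclei` color, stroma/cytoplasm the light gray and background
#' white.  No smoothing is applied; the slightly "fuzzy" appearance
#' relative to a chemical stain is deliberate, since only pixels whose
#' spectra match the basal signature are colorized.
#'
#' @param lm a [label_map()].
#' @param palette a `"p63"` [stain_palette()].
#' @return A `"StainImage"` (list with `rgb` array and `legend`).
#' @export
render_p63 <- function(lm, palette = stain_palette("p63")) {
  stopifnot(inherits(lm, "LabelMap"), inherits(palette, "StainPalette"))
  need <- c("basal", "other_nuclei", "stroma", "background")
  if (!all(need %in% names(palette)))
    stopf("p63 palette must define: %s", paste(need, collapse = ", "))
  colors <- list(palette$background,     # 0 background
                 palette$stroma,         # 1 stroma_cytoplasm
                 palette$other_nuclei,   # 2 luminal_fibroblast
                 palette$other_nuclei,   # 3 inflammation
                 palette$basal)          # 4 basal
  structure(list(rgb = render_lookup(lm$labels, colors),
                 legend = list(scheme = "p63",
                               colors = colors, classes = uv_classes)),
            class = "StainImage")
}

#' Render the four-channel molecular map
#'
#' Per-pixel lookup of the four tissue classes into red (basal), yellow
#' (inflammation), green (luminal epithelial / fibroblast nuclei) and blue
#' (stroma and cytoplasm), black background.
#'
#' @param lm a [label_map()].
#' @param palette a `"four_channel"` [stain_palette()].
#' @return A `"StainImage"`.
#' @export
render_4channel <- function(lm, palette = stain_palette("four_channel")) {
  stopifnot(inherits(lm, "LabelMap"), inherits(palette, "StainPalette"))
  need <- c("basal", "inflammation", "luminal_fibroblast",
            "stroma_cytoplasm", "background")
  if (!all(need %in% names(palette)))
    stopf("four_channel palette must define: %s", paste(need, collapse = ", "))
  colors <- list(palette$background,
                 palette$stroma_cytoplasm,
                 palette$luminal_fibroblast,
                 palette$inflammation,
                 palette$basal)
  structure(list(rgb = render_lookup(lm$labels, colors),
                 legend = list(scheme = "four_channel",
                               colors = colors, classes = uv_classes)),
            class = "StainImage")
}

#' Invert a rendered stain image back to labels
#'
#' Exact inverse lookup for palettes with distinct colors (such as the
#' four-channel defaults); errors if a pixel color is not in the legend.
#'
#' @param img a `"StainImage"` produced by [render_4channel()] (or
#'   [render_p63()] -- note p63 merges the two non-basal nuclear classes,
#'   so inversion returns `luminal_fibroblast` for both).
#' @param pixel_size_nm pixel pitch for the output map.
#' @return A [label_map()].
#' @export
stain_to_labels <- function(img, pixel_size_nm = 250) {
  stopifnot(inherits(img, "StainImage"))
  colors <- img$legend$colors
  key <- vapply(colors, paste, character(1), collapse = "/")
  d <- dim(img$rgb)
  px <- paste(img$rgb[, , 1], img$rgb[, , 2], img$rgb[, , 3], sep = "/")
  code <- match(px, key) - 1L
  if (anyNA(code)) stopf("image contains colors not present in the legend")
  label_map(matrix(code, d[1], d[2]), pixel_size_nm)
}

#' Write a stain image as PNG (with a JSON legend sidecar)
#'
#' @param img a `"StainImage"`.
#' @param path PNG path.
#' @export
write_stain_image <- function(img, path) {
  stopifnot(inherits(img, "StainImage"))
  png::writePNG(img$rgb, path)
  jsonlite::write_json(img$legend,
                       paste0(tools::file_path_sans_ext(path), ".legend.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
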