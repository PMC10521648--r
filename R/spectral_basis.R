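#' Sample pixel spectra from absorbance cubes
#'
#' Pools pixel spectra from one or more absorbance cubes (optionally
#' restricted to masks) and draws up to `max_count` of them uniformly at
#' random without replacement.  When the pool is no larger than `max_count`
#' every spectrum is returned exactly once.  Sampling is performed in a
#' private RNG stream, so results are reproducible for a fixed `seed` and
#' the caller's RNG state is untouched.
#'
#' @param cubes a [spectral_cube()] or list of them, absorbance domain.
#' @param masks optional logical matrix or list of matrices (one per cube)
#'   selecting the pixels to pool; `NULL` pools every pixel.
#' @param max_count maximum number of spectra returned.  The default desk
#'   scale cap is 2e6: the basis stabilizes far below the hundreds of
#'   millions of spectra a whole study pools.
#' @param seed integer seed for the subsample draw.
#' @return Numeric matrix (spectra x channels) with attribute
#'   `"wavelengths_nm"`.
#' @export
sample_spectra <- function(cubes, masks = NULL, max_count = 2e6, seed = 1) {
  if (inherits(cubes, "SpectralCube")) cubes <- list(cubes)
  if (!is.null(masks) && is.matrix(masks)) masks <- list(masks)
  pool <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    cb <- cubes[[i]]
    stopifnot(inherits(cb, "SpectralCube"))
    if (cb$domain != "absorbance")
      stopf("sample_spectra expects absorbance-domain cubes")
    d <- dim(cb$values)
    m <- matrix(cb$values, nrow = d[1] * d[2], ncol = d[3])
    if (!is.null(masks)) {
      msk <- masks[[i]]
      if (!any(msk)) stopf("empty mask for cube %d", i)
      m <- m[as.vector(msk), , drop = FALSE]
    }
    pool[[i]] <- m
  }
  x <- do.call(rbind, pool)
  if (nrow(x) > max_count) {
    keep <- with_seed(seed, sample.int(nrow(x), max_count))
    x <- x[keep, , drop = FALSE]
  }
  attr(x, "wavelengths_nm") <- cubes[[1]]$wavelengths_nm
  x
}

#' Fit the uncentered principal-component spectral basis
#'
#' Computes the leading right singular directions of the (uncentered) pooled
#' spectrum matrix -- equivalently, the eigenvectors of the spectral
#' second-moment matrix.  The basis is deliberately *not* mean-centered:
#' the components then resemble physical absorption/scattering spectra and
#' the origin of the projection space corresponds to zero absorbance, which
#' is what lets the spherical radius act as a relative concentration measure
#' downstream.  The sign of each component is fixed by making its
#' largest-magnitude entry positive, removing the SVD sign ambiguity that
#' would otherwise flip azimuth/elevation between fits.
#'
#' Spectra containing non-finite values are dropped before fitting (the
#' count is recorded in the result).
#'
#' @param spectra numeric matrix (spectra x channels), e.g. from
#'   [sample_spectra()]; needs at least as many spectra as channels.
#' @return An object of class `"PCABasis"`: list with `components`
#'   (channels x n_components matrix, columns `PC1..`), ordered
#'   `explained_variance_fraction`, `sign_convention`, `n_spectra`,
#'   `n_dropped`, and `wavelengths_nm` (if known).
#' @export
fit_basis <- function(spectra) {
  if (!is.matrix(spectra)) spectra <- as.matrix(spectra)
  wl <- attr(spectra, "wavelengths_nm")
  finite <- rowSums(!is.finite(spectra)) == 0
  n_dropped <- sum(!finite)
  x <- spectra[finite, , drop = FALSE]
  nch <- ncol(x)
  if (nrow(x) < nch) stopf("need at least %d finite spectra", nch)
  if (all(x == 0)) stopf("degenerate input: all spectra are zero")
  sv <- svd(x, nu = 0)
  ncomp <- min(4L, nch)
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  for (k in seq_len(ncomp)) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  colnames(V) <- paste0("PC", seq_len(ncomp))
  evf <- sv$d^2 / sum(sv$d^2)
  structure(list(components = V,
                 explained_variance_fraction = evf[seq_len(ncomp)],
                 sign_convention = "largest-magnitude entry positive",
                 n_spectra = nrow(x),
                 n_dropped = n_dropped,
                 wavelengths_nm = wl),
            class = "PCABasis")
}

#' @export
print.PCABasis <- function(x, ...) {
  cat(sprintf("PCABasis: %d components over %d channels, fit on %d spectra\n",
              ncol(x$components), nrow(x$components), x$n_spectra))
  cat("explained variance fraction:",
      paste(sprintf("%.4f", x$explained_variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Project an absorbance cube onto a principal-component triplet
#'
#' `coords[r, c, k]` is the inner product of the pixel spectrum with
#' component `triplet[k]`.  The pipeline uses triplets `(1, 2, 3)` (the
#' scattering-dominated domain, whose elevation separates nuclei from
#' stroma/cytoplasm) and `(2, 3, 4)` (the absorption-contrast domain, whose
#' azimuth separates nuclei subtypes).
#'
#' @param cube absorbance-domain [spectral_cube()].
#' @param basis a [fit_basis()] result.
#' @param triplet three distinct component indices.
#' @return An object of class `"ProjectionField"`: list with `coords`
#'   (rows x cols x 3) and `triplet`.
#' @export
project_cube <- function(cube, basis, triplet = c(1, 2, 3)) {
  stopifnot(inherits(cube, "SpectralCube"), inherits(basis, "PCABasis"))
  if (cube$domain != "absorbance")
    stopf("project_cube expects an absorbance-domain cube")
  triplet <- as.integer(triplet)
  if (length(triplet) != 3 || anyDuplicated(triplet) ||
      any(triplet < 1 | triplet > ncol(basis$components)))
    stopf("triplet must be 3 distinct component indices")
  d <- dim(cube$values)
  if (d[3] != nrow(basis$components))
    stopf("cube channel count (%d) != basis spectral length (%d)",
          d[3], nrow(basis$components))
  m <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  p <- m %*% basis$components[, triplet, drop = FALSE]
  structure(list(coords = array(p, c(d[1], d[2], 3)), triplet = triplet),
            class = "ProjectionField")
}

#' Write / read a fitted basis as YAML
#'
#' @param basis a [fit_basis()] result.
#' @param path YAML file path.
#' @return `path` (write) or the `PCABasis` (read).
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "PCABasis"))
  yaml::write_yaml(precision = 15L, list(
    components = lapply(seq_len(ncol(basis$components)),
                        function(k) as.numeric(basis$components[, k])),
    explained_variance_fraction = as.numeric(basis$explained_variance_fraction),
    sign_convention = basis$sign_convention,
    n_spectra = basis$n_spectra,
    n_dropped = basis$n_dropped,
    wavelengths_nm = basis$wavelengths_nm), path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  y <- yaml::read_yaml(path)
  V <- do.call(cbind, lapply(y$components, as.numeric))
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(components = V,
                 explained_variance_fraction = as.numeric(y$explained_variance_fraction),
                 sign_convention = y$sign_convention,
                 n_spectra = y$n_spectra,
                 n_dropped = y$n_dropped %||% 0L,
                 wavelengths_nm = if (is.null(y$wavelengths_nm)) NULL
                                  else as.numeric(unlist(y$wavelengths_nm))),
            class = "PCABasis")
}
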