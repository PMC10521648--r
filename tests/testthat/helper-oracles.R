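# Independent oracles used to cross-check the implementation.

# Naive nested-loop Prewitt convolution with edge replication.
naive_prewitt <- function(img) {
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # columns -1, 0, +1
  ky <- t(kx)
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  at <- function(r, c) img[min(max(r, 1), n1), min(max(c, 1), n2)]
  for (r in seq_len(n1)) for (c in seq_len(n2)) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- at(r + dr, c + dc)
      gx <- gx + v * kx[dr + 2, dc + 2]
      gy <- gy + v * ky[dr + 2, dc + 2]
    }
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Breadth-first flood-fill component labeling (queue-based), independent of
# the union-find implementation in the package.
flood_fill_components <- function(mask, connectivity = 8L) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (r0 in seq_len(n1)) for (c0 in seq_len(n2)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= n1 && c >= 1 && c <= n2 &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# Inventory of components as a canonical multiset of sorted pixel-index sets;
# label numbering is irrelevant, membership is what matters.
component_inventory <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, function(s) s[1], numeric(1)))]
}

# Small phantom for fast unit tests: one gland, one inflammation cluster.
small_phantom <- function(seed = 1, snr = Inf, size = 192) {
  generate_phantom(phantom_spec(image_size_px = size, seed = seed, snr = snr))
}

# Build a SphericalMap directly from given angle/radius fields (tests of the
# calibration and classification geometry).
synthetic_sph <- function(azimuth, elevation, radius, triplet) {
  x <- radius * cos(elevation) * cos(azimuth)
  y <- radius * cos(elevation) * sin(azimuth)
  z <- radius * sin(elevation)
  coords <- array(c(x, y, z), c(nrow(azimuth), ncol(azimuth), 3))
  to_spherical(structure(list(coords = coords, triplet = as.integer(triplet)),
                         class = "ProjectionField"))
}
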