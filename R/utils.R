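# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Circular mean of angles in radians; NA when resultant length is ~0.
circular_mean <- function(theta) {
  s <- mean(sin(theta)); c <- mean(cos(theta))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  atan2(s, c)
}

# theta in half-open circular interval [lower, upper), walking counterclockwise.
in_circular_interval <- function(theta, lower, upper) {
  if (lower <= upper) theta >= lower & theta < upper
  else theta >= lower | theta < upper
}

# Integer translation of a matrix by (dy, dx); exposed pixels become NA.
translate_int <- function(m, dy, dx) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(NA_real_, n1, n2)
  sr <- max(1, 1 + dy):min(n1, n1 + dy)
  sc <- max(1, 1 + dx):min(n2, n2 + dx)
  if (length(sr) > 0 && length(sc) > 0) out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

# Circular cross-correlation peak between two equal-size matrices.
# Returns the displacement s = (dy, dx) maximizing sum(a * roll(b, s)),
# i.e. if b == roll(a, s0) the estimate is s == -s0 ... see register_channels.
cross_correlation_shift <- function(a, b, max_shift = NULL) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE))
  if (!is.null(max_shift)) {
    n1 <- nrow(cc); n2 <- ncol(cc)
    dr <- pmin(0:(n1 - 1), n1 - (0:(n1 - 1)))
    dc <- pmin(0:(n2 - 1), n2 - (0:(n2 - 1)))
    cc[dr > max_shift, ] <- -Inf
    cc[, dc > max_shift] <- -Inf
  }
  peak <- arrayInd(which.max(cc), dim(cc))
  n1 <- nrow(cc); n2 <- ncol(cc)
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > n1 / 2) dy <- dy - n1
  if (dx > n2 / 2) dx <- dx - n2
  c(dy, dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
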