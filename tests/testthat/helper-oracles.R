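# Independent oracles and fixture helpers shared across tests.

# Naive O(n^2) peak finder: every strict local maximum, with topographic
# prominence computed by direct scanning. Written independently of the
# package's peak detector so the two can be cross-checked.
brute_force_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    lmin <- x[i]
    prom_l <- -Inf
    for (j in (i - 1):1) {
      if (x[j] > x[i]) break
      lmin <- min(lmin, x[j])
      if (j == 1) break
    }
    prom_l <- x[i] - lmin
    rmin <- x[i]
    for (j in (i + 1):n) {
      if (x[j] > x[i]) break
      rmin <- min(rmin, x[j])
    }
    prom_r <- x[i] - rmin
    if (min(prom_l, prom_r) >= min_prominence) out <- c(out, i)
  }
  out
}

# Moving average mirroring the package's smoothing, for oracle parity.
oracle_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, numeric(1))
}

# Random rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid motion to the coordinate columns of a long marker table.
transform_markers <- function(markers, R, shift) {
  pts <- as.matrix(markers[, c("x", "y", "z")]) %*% t(R)
  markers$x <- pts[, 1] + shift[1]
  markers$y <- pts[, 2] + shift[2]
  markers$z <- pts[, 3] + shift[3]
  markers
}
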