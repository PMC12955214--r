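# Internal numeric and RNG helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) {
    stop("cannot normalize a (near) zero-length vector")
  }
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Angle between two vectors in degrees; dot product clamped to [-1, 1]
# for floating-point safety.
angle_between_deg <- function(a, b) {
  d <- sum(unitize(a) * unitize(b))
  rad2deg(acos(pmin(1, pmax(-1, d))))
}

# Rotation matrix mapping unit vector `a` onto unit vector `b`
# (Rodrigues construction; handles the antiparallel case).
rotation_between <- function(a, b) {
  a <- unitize(a)
  b <- unitize(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitize(axis - sum(axis * a) * a)
    return(rotation_about(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2],
                 -v[3], 0, v[1],
                 v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Rotation matrix about unit `axis` by `theta` radians.
rotation_about <- function(axis, theta) {
  axis <- unitize(axis)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
  matrix(c(ct + x^2 * vt,     x * y * vt + z * st, x * z * vt - y * st,
           x * y * vt - z * st, ct + y^2 * vt,     y * z * vt + x * st,
           x * z * vt + y * st, y * z * vt - x * st, ct + z^2 * vt),
         3, 3)
}

# Any unit vector orthogonal to v.
orthogonal_to <- function(v) {
  v <- unitize(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(ref - sum(ref * v) * v)
}

# Centered moving average with window given in samples (odd-sized kernel);
# edges use the partial window so the output has no NA.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of local maxima of x with topographic prominence >= min_prominence.
# Plateaus report their first sample. O(n * n_peaks); trajectories are short.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (min_prominence <= 0) return(cand)
  keep <- vapply(cand, function(p) {
    peak <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > peak)
    base_l <- min(x[(if (length(higher_l)) max(higher_l) else 1L):p])
    right <- x[(p + 1L):n]
    higher_r <- which(right > peak)
    hi_r <- if (length(higher_r)) p + min(higher_r) else n
    base_r <- min(x[p:hi_r])
    peak - max(base_l, base_r) >= min_prominence
  }, logical(1))
  cand[keep]
}

# Unwrap a phase series (radians) so successive differences lie in (-pi, pi].
unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1] + c(0, cumsum(d))
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
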