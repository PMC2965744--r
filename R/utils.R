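#' @importFrom rlang %||% abort
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rnorm runif rexp sd setNames optimize uniroot integrate
#' @importFrom utils head tail
NULL

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  sqrt(rowSums(m * m))
}

# Normalize rows to unit length; zero rows raise an error unless `allow_zero`.
unit_rows <- function(m, allow_zero = FALSE) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  n <- row_norms(m)
  if (!allow_zero && any(n < 1e-12)) {
    abort("cannot normalize a zero-length vector (undefined direction)")
  }
  m / pmax(n, 1e-300)
}

# Angle in degrees between paired rows of two n x 3 matrices, in [0, 180].
angle_deg <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  ca <- rowSums(a * b) / (row_norms(a) * row_norms(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# Rotation matrix taking the +z axis onto unit vector u (Rodrigues formula).
rotation_z_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  c_ <- u[3]
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Uniform random unit vectors (n x 3).
random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3L * n), ncol = 3L)
  unit_rows(m)
}

# Least-squares rigid superposition (Kabsch): rotation + translation mapping
# `x` onto `ref` (both n x 3). Returns the transformed x.
kabsch_fit <- function(x, ref) {
  cx <- colMeans(x)
  cr <- colMeans(ref)
  xc <- sweep(x, 2, cx)
  rc <- sweep(ref, 2, cr)
  s <- svd(crossprod(xc, rc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(rot), 2, cr, `+`)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) abort(msg)
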