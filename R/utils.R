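# Small numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp1 <- function(x) pmin(1, pmax(-1, x))

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about the z axis
#' @param angle rotation angle in radians
#' @return 3x3 rotation matrix
#' @keywords internal
rot_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about an arbitrary unit axis.
rot_axis <- function(axis, angle) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation (quaternion method); draws 4 normals from the
# active RNG stream.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# Angle between two vectors via atan2: full precision near 0 and pi,
# unlike acos of the clamped dot product.
vec_angle <- function(u, v) {
  atan2(vnorm(cross3(u, v)), sum(u * v))
}

#' Minimum-image displacement under an orthorhombic box
#'
#' @param d displacement vector or n x 3 matrix of displacements (Angstrom)
#' @param box orthorhombic edge lengths (length-3 numeric) or `NULL` for a
#'   non-periodic system
#' @return displacement(s) wrapped to the nearest periodic image
#' @keywords internal
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

# All pairwise distances between two coordinate sets, minimum-image.
cross_dist <- function(xa, xb, box = NULL) {
  na <- nrow(xa); nb <- nrow(xb)
  dx <- rep(xa[, 1], times = nb) - rep(xb[, 1], each = na)
  dy <- rep(xa[, 2], times = nb) - rep(xb[, 2], each = na)
  dz <- rep(xa[, 3], times = nb) - rep(xb[, 3], each = na)
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  matrix(sqrt(dx * dx + dy * dy + dz * dz), na, nb)
}

min_cross_dist <- function(xa, xb, box = NULL) min(cross_dist(xa, xb, box))

# Scoped RNG: run `expr` under a seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Per-frame sub-stream seed derived from the master seed by a fixed offset
# (kept below 2^31 - 1).
frame_seed <- function(seed, frame_index) {
  (as.numeric(seed) + 10007 * as.numeric(frame_index)) %% 2147483647
}
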