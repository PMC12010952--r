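# Internal geometry and identity helpers shared across modules.

#' @noRd
res_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  paste(chain, resno, ins, sep = "|")
}

# Full cross pairwise Euclidean distance matrix between two coordinate
# matrices (n x 3, m x 3). Small negative values from cancellation are
# clamped before the sqrt.
#' @noRd
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Uniform random unit vector.
#' @noRd
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Rotation matrix about an arbitrary axis (Rodrigues formula), angle in
# radians.
#' @noRd
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation matrix (uniform over SO(3) via random quaternion).
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Small random rotation: axis uniform on the sphere, angle ~ N(0, sd_deg).
#' @noRd
random_small_rotation <- function(sd_deg) {
  rotation_about_axis(random_unit_vector(), stats::rnorm(1, 0, sd_deg * pi / 180))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
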