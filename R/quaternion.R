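#' Unit-quaternion helpers
#'
#' Rotations are parameterised internally by unit quaternions `(w, x, y, z)`;
#' rotation matrices and Euler angles appear only at I/O.
#'
#' @name quaternion
NULL

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion", call. = FALSE)
  q / n
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q numeric length-4 `(w, x, y, z)`, unit norm.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion (w >= 0)
#' @param R 3x3 rotation matrix.
#' @return numeric length-4 unit quaternion.
#' @export
matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- 0.25 * s
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Quaternion for a rotation about an axis
#' @param axis length-3 axis (normalised internally).
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# uniformly random unit quaternion (uses current RNG state)
random_quaternion <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  if (q[1] < 0) -q else q
}

# angle (rad) between two rotations given as quaternions; the chord-based
# form stays accurate for very small angles where acos(dot) loses precision
quat_angle_between <- function(q1, q2) {
  q1 <- quat_normalize(q1); q2 <- quat_normalize(q2)
  chord <- min(sqrt(sum((q1 - q2)^2)), sqrt(sum((q1 + q2)^2)))
  4 * asin(pmin(1, chord / 2))
}
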