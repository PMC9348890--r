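# Unit-quaternion utilities for particle orientations. Convention (w, x, y, z);
# q and -q represent the same rotation (double cover of SO(3)).

#' Normalize a quaternion
#' @param q Numeric length-4 vector `(w, x, y, z)`.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion")
  q / n
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return 3 x 3 rotation matrix acting on column vectors.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Draw quaternions uniformly over SO(3)
#'
#' Uses the standard subgroup-algorithm construction (three uniform variates),
#' giving the unique rotation-invariant distribution on orientations.
#'
#' @param n Number of quaternions.
#' @return n x 4 matrix of unit quaternions, rows `(w, x, y, z)`.
#' @export
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(w = sqrt(u1) * cos(2 * pi * u3),
        x = sqrt(1 - u1) * sin(2 * pi * u2),
        y = sqrt(1 - u1) * cos(2 * pi * u2),
        z = sqrt(u1) * sin(2 * pi * u3))
}
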