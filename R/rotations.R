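## Small rotation / rigid-body helpers used throughout the package.
## All rotation matrices are 3x3, right-handed, columns = axes.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Rotation matrix about a principal axis
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
#' @noRd
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @noRd
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @noRd
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues formula)
#'
#' @param axis length-3 vector (normalized internally).
#' @param theta angle in radians.
#' @keywords internal
#' @noRd
rot_axis <- function(axis, theta) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    if (abs(theta) < 1e-12) return(diag(3))
    stop("rotation axis has zero length")
  }
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Axis and angle of a rotation matrix
#'
#' Returns the rotation angle in `[0, pi]` and a unit axis.  For the identity
#' the axis is arbitrary (z is returned).
#' @keywords internal
#' @noRd
rot_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cth)
  if (theta < 1e-12) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(theta - pi) < 1e-7) {
    ## near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    ## fix signs using off-diagonals
    i <- which.max(ax)
    if (i == 1) {
      ax[2] <- B[1, 2] / ax[1]; ax[3] <- B[1, 3] / ax[1]
    } else if (i == 2) {
      ax[1] <- B[1, 2] / ax[2]; ax[3] <- B[2, 3] / ax[2]
    } else {
      ax[1] <- B[1, 3] / ax[3]; ax[2] <- B[2, 3] / ax[3]
    }
    ax <- ax / sqrt(sum(ax^2))
    return(list(axis = ax, angle = theta))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(axis = ax / sqrt(sum(ax^2)), angle = theta)
}

#' Check that a matrix is a proper rotation
#' @keywords internal
#' @noRd
assert_rotation <- function(R, tol = 1e-8, what = "rotation") {
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop(sprintf("%s matrix is not orthonormal with det +1", what))
  invisible(R)
}

#' Signed angle from vector a to vector b about axis n
#' @keywords internal
#' @noRd
signed_angle <- function(a, b, n) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sum(cr * n), sum(a * b))
}

#' Optimal rigid superposition (Kabsch, SVD-based)
#'
#' Finds rotation `R` and translation `t` minimising
#' `sum_i w_i |R x_i + t - y_i|^2` for paired coordinate sets.
#'
#' @param x,y n x 3 matrices of source and target coordinates.
#' @param w optional weights (length n).
#' @return list with `R` (3x3), `t` (length 3) and `rmsd`.
#' @export
kabsch <- function(x, y, w = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 3)
  if (is.null(w)) w <- rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- t(xc * w) %*% yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, cy, `+`)
  rmsd <- sqrt(sum(w * rowSums((fit - y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Wrap angles (degrees) into (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Minimum-image angular difference in degrees
#' @keywords internal
#' @noRd
ang_diff <- function(a, b) wrap180(a - b)
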