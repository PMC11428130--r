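## Rotation utilities shared by fixture construction, sampling and tests.

#' Rotation matrix carrying unit vector a onto unit vector b
#' @param a,b numeric length-3 vectors (need not be normalised).
#' @return 3 x 3 rotation matrix R with `R %*% a` parallel to `b`.
#' @export
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    ## antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Rotation about an axis by an angle (Rodrigues)
#' @param axis numeric length-3 axis.
#' @param theta angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * ux + (1 - cos(theta)) * ux %*% ux
}

## Least-squares rotation mapping row set A onto row set B (both k x 3,
## already centred / directional). Kabsch via SVD, proper rotation.
kabsch_rotation <- function(A, B) {
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Uniform random rotation matrix
#' @param rng an RNG stream from the package's seeded-stream helper, or an
#'   integer seed.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(rng) {
  if (!is.function(rng)) rng <- make_rng(rng)
  M <- matrix(rng("norm", 9L), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Deterministic SO(3) frame from a metal-centred context: Gram-Schmidt on
## the first two non-collinear context atoms; third axis by cross product.
## Rotating the context by R rotates the frame to R Q, which is what makes
## seeded sampling commute with rotations.
context_frame <- function(coords) {
  n <- nrow(coords)
  if (n < 1L) return(diag(3))
  e1 <- NULL
  for (i in seq_len(n)) {
    v <- coords[i, ]
    if (sqrt(sum(v^2)) > 1e-8) { e1 <- v / sqrt(sum(v^2)); break }
  }
  if (is.null(e1)) return(diag(3))
  e2 <- NULL
  for (i in seq_len(n)) {
    v <- coords[i, ] - sum(coords[i, ] * e1) * e1
    if (sqrt(sum(v^2)) > 1e-6) { e2 <- v / sqrt(sum(v^2)); break }
  }
  if (is.null(e2)) {
    warning("context is collinear; using an axis-aligned sampling frame")
    p <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * e1) * e1
    e2 <- v / sqrt(sum(v^2))
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}
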