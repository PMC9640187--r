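# Internal geometry helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angle` degrees
#' about the (normalized) `axis`.
#'
#' @param axis numeric(3), rotation axis (normalized internally).
#' @param angle rotation angle in degrees.
#' @return a 3x3 orthogonal matrix with determinant +1.
#' @export
rotationMatrix <- function(axis, angle) {
  u <- unitv(as.numeric(axis))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply rotation R and translation t to an n x 3 coordinate matrix.
transformCoords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Rotate n x 3 coords about `axis` through point `pivot` by `angle` degrees.
rotateAboutAxis <- function(xyz, axis, angle, pivot = c(0, 0, 0)) {
  R <- rotationMatrix(axis, angle)
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, -pivot)
}

# Angle (degrees) at vertex b of the triangle a-b-c.
angleAt <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# All pairwise Euclidean distances between rows of A (n x 3) and B (m x 3).
crossDist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# NeRF atom placement: position of atom D given positions A-B-C, the C-D bond
# length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
placeAtom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
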