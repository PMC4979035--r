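# Internal geometry helpers. All coordinates Angstrom, angles radians unless
# a function name says degrees.

.unit <- function(v) v / sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle A-B-C at vertex B, radians
.angle3 <- function(A, B, C) {
  u <- .unit(A - B); v <- .unit(C - B)
  acos(max(-1, min(1, sum(u * v))))
}

# Place atom D from reference atoms A-B-C with |CD| = bond, angle(B,C,D) =
# ang and dihedral(A,B,C,D) = tors (natural extension reference frame).
.placeAtom <- function(A, B, C, bond, ang, tors) {
  bc <- .unit(C - B)
  n  <- .unit(.cross(B - A, bc))
  m  <- cbind(bc, .cross(n, bc), n)
  d  <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tors),
          bond * sin(ang) * sin(tors))
  C + as.numeric(m %*% d)
}

# All pairwise distances between rows of two coordinate matrices
.crossDist <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  dx <- outer(X[, 1], Y[, 1], "-")
  dy <- outer(X[, 2], Y[, 2], "-")
  dz <- outer(X[, 3], Y[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}
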