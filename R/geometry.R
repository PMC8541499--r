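# Small 3-vector helpers used across modules. Coordinates are plain
# numeric length-3 vectors or n x 3 matrices; units nm unless stated.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle a-b-c at vertex b, degrees.
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ca <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d by the atan2 convention, in degrees in
#' `(-180, 180]`.
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors.
#' @return Dihedral in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural-extension (NeRF) placement: position a new atom d given the three
# preceding atoms a-b-c, the bond length c-d, the angle b-c-d (degrees) and
# the torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign fixed to the atan2 dihedral convention
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.vector(m %*% d2) + c
}

# Uniform random rotation matrix via a normalised quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Apply a rigid transform (3x3 rotation + translation) to every frame.
transform_frames <- function(coords, rot, shift = c(0, 0, 0)) {
  nf <- dim(coords)[1]
  out <- coords
  for (i in seq_len(nf)) {
    m <- matrix(coords[i, , ], ncol = 3) %*% t(rot)
    out[i, , ] <- sweep(m, 2, shift, `+`)
  }
  out
}
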