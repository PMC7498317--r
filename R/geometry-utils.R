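## Small internal 3D geometry helpers shared by the builders and the
## geometry/superposition modules.

rotZ <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

## rotation by `deg` degrees about arbitrary unit axis (Rodrigues)
rotAxis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

angleDeg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
}

torsionDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  m1 <- pracma::cross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## NeRF placement: position of atom D given A-B-C, |CD|, angle(BCD),
## torsion(ABCD) (degrees)
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unitv(c - b)
  ab <- b - a
  n <- unitv(ab - sum(ab * bc) * bc)
  m <- pracma::cross(bc, n)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * n + d2[3] * m
}

## Kabsch: proper rotation R and translation t minimizing |R x + t - y|
## over paired rows of x (mobile) and y (reference)
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  H <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.vector(cy - R %*% cx))
}

## orthonormalize the average of rotation matrices (nearest rotation in
## Frobenius norm)
averageRotation <- function(...) {
  M <- Reduce(`+`, list(...))
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## signed angle (degrees) from v1 to v2 about unit axis n
signedAngle <- function(v1, v2, n) {
  v1 <- unitv(v1 - sum(v1 * n) * n)
  v2 <- unitv(v2 - sum(v2 * n) * n)
  atan2(sum(pracma::cross(v1, v2) * n), sum(v1 * v2)) * 180 / pi
}
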