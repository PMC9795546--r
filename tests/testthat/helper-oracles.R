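# Independent oracle implementations used for dual-route checks. These are
# deliberately written with different algorithms than the package code.

# Dihedral via the direct atan2 normal-vector formula (independent of the
# projection-based implementation in the package).
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2); y <- sum(cr * b2) / sqrt(sum(b2 * b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# RMSD after optimal superposition via Horn's quaternion method -- a
# different algorithm from the package's SVD-based Kabsch solve.
oracleRmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(B, A)  # t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A * A) + sum(B * B) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force Daura clustering: recomputes neighbour lists from the distance
# matrix by full rescans each round (no adjacency bookkeeping).
oracleDaura <- function(D, cutoff) {
  n <- nrow(D)
  pool <- seq_len(n)
  membership <- integer(n)
  cl <- 0L
  while (length(pool)) {
    cl <- cl + 1L
    bestCount <- -1L; bestFrame <- NA_integer_
    for (f in pool) {
      cnt <- sum(D[f, pool] < cutoff)
      if (cnt > bestCount) { bestCount <- cnt; bestFrame <- f }
    }
    members <- pool[D[bestFrame, pool] < cutoff]
    membership[members] <- cl
    pool <- setdiff(pool, members)
  }
  membership
}

# Random rigid transform (proper rotation + translation).
randomRigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3))
}

applyRigidTo <- function(coords, rigid) {
  out <- coords %*% t(rigid$R) +
    matrix(rigid$t, nrow(coords), 3, byrow = TRUE)
  rownames(out) <- rownames(coords)
  out
}

rigidEnsemble <- function(ensemble, rigid) {
  for (f in seq_len(nFrames(ensemble)))
    ensemble@coords[, , f] <- applyRigidTo(ensemble@coords[, , f], rigid)
  ensemble
}
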