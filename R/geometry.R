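# Vector geometry: dihedrals, Kabsch superposition, RMSD. Units: nm, degrees.

# Vectorised dihedral over n x 3 point matrices; returns degrees in (-180, 180].
.dihedralMat <- function(p1, p2, p3, p4, labels = NULL) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  n1 <- .rowNorm(b1)
  if (any(n1 < 1e-12)) stop("degenerate geometry: coincident central atoms")
  b1 <- b1 / n1
  # collinearity of (p1,p2,p3) or (p2,p3,p4): zero rejection of b0 / b2
  v <- b0 - rowSums(b0 * b1) * b1
  w <- b2 - rowSums(b2 * b1) * b1
  bad <- .rowNorm(v) < 1e-9 | .rowNorm(w) < 1e-9
  if (any(bad)) {
    what <- if (is.null(labels)) "three consecutive points are collinear"
            else paste("collinear triplet involving atoms:",
                       paste(labels, collapse = ", "))
    stop("degenerate geometry: ", what)
  }
  x <- rowSums(v * w)
  y <- rowSums(.cross(b1, v) * w)
  wrapAngle(.rad2deg(atan2(y, x)))
}

#' Signed torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = 180, positive when, looking from
#' p2 towards p3, the far bond rotates clockwise relative to the near bond.
#' This matches the convention used by standard structural-biology toolkits,
#' so phi/psi of an alpha-helical L-residue come out negative.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, or n x 3 matrices for a
#'   vectorised series of quadruples.
#' @param labels optional atom labels used in degenerate-geometry errors.
#' @return angle(s) in degrees, in (-180, 180].
#' @examples
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0))  # trans: 180
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1))  # +90
#' @export
dihedralAngle <- function(p1, p2, p3, p4, labels = NULL) {
  .dihedralMat(.asRowMatrix(p1), .asRowMatrix(p2),
               .asRowMatrix(p3), .asRowMatrix(p4), labels = labels)
}

# Angle p1-p2-p3 at p2, degrees; vectorised over rows.
.angleMat <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  cosang <- rowSums(v1 * v2) / (.rowNorm(v1) * .rowNorm(v2))
  .rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

# Resolve an AtomSelection to coordinate rows of a conformer matrix.
.resolveSelection <- function(coords, selection) {
  keys <- .atomKey(selection@resno, selection@atom)
  idx <- match(keys, rownames(coords))
  if (anyNA(idx))
    stop("selection atoms not found: ",
         paste(keys[is.na(idx)], collapse = ", "))
  idx
}

# Kabsch/Procrustes: optimal proper rotation of B (mobile, centered) onto
# A (reference, centered). Returns list(R, rmsd).
.kabsch <- function(A, B) {
  C <- crossprod(B, A)            # 3x3, t(B) %*% A
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)       # x_fit = R %*% x_mobile
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(R = R, rmsd = rmsd)
}

#' Least-squares superposition of two conformers
#'
#' Centers both conformers on the centroid of the selected atoms, then solves
#' the orthogonal Procrustes problem by singular value decomposition with a
#' determinant correction so that reflections are excluded. The returned RMSD
#' is the minimum attainable over all rigid transforms of the selected atoms.
#'
#' @param reference,mobile \linkS4class{Conformer} objects (or plain
#'   coordinate matrices with atom-key rownames).
#' @param selection an \linkS4class{AtomSelection}; at least 3 non-collinear
#'   atoms.
#' @return a \linkS4class{SuperpositionResult}; applying
#'   \code{x \%*\% t(rotation) + translation} to mobile coordinates realises
#'   the fit.
#' @export
superpose <- function(reference, mobile, selection) {
  refc <- if (is(reference, "Conformer")) reference@coords else reference
  mobc <- if (is(mobile, "Conformer")) mobile@coords else mobile
  ir <- .resolveSelection(refc, selection)
  im <- .resolveSelection(mobc, selection)
  if (length(ir) < 3) stop("selection must contain at least 3 atoms")
  A <- refc[ir, , drop = FALSE]
  B <- mobc[im, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A <- sweep(A, 2, ca); B <- sweep(B, 2, cb)
  # degenerate (collinear) selections leave the rotation underdetermined
  if (qr(A)$rank < 2 || qr(B)$rank < 2)
    stop("degenerate selection: selected atoms are collinear")
  k <- .kabsch(A, B)
  new("SuperpositionResult", rotation = k$R,
      translation = as.numeric(ca - k$R %*% cb), rmsd = k$rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param fit a \linkS4class{SuperpositionResult}.
#' @param coords n x 3 coordinate matrix (or a \linkS4class{Conformer}).
#' @return transformed coordinates of the same shape.
#' @export
applySuperposition <- function(fit, coords) {
  m <- if (is(coords, "Conformer")) coords@coords else coords
  out <- m %*% t(fit@rotation) + matrix(fit@translation, nrow(m), 3,
                                        byrow = TRUE)
  rownames(out) <- rownames(m)
  if (is(coords, "Conformer")) {
    coords@coords <- out
    coords
  } else out
}

#' Per-frame RMSD of an ensemble against a reference conformer
#'
#' Each value is the superposition RMSD (\code{\link{superpose}}) of that
#' frame onto the reference over the selection -- the standard folded-state
#' deviation measure for a hairpin backbone.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param reference a \linkS4class{Conformer}.
#' @param selection an \linkS4class{AtomSelection}; defaults to backbone
#'   N/CA/C of residues 2--11.
#' @return numeric vector of per-frame RMSD values in nm.
#' @export
rmsdSeries <- function(ensemble, reference, selection = backboneSelection()) {
  stopifnot(is(ensemble, "Ensemble"))
  nf <- nFrames(ensemble)
  if (nf < 1) stop("empty ensemble")
  refc <- if (is(reference, "Conformer")) reference@coords else reference
  ir <- .resolveSelection(refc, selection)
  A <- refc[ir, , drop = FALSE]
  A <- sweep(A, 2, colMeans(A))
  im <- .resolveSelection(ensemble@coords[, , 1], selection)
  vapply(seq_len(nf), function(i) {
    B <- ensemble@coords[im, , i]
    B <- sweep(B, 2, colMeans(B))
    .kabsch(A, B)$rmsd
  }, numeric(1))
}
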