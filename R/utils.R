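# Internal helpers shared across modules. All lengths are nm, all angles degrees.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrapAngle <- function(x) {
  y <- x %% 360
  y - 360 * (y > 180)
}

# Shortest wrapped angular difference a - b, in (-180, 180]
.angDiff <- function(a, b) wrapAngle(a - b)

# Row-wise cross product for n x 3 matrices
.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rowNorm <- function(a) sqrt(rowSums(a * a))

.asRowMatrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, nrow = 1)
}

.atomKey <- function(resno, atom) paste0(resno, ":", atom)

# Internal geometry table used by the chain builder (nm / degrees).
# Standard peptide values; only internal consistency matters for the
# geometric analyses built on top.
.GEOM <- list(
  b = c(NCA = 0.147, CAC = 0.153, CN = 0.133, CO = 0.123, NH = 0.100,
        NNB = 0.140, NBHB = 0.100, CACB = 0.153),
  a = c(NCAC = 111, CACN = 116, CNCA = 122, CACO = 121, CNH = 119,
        CNNB = 119, NNBHB = 120, CANH3 = 109.5, CCACB = 109.45),
  # torsion N-C-CA-CB fixing the CA chirality (+ for L, sign flips for D)
  tauCB = 120,
  # rotation of the amination NH2 plane about the N-NB bond, measured as the
  # torsion C(i-1)-N(i)-NB-HB2; frozen so the intraresidue C6 contact forms
  # in beta-strand backbone conformations (HB1 sits at tauAmine + 180)
  tauAmine = 173
)
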