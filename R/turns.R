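# Beta-turn typing, peptide-plane-flip counting, hairpin twist metric and
# Ramachandran-region occupancy.

.TURN_LABELS <- c("I'", "II'", "other")

# Wrapped Euclidean distance in the 4-torus of (phi1, psi1, phi2, psi2).
.turnDist <- function(phiPsi, center) {
  d <- .angDiff(phiPsi, matrix(center, nrow(phiPsi), 4, byrow = TRUE))
  sqrt(rowSums(d * d))
}

#' Classify a beta-turn from the (phi, psi) of its two central residues
#'
#' Nearest canonical turn center (type I' = (60, 30)/(90, 0), type II' =
#' (60, -120)/(-80, 0)) in wrapped Euclidean angle distance over the four
#' torsions; \code{"other"} when both centers are farther than
#' \code{cutoff}.
#'
#' @param phiPsi1 (phi, psi) of turn residue i+1: length-2 vector or an
#'   n x 2 matrix for a series.
#' @param phiPsi2 (phi, psi) of turn residue i+2, same shape.
#' @param cutoff classification radius in degrees (default 60).
#' @return character vector of \code{"I'"}, \code{"II'"} or \code{"other"}.
#' @examples
#' classifyTurn(c(60, 30), c(90, 0))      # "I'"
#' classifyTurn(c(60, -120), c(-80, 0))   # "II'"
#' @export
classifyTurn <- function(phiPsi1, phiPsi2, cutoff = 60) {
  m1 <- .asRowMatrix(phiPsi1)
  m2 <- .asRowMatrix(phiPsi2)
  x <- cbind(m1, m2)
  canon <- turnCanon()
  dI <- .turnDist(x, as.vector(t(canon[["I'"]])))
  dII <- .turnDist(x, as.vector(t(canon[["II'"]])))
  lab <- ifelse(dI < dII, "I'", "II'")
  lab[pmin(dI, dII) > cutoff] <- "other"
  lab
}

#' Classify the turn type from psi of the turn's i+1 residue alone
#'
#' The quick classifier behind turn-type populations: type I' when the
#' wrapped psi is nearer the canonical I' value of 30 degrees than the
#' canonical II' value of -120 degrees, type II' otherwise. The decision
#' boundaries sit at the wrapped midpoints -45 and 135 degrees; boundary
#' values are assigned II'.
#'
#' @param psi numeric vector of psi angles in degrees.
#' @return character vector of \code{"I'"} / \code{"II'"}.
#' @examples
#' classifyTurnByPsi(c(30, -120, 140))  # I', II', II'
#' @export
classifyTurnByPsi <- function(psi) {
  dI <- abs(.angDiff(psi, 30))
  dII <- abs(.angDiff(psi, -120))
  ifelse(dI < dII, "I'", "II'")
}

#' Count peptide-plane-flip transitions from a turn-type label series
#'
#' Frames labelled \code{"other"} inherit the previous defined label
#' (leading undefined frames are dropped). Runs shorter than
#' \code{debounce} frames are merged into the preceding run, then the
#' number of I' <-> II' label changes is counted. The default
#' \code{debounce = 1} applies no smoothing.
#'
#' @param labels character vector of per-frame labels
#'   (\code{"I'"}, \code{"II'"}, \code{"other"}).
#' @param debounce minimum run length (frames) for a state visit to count.
#' @return integer transition count.
#' @examples
#' countFlips(c("I'", "I'", "II'", "II'", "I'"))  # 2
#' @export
countFlips <- function(labels, debounce = 1L) {
  if (length(labels) < 1) stop("need at least one frame")
  lab <- labels
  # carry the previous defined label over "other" frames
  def <- lab %in% c("I'", "II'")
  if (!any(def)) return(0L)
  lab <- lab[which(def)[1]:length(lab)]
  for (t in seq_along(lab))
    if (!lab[t] %in% c("I'", "II'")) lab[t] <- lab[t - 1]
  r <- rle(lab)
  if (debounce > 1L && length(r$lengths) > 1L) {
    keep <- r$lengths >= debounce
    keep[1] <- TRUE
    vals <- r$values[keep]
    vals <- vals[c(TRUE, vals[-1] != vals[-length(vals)])]
  } else {
    vals <- r$values
  }
  sum(vals[-1] != vals[-length(vals)])
}

#' Hairpin twist angle series
#'
#' The cross-strand torsion angle over four backbone atoms (by default
#' C of residue 1, N of residue 12, C of residue 8, N of residue 5) measured
#' per frame; its mean quantifies the right-hand twist of the two strands.
#' The mean is circular (resultant-vector direction), which coincides with
#' the linear mean to well under 0.1 degree for angle distributions
#' clustered away from the +/-180 seam.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param atoms character vector of four atom keys
#'   (\code{"<resno>:<atom>"}); the default is the hairpin twist torsion
#'   1C-12N-8C-5N.
#' @return list with \code{angles} (per-frame degrees in (-180, 180]) and
#'   \code{mean} (circular mean, degrees).
#' @export
twistSeries <- function(ensemble,
                        atoms = c("1:C", "12:N", "8:C", "5:N")) {
  stopifnot(is(ensemble, "Ensemble"), length(atoms) == 4)
  if (anyDuplicated(atoms)) stop("twist atoms must be distinct")
  keys <- atomKeys(ensemble)
  idx <- match(atoms, keys)
  if (anyNA(idx)) stop("missing atom: ", atoms[is.na(idx)][1])
  nf <- nFrames(ensemble)
  pick <- function(i) {
    m <- t(ensemble@coords[idx[i], , , drop = TRUE])
    if (nf == 1L) m <- matrix(ensemble@coords[idx[i], , 1], 1, 3)
    m
  }
  ang <- .dihedralMat(pick(1), pick(2), pick(3), pick(4), labels = atoms)
  rad <- .deg2rad(ang)
  list(angles = ang,
       mean = wrapAngle(.rad2deg(atan2(mean(sin(rad)), mean(cos(rad))))))
}

#' Ramachandran region of (phi, psi) pairs
#'
#' Rectangular region definitions (declared, versioned with the package):
#' beta is phi in (-180, -45) with psi in (45, 180] or (-180, -150);
#' alpha is phi in (-160, -20) with psi in (-120, 30); beta wins ties
#' (the boxes as defined do not overlap). Everything else is "other".
#'
#' @param phi,psi numeric vectors in degrees.
#' @return character vector of \code{"alpha"}, \code{"beta"}, \code{"other"}.
#' @export
ramaRegion <- function(phi, psi) {
  phi <- wrapAngle(phi); psi <- wrapAngle(psi)
  beta <- phi > -180 & phi < -45 & (psi > 45 | psi < -150)
  alpha <- !beta & phi > -160 & phi < -20 & psi > -120 & psi < 30
  out <- rep("other", length(phi))
  out[alpha] <- "alpha"
  out[beta] <- "beta"
  out
}

#' Per-residue Ramachandran-region occupancy over an ensemble
#'
#' Fraction of frames each residue spends in the alpha, beta and other
#' regions of (phi, psi) space (\code{\link{ramaRegion}}); fractions sum to
#' 1 per residue. Residues with undefined phi or psi are skipped.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param residues residue indices to report (default: all with defined
#'   phi and psi).
#' @return data.frame with columns \code{resno}, \code{alpha}, \code{beta},
#'   \code{other}.
#' @export
ramaOccupancy <- function(ensemble, residues = NULL) {
  ts <- torsionSeries(ensemble)
  n <- dim(ts)[1]
  if (is.null(residues))
    residues <- which(apply(!is.na(ts[, "phi", , drop = FALSE]), 1, all) &
                      apply(!is.na(ts[, "psi", , drop = FALSE]), 1, all))
  rows <- lapply(residues, function(i) {
    reg <- ramaRegion(ts[i, "phi", ], ts[i, "psi", ])
    data.frame(resno = i,
               alpha = mean(reg == "alpha"),
               beta = mean(reg == "beta"),
               other = mean(reg == "other"))
  })
  do.call(rbind, rows)
}

#' Turn-type summary of an ensemble
#'
#' Classifies every frame's turn (both the full two-residue classifier and
#' the psi-only classifier on the turn's i+1 residue), reports populations
#' and the peptide-plane-flip count.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param turnResidues the two turn residues (default 6:7).
#' @param debounce flip-count debounce in frames (default 1 = none).
#' @return list with \code{labels}, \code{labelsByPsi} (per frame),
#'   \code{populations} (percent I'/II'/other), \code{populationsByPsi},
#'   \code{flips} (full-classifier flip count), \code{flipsByPsi}.
#' @export
turnSummary <- function(ensemble, turnResidues = 6:7, debounce = 1L) {
  ts <- torsionSeries(ensemble)
  i1 <- turnResidues[1]; i2 <- turnResidues[2]
  m1 <- cbind(ts[i1, "phi", ], ts[i1, "psi", ])
  m2 <- cbind(ts[i2, "phi", ], ts[i2, "psi", ])
  lab <- classifyTurn(m1, m2)
  labPsi <- classifyTurnByPsi(ts[i1, "psi", ])
  popOf <- function(l) {
    p <- 100 * c("I'" = mean(l == "I'"), "II'" = mean(l == "II'"),
                 other = mean(l == "other"))
    p
  }
  list(labels = lab, labelsByPsi = labPsi,
       populations = popOf(lab), populationsByPsi = popOf(labPsi),
       flips = countFlips(lab, debounce),
       flipsByPsi = countFlips(labPsi, debounce))
}
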