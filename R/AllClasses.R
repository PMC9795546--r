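#' @import methods
NULL

#' Peptide topology
#'
#' Static description of a peptide chain: residue sequence, chirality flags,
#' backbone N-amination sites, terminal chemistry and the derived atom roster.
#' Every analysis in the package resolves atoms against this object.
#'
#' @slot residues data.frame with columns \code{name} (3-letter code),
#'   \code{chirality} ("L", "D" or "achiral") and \code{nAminated} (logical).
#' @slot nTermProtonated logical; \code{TRUE} models a protonated N-terminus
#'   carrying an NH3+ group (hydrogens H1/H2/H3).
#' @slot cTermAmide logical; \code{TRUE} adds the C-terminal amide nitrogen
#'   \code{NT} (its hydrogens are not modelled and it is not a donor).
#' @slot atoms data.frame with columns \code{resno}, \code{atom}: the full
#'   atom roster, one row per atom, in build order.
#' @slot pseudoAcceptors data.frame with columns \code{resno}, \code{atom}:
#'   declared side-chain acceptor stubs, placed on the CB direction by the
#'   builder (approximation; side chains beyond CB are not modelled).
#' @export
setClass("PeptideTopology", representation(
  residues = "data.frame",
  nTermProtonated = "logical",
  cTermAmide = "logical",
  atoms = "data.frame",
  pseudoAcceptors = "data.frame"
))

setValidity("PeptideTopology", function(object) {
  res <- object@residues
  msgs <- character()
  if (nrow(res) < 1) msgs <- c(msgs, "topology needs at least one residue")
  if (!all(c("name", "chirality", "nAminated") %in% names(res)))
    msgs <- c(msgs, "residues must have columns name, chirality, nAminated")
  if (!all(res$chirality %in% c("L", "D", "achiral")))
    msgs <- c(msgs, "chirality must be L, D or achiral")
  bad <- res$nAminated & res$name == "PRO"
  if (any(bad)) msgs <- c(msgs, "proline cannot be N-aminated (no amide H)")
  key <- .atomKey(object@atoms$resno, object@atoms$atom)
  if (anyDuplicated(key)) msgs <- c(msgs, "duplicate atoms in roster")
  if (length(msgs)) msgs else TRUE
})

#' Set of backbone torsion angles
#'
#' Per-residue (phi, psi, omega) in degrees, in (-180, 180]. Undefined
#' torsions (e.g. phi of residue 1) are \code{NA}.
#'
#' @slot angles numeric matrix, one row per residue, columns
#'   \code{phi}, \code{psi}, \code{omega}.
#' @export
setClass("TorsionSet", representation(angles = "matrix"))

setValidity("TorsionSet", function(object) {
  a <- object@angles
  if (!identical(colnames(a), c("phi", "psi", "omega")))
    return("angles must have columns phi, psi, omega")
  v <- a[!is.na(a)]
  if (any(v <= -180 | v > 180)) return("angles must lie in (-180, 180]")
  TRUE
})

#' Single conformer (one frame of Cartesian coordinates)
#'
#' @slot coords numeric matrix (n atoms x 3), in nm, with rownames
#'   \code{"<resno>:<atom>"}.
#' @slot frameIndex integer frame index (>= 0).
#' @slot timePs frame time stamp in ps, or \code{NA}.
#' @export
setClass("Conformer", representation(
  coords = "matrix", frameIndex = "integer", timePs = "numeric"
))

setValidity("Conformer", function(object) {
  if (ncol(object@coords) != 3) return("coords must be an n x 3 matrix")
  if (is.null(rownames(object@coords))) return("coords must have atom-key rownames")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' Conformer ensemble
#'
#' A stack of conformers sharing one topology, stored as an
#' atoms x 3 x frames array (nm).
#'
#' @slot topology the shared \linkS4class{PeptideTopology}.
#' @slot coords numeric array (n atoms x 3 x n frames) with atom-key dimnames.
#' @slot frameIndex integer vector of frame indices.
#' @slot timePs numeric vector of time stamps (ps) or \code{NA}.
#' @slot source character vector: source-trajectory id of each frame.
#' @export
setClass("Ensemble", representation(
  topology = "PeptideTopology",
  coords = "array",
  frameIndex = "integer",
  timePs = "numeric",
  source = "character"
))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3) return("coords must be atoms x 3 x frames")
  nf <- d[3]
  if (nf < 1) return("ensemble must contain at least one frame")
  if (length(object@frameIndex) != nf) return("frameIndex length mismatch")
  if (length(object@source) != nf) return("source length mismatch")
  want <- .atomKey(object@topology@atoms$resno, object@topology@atoms$atom)
  have <- dimnames(object@coords)[[1]]
  if (!identical(have, want)) return("coords atom keys must match topology roster")
  TRUE
})

#' Atom selection
#'
#' An ordered set of (residue index, atom name) pairs resolved against a
#' topology at use time.
#'
#' @slot resno integer vector of 1-based residue indices.
#' @slot atom character vector of atom names.
#' @export
setClass("AtomSelection", representation(resno = "integer", atom = "character"))

setValidity("AtomSelection", function(object) {
  if (length(object@resno) != length(object@atom)) return("length mismatch")
  if (length(object@resno) == 0) return("selection must be non-empty")
  if (anyDuplicated(.atomKey(object@resno, object@atom)))
    return("selection entries must be unique")
  TRUE
})

#' Geometric hydrogen-bond criteria
#'
#' @slot maxDist maximum hydrogen--acceptor distance in nm (exclusive).
#' @slot minAngle minimum donor--hydrogen--acceptor angle in degrees
#'   (exclusive), measured at the hydrogen.
#' @slot preset one of \code{"medium_strong"}, \code{"weak"}, \code{"custom"}.
#' @export
setClass("HBondCriteria", representation(
  maxDist = "numeric", minAngle = "numeric", preset = "character"
))

setValidity("HBondCriteria", function(object) {
  if (object@maxDist <= 0) return("maxDist must be > 0")
  if (object@minAngle < 0 || object@minAngle > 180)
    return("minAngle must be in [0, 180]")
  TRUE
})

#' Rigid-body superposition result
#'
#' Least-squares (Kabsch) fit of a mobile conformer onto a reference over a
#' selection; reflections are excluded. Applying
#' \code{x \%*\% t(rotation) + translation} to mobile coordinates realises the
#' fit.
#'
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation length-3 numeric translation (nm).
#' @slot rmsd minimum attainable RMSD over the selection (nm).
#' @export
setClass("SuperpositionResult", representation(
  rotation = "matrix", translation = "numeric", rmsd = "numeric"
))

setValidity("SuperpositionResult", function(object) {
  if (!isTRUE(all.equal(det(object@rotation), 1, tolerance = 1e-6)))
    return("rotation must have determinant +1")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' Conformational state template for the synthetic generator
#'
#' @slot label state label.
#' @slot torsions \linkS4class{TorsionSet} of the noiseless template.
#' @slot jitterSigma Gaussian torsion jitter standard deviation (degrees).
#' @export
setClass("StateTemplate", representation(
  label = "character", torsions = "TorsionSet", jitterSigma = "numeric"
))

setValidity("StateTemplate", function(object) {
  if (object@jitterSigma < 0) return("jitterSigma must be >= 0")
  TRUE
})

#' Markov specification for synthetic ensembles
#'
#' @slot states list of \linkS4class{StateTemplate}.
#' @slot transitionMatrix row-stochastic matrix (rows sum to 1 within 1e-12).
#' @slot initialState label of the starting state.
#' @slot nFrames number of frames to generate.
#' @slot seed RNG seed; same seed gives bit-identical ensembles.
#' @export
setClass("MarkovSpec", representation(
  states = "list", transitionMatrix = "matrix", initialState = "character",
  nFrames = "integer", seed = "integer"
))

setValidity("MarkovSpec", function(object) {
  k <- length(object@states)
  P <- object@transitionMatrix
  if (!all(dim(P) == c(k, k))) return("transition matrix dimension mismatch")
  if (any(P < 0)) return("transition probabilities must be >= 0")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    return("transition matrix rows must sum to 1 (within 1e-12)")
  labs <- vapply(object@states, function(s) s@label, character(1))
  if (!(object@initialState %in% labs)) return("unknown initial state")
  if (object@nFrames < 1) return("nFrames must be >= 1")
  TRUE
})

#' Daura clustering result
#'
#' @slot membership integer cluster id per pooled frame (1 = largest cluster).
#' @slot medoids integer vector: pooled frame index of each cluster medoid.
#' @slot sizes integer cluster sizes (non-increasing).
#' @slot source character source-trajectory id per pooled frame.
#' @slot contributions numeric matrix (clusters x sources): percent of each
#'   source's frames falling in each cluster.
#' @export
setClass("ClusterResult", representation(
  membership = "integer", medoids = "integer", sizes = "integer",
  source = "character", contributions = "matrix"
))

setValidity("ClusterResult", function(object) {
  n <- length(object@membership)
  k <- length(object@medoids)
  if (length(object@sizes) != k) return("sizes/medoids length mismatch")
  if (!all(sort(unique(object@membership)) == seq_len(k)))
    return("membership must partition frames into clusters 1..k")
  if (any(diff(object@sizes) > 0)) return("clusters must be ordered by size")
  if (!all(object@membership[object@medoids] == seq_len(k)))
    return("each medoid must belong to its own cluster")
  if (length(object@source) != n) return("source length mismatch")
  TRUE
})
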