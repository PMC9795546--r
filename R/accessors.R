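#' @describeIn nFrames frames in an ensemble
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])

#' @describeIn nFrames a single conformer has one frame
#' @export
setMethod("nFrames", "Conformer", function(x) 1L)

#' @describeIn nResidues residues in a topology
#' @export
setMethod("nResidues", "PeptideTopology", function(x) nrow(x@residues))

#' @describeIn nResidues residues of the underlying topology
#' @export
setMethod("nResidues", "Ensemble", function(x) nrow(x@topology@residues))

#' @describeIn nResidues rows of the torsion matrix
#' @export
setMethod("nResidues", "TorsionSet", function(x) nrow(x@angles))

#' @describeIn atomKeys roster keys of a topology
#' @export
setMethod("atomKeys", "PeptideTopology", function(x)
  .atomKey(x@atoms$resno, x@atoms$atom))

#' @describeIn atomKeys rownames of the coordinate matrix
#' @export
setMethod("atomKeys", "Conformer", function(x) rownames(x@coords))

#' @describeIn atomKeys atom dimnames of the coordinate array
#' @export
setMethod("atomKeys", "Ensemble", function(x) dimnames(x@coords)[[1]])

#' @describeIn torsionAngles the angle matrix
#' @export
setMethod("torsionAngles", "TorsionSet", function(x) x@angles)

#' @describeIn membership accessor
#' @export
setMethod("membership", "ClusterResult", function(x) x@membership)

#' @describeIn medoids accessor
#' @export
setMethod("medoids", "ClusterResult", function(x) x@medoids)

#' @describeIn clusterSizes accessor
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) x@sizes)

#' @describeIn contributions accessor
#' @export
setMethod("contributions", "ClusterResult", function(x) x@contributions)

#' Topology of an ensemble
#' @param x an \linkS4class{Ensemble}.
#' @return the shared \linkS4class{PeptideTopology}.
#' @export
ensembleTopology <- function(x) {
  stopifnot(is(x, "Ensemble"))
  x@topology
}

#' Extract one conformer from an ensemble
#'
#' @param x an \linkS4class{Ensemble}.
#' @param i frame number (1-based position in the ensemble).
#' @return a \linkS4class{Conformer}.
#' @export
getConformer <- function(x, i) {
  stopifnot(is(x, "Ensemble"))
  i <- as.integer(i)
  if (i < 1 || i > nFrames(x)) stop("frame index out of range: ", i)
  m <- x@coords[, , i, drop = TRUE]
  dimnames(m) <- list(atomKeys(x), NULL)
  new("Conformer", coords = m, frameIndex = x@frameIndex[i],
      timePs = x@timePs[i])
}

#' Subset an ensemble by frame positions
#'
#' @param x an \linkS4class{Ensemble}.
#' @param idx integer vector of frame positions to keep (order preserved).
#' @return an \linkS4class{Ensemble} with the selected frames.
#' @export
subsetFrames <- function(x, idx) {
  stopifnot(is(x, "Ensemble"))
  idx <- as.integer(idx)
  if (length(idx) < 1) stop("cannot subset to an empty ensemble")
  if (any(idx < 1 | idx > nFrames(x))) stop("frame index out of range")
  new("Ensemble", topology = x@topology,
      coords = x@coords[, , idx, drop = FALSE],
      frameIndex = x@frameIndex[idx], timePs = x@timePs[idx],
      source = x@source[idx])
}

#' Pool several ensembles sharing a topology into one
#'
#' Frames are concatenated in the order given; each frame keeps (or is
#' assigned) a source-trajectory id so per-source cluster contributions can
#' be computed.
#'
#' @param ensembles a single \linkS4class{Ensemble} or a (possibly named)
#'   list of them; all must share the same atom roster.
#' @param sources optional character vector of source ids, one per ensemble;
#'   defaults to list names or \code{"ens<k>"}.
#' @return one pooled \linkS4class{Ensemble}.
#' @export
poolEnsembles <- function(ensembles, sources = NULL) {
  if (is(ensembles, "Ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1)
  if (is.null(sources)) {
    sources <- names(ensembles)
    if (is.null(sources)) sources <- paste0("ens", seq_along(ensembles))
    sources[sources == ""] <- paste0("ens", which(sources == ""))
  }
  keys <- atomKeys(ensembles[[1]])
  for (e in ensembles[-1])
    if (!identical(atomKeys(e), keys))
      stop("all ensembles must share the same atom roster")
  arr <- array(NA_real_, dim = c(length(keys), 3,
                                 sum(vapply(ensembles, nFrames, 1L))),
               dimnames = list(keys, NULL, NULL))
  off <- 0L
  src <- character(0); fi <- integer(0); tp <- numeric(0)
  for (k in seq_along(ensembles)) {
    e <- ensembles[[k]]
    nf <- nFrames(e)
    arr[, , off + seq_len(nf)] <- e@coords
    src <- c(src, rep(sources[k], nf))
    fi <- c(fi, e@frameIndex)
    tp <- c(tp, e@timePs)
    off <- off + nf
  }
  new("Ensemble", topology = ensembles[[1]]@topology, coords = arr,
      frameIndex = fi, timePs = tp, source = src)
}

#' Construct an atom selection
#'
#' @param resno integer vector of 1-based residue indices.
#' @param atom character vector of atom names (recycled against resno).
#' @return an \linkS4class{AtomSelection}.
#' @examples
#' atomSelection(rep(2:11, each = 3), c("N", "CA", "C"))
#' @export
atomSelection <- function(resno, atom) {
  n <- max(length(resno), length(atom))
  new("AtomSelection", resno = as.integer(rep_len(resno, n)),
      atom = as.character(rep_len(atom, n)))
}

#' Backbone N/CA/C selection over a residue range
#'
#' The selection used throughout for hairpin RMSD work: backbone N, CA and C
#' atoms of a residue window (by default residues 2--11, dropping the frayed
#' termini).
#'
#' @param residues integer vector of residue indices.
#' @return an \linkS4class{AtomSelection}.
#' @export
backboneSelection <- function(residues = 2:11) {
  atomSelection(rep(as.integer(residues), each = 3),
                rep(c("N", "CA", "C"), length(residues)))
}

setMethod("show", "PeptideTopology", function(object) {
  res <- object@residues
  mods <- ifelse(res$nAminated, "*", "")
  chir <- ifelse(res$chirality == "D", "d-", "")
  cat("PeptideTopology:", nrow(res), "residues,",
      nrow(object@atoms), "atoms\n")
  cat("  ", paste0(chir, res$name, mods, collapse = "-"), "\n", sep = "")
  if (any(res$nAminated))
    cat("  N-aminated sites (*):",
        paste(which(res$nAminated), collapse = ", "), "\n")
  cat("  N-terminus:", if (object@nTermProtonated) "NH3+" else "NH2",
      " C-terminus:", if (object@cTermAmide) "amide" else "free", "\n")
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", nFrames(object), "frames,",
      dim(object@coords)[1], "atoms,",
      nResidues(object), "residues\n")
  cat("  sources:", paste(unique(object@source), collapse = ", "), "\n")
})

setMethod("show", "TorsionSet", function(object) {
  cat("TorsionSet over", nResidues(object), "residues (degrees)\n")
  print(round(object@angles, 2))
})

setMethod("show", "HBondCriteria", function(object) {
  cat(sprintf("HBondCriteria [%s]: d(H..A) < %g nm, angle(D-H..A) > %g deg\n",
              object@preset, object@maxDist, object@minAngle))
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@sizes), "clusters over",
      length(object@membership), "frames\n")
  cat("  sizes:", paste(utils::head(object@sizes, 10), collapse = ", "),
      if (length(object@sizes) > 10) "..." else "", "\n")
})
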