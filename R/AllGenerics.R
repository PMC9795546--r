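#' Number of frames in an object
#' @param x an object with frames (e.g. an \linkS4class{Ensemble}).
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues described by an object
#' @param x a \linkS4class{PeptideTopology}, \linkS4class{Ensemble} or
#'   \linkS4class{TorsionSet}.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom keys ("<resno>:<atom>") of an object
#' @param x a topology, conformer or ensemble.
#' @return character vector of atom keys in roster order.
#' @export
setGeneric("atomKeys", function(x) standardGeneric("atomKeys"))

#' Torsion angle matrix of a TorsionSet
#' @param x a \linkS4class{TorsionSet}.
#' @return numeric matrix (residues x phi/psi/omega), degrees.
#' @export
setGeneric("torsionAngles", function(x) standardGeneric("torsionAngles"))

#' Cluster membership vector
#' @param x a \linkS4class{ClusterResult}.
#' @return integer cluster id per pooled frame.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' Cluster medoid frame indices
#' @param x a \linkS4class{ClusterResult}.
#' @return integer pooled frame index per cluster.
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' Cluster sizes
#' @param x a \linkS4class{ClusterResult}.
#' @return integer sizes, largest first.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' Per-source cluster contributions
#' @param x a \linkS4class{ClusterResult}.
#' @return numeric matrix (clusters x sources), percent of each source's
#'   frames in each cluster.
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))
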