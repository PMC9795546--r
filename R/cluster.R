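# Conformational clustering by the Daura greedy-medoid algorithm over
# backbone RMSD, with multi-trajectory pooling and per-source contributions.

# Pairwise superposition RMSD matrix over selected atoms. Coordinates are
# centered once; each pair then needs one 3x3 SVD.
.pairwiseRmsd <- function(centered) {
  n <- length(centered)
  natom <- nrow(centered[[1]])
  tr <- vapply(centered, function(m) sum(m * m), numeric(1))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    A <- centered[[i]]
    for (j in (i + 1):n) {
      B <- centered[[j]]
      C <- crossprod(B, A)
      s <- svd(C, nu = 0, nv = 0)$d
      sig <- if (det(C) < 0) sum(s[1:2]) - s[3] else sum(s)
      msd <- max(0, (tr[i] + tr[j] - 2 * sig) / natom)
      D[i, j] <- D[j, i] <- sqrt(msd)
    }
  }
  D
}

#' Daura conformational clustering
#'
#' Greedy medoid clustering: the frame with the most neighbours (pairwise
#' superposition RMSD strictly below the cutoff) becomes the first cluster's
#' medoid; it and its neighbours are removed and the procedure repeats until
#' no frames remain. Frames from all input ensembles are pooled, and each
#' cluster's composition is reported per source trajectory. Ties in
#' neighbour count are broken towards the lowest pooled frame index.
#'
#' @param ensembles an \linkS4class{Ensemble} or a (named) list of them,
#'   pooled with \code{\link{poolEnsembles}}.
#' @param selection \linkS4class{AtomSelection} for the RMSD fit; default
#'   backbone N/CA/C of residues 2--11.
#' @param cutoff RMSD cutoff in nm (default 0.1).
#' @return a \linkS4class{ClusterResult}.
#' @examples
#' top <- hairpinTopology()
#' st <- defaultStateTemplates(top, jitterSigma = 3)
#' gen <- generateMarkovEnsemble(markovSpec(st[c("folded_II", "unfolded")],
#'   diag(2), "folded_II", nFrames = 5, seed = 1), top)
#' dauraCluster(gen$ensemble, cutoff = 0.1)
#' @export
dauraCluster <- function(ensembles, selection = backboneSelection(),
                         cutoff = 0.1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  pooled <- if (is(ensembles, "Ensemble")) poolEnsembles(list(ensembles))
            else poolEnsembles(ensembles)
  n <- nFrames(pooled)
  idx <- .resolveSelection(pooled@coords[, , 1], selection)
  centered <- lapply(seq_len(n), function(i) {
    m <- pooled@coords[idx, , i]
    sweep(m, 2, colMeans(m))
  })
  D <- .pairwiseRmsd(centered)
  adj <- D < cutoff          # strict; diagonal TRUE (self-distance 0)
  remaining <- rep(TRUE, n)
  membership <- integer(n)
  medoids <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- rowSums(adj[, remaining, drop = FALSE])
    counts[!remaining] <- -1L
    med <- which.max(counts)   # lowest index wins ties
    members <- which(remaining & adj[med, ])
    membership[members] <- cl
    medoids[cl] <- med
    remaining[members] <- FALSE
  }
  sizes <- tabulate(membership, nbins = cl)
  srcs <- unique(pooled@source)
  contrib <- matrix(0, cl, length(srcs), dimnames = list(NULL, srcs))
  for (s in srcs) {
    tot <- sum(pooled@source == s)
    for (k in seq_len(cl))
      contrib[k, s] <- 100 * sum(membership == k & pooled@source == s) / tot
  }
  new("ClusterResult", membership = membership, medoids = medoids,
      sizes = sizes, source = pooled@source, contributions = contrib)
}

#' Hydrogen-bond signature of one cluster
#'
#' Hydrogen-bond populations computed over the member frames of a single
#' cluster -- the per-cluster bond inventory used to characterise folded,
#' misfolded and register-shifted conformations.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param clusterIndex 1-based cluster index (1 = largest).
#' @param ensembles the same ensemble(s) passed to
#'   \code{\link{dauraCluster}}.
#' @param criteria an \linkS4class{HBondCriteria}.
#' @param ... passed to \code{\link{hbondPopulations}} (e.g.
#'   \code{minReport}).
#' @return a hydrogen-bond population data.frame.
#' @export
clusterSignature <- function(result, clusterIndex, ensembles,
                             criteria = hbondCriteria("medium_strong"),
                             ...) {
  stopifnot(is(result, "ClusterResult"))
  k <- length(result@sizes)
  if (clusterIndex < 1 || clusterIndex > k)
    stop("cluster index out of range: ", clusterIndex, " (have ", k, ")")
  pooled <- if (is(ensembles, "Ensemble")) poolEnsembles(list(ensembles))
            else poolEnsembles(ensembles)
  members <- which(result@membership == clusterIndex)
  hbondPopulations(subsetFrames(pooled, members), criteria = criteria, ...)
}
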