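# Geometric hydrogen-bond detection and population analysis.

#' Hydrogen-bond criteria presets
#'
#' Two geometric definitions: a medium-strong hydrogen bond exists when the
#' hydrogen--acceptor distance is smaller than 0.25 nm and the
#' donor--hydrogen--acceptor angle is larger than 135 degrees; a weak
#' hydrogen bond when the distance is smaller than 0.32 nm and the angle
#' larger than 90 degrees. Inequalities are strict: exact-boundary geometry
#' counts as absent.
#'
#' @param preset \code{"medium_strong"}, \code{"weak"} or \code{"custom"}.
#' @param maxDist,minAngle used when \code{preset = "custom"}: maximum
#'   H--acceptor distance (nm) and minimum D-H-A angle (degrees).
#' @return an \linkS4class{HBondCriteria}.
#' @examples
#' hbondCriteria("medium_strong")
#' hbondCriteria("weak")
#' @export
hbondCriteria <- function(preset = c("medium_strong", "weak", "custom"),
                          maxDist = NULL, minAngle = NULL) {
  preset <- match.arg(preset)
  if (preset == "medium_strong") {
    maxDist <- 0.25; minAngle <- 135
  } else if (preset == "weak") {
    maxDist <- 0.32; minAngle <- 90
  } else if (is.null(maxDist) || is.null(minAngle)) {
    stop("custom criteria need maxDist and minAngle")
  }
  new("HBondCriteria", maxDist = maxDist, minAngle = minAngle,
      preset = preset)
}

# Donor label from the hydrogen atom name.
.donorLabel <- function(h) {
  c(H = "NH", H1 = "NH1", H2 = "NH2", H3 = "NH3",
    HB1 = "NBHB1", HB2 = "NBHB2")[h]
}

#' Enumerate candidate donor/acceptor pairs of a topology
#'
#' Donors: backbone amide N-H, the N-terminal NH3+ hydrogens (reported
#' separately as NH1/NH2/NH3), and the amination NB-HB1 / NB-HB2 hydrogens
#' (an N-aminated residue contributes no amide NH). Proline contributes no
#' amide donor. Acceptors: every backbone carbonyl O plus declared
#' pseudo-acceptors. Intraresidue pairs are excluded except the amination
#' NB-H to O(i) pair, whose C6 hydrogen bond is intraresidue by definition.
#'
#' @param topology a \linkS4class{PeptideTopology}.
#' @return data.frame with columns \code{donorRes}, \code{donorHeavy},
#'   \code{donorH}, \code{acceptorRes}, \code{acceptorAtom} and a display
#'   \code{label} like \code{"3NH-10O"}.
#' @export
enumeratePairs <- function(topology) {
  stopifnot(is(topology, "PeptideTopology"))
  res <- topology@residues
  n <- nrow(res)
  donors <- list()
  for (i in seq_len(n)) {
    if (i == 1L) {
      if (res$name[1] != "PRO") {
        hs <- if (topology@nTermProtonated) c("H1", "H2", "H3") else "H"
        donors[[length(donors) + 1]] <-
          data.frame(donorRes = i, donorHeavy = "N", donorH = hs)
      }
    } else if (res$nAminated[i]) {
      donors[[length(donors) + 1]] <-
        data.frame(donorRes = i, donorHeavy = "NB", donorH = c("HB1", "HB2"))
    } else if (res$name[i] != "PRO") {
      donors[[length(donors) + 1]] <-
        data.frame(donorRes = i, donorHeavy = "N", donorH = "H")
    }
  }
  donors <- do.call(rbind, donors)
  acc <- data.frame(acceptorRes = seq_len(n), acceptorAtom = "O")
  pa <- topology@pseudoAcceptors
  if (nrow(pa))
    acc <- rbind(acc, data.frame(acceptorRes = pa$resno, acceptorAtom = pa$atom))
  pairs <- merge(donors, acc, by = NULL)
  keep <- pairs$donorRes != pairs$acceptorRes | pairs$donorHeavy == "NB"
  pairs <- pairs[keep, , drop = FALSE]
  pairs$label <- paste0(pairs$donorRes, .donorLabel(pairs$donorH), "-",
                        pairs$acceptorRes,
                        ifelse(pairs$acceptorAtom == "O", "O",
                               pairs$acceptorAtom))
  pairs <- pairs[order(pairs$donorRes, pairs$donorH, pairs$acceptorRes,
                       pairs$acceptorAtom), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# Presence matrix (pairs x frames) for an ensemble under criteria.
.presenceMatrix <- function(ensemble, pairs, criteria) {
  keys <- atomKeys(ensemble)
  idxOf <- function(res, atom) {
    i <- match(.atomKey(res, atom), keys)
    if (anyNA(i))
      stop("missing atom in ensemble: ",
           .atomKey(res, atom)[is.na(i)][1])
    i
  }
  hI <- idxOf(pairs$donorRes, pairs$donorH)
  dI <- idxOf(pairs$donorRes, pairs$donorHeavy)
  aI <- idxOf(pairs$acceptorRes, pairs$acceptorAtom)
  arr <- ensemble@coords
  H <- arr[hI, , , drop = FALSE]
  D <- arr[dI, , , drop = FALSE]
  A <- arr[aI, , , drop = FALSE]
  dif <- H - A
  dist <- sqrt(dif[, 1, ]^2 + dif[, 2, ]^2 + dif[, 3, ]^2)
  v1 <- D - H; v2 <- A - H
  dot <- v1[, 1, ] * v2[, 1, ] + v1[, 2, ] * v2[, 2, ] + v1[, 3, ] * v2[, 3, ]
  n1 <- sqrt(v1[, 1, ]^2 + v1[, 2, ]^2 + v1[, 3, ]^2)
  n2 <- sqrt(v2[, 1, ]^2 + v2[, 2, ]^2 + v2[, 3, ]^2)
  ang <- .rad2deg(acos(pmin(1, pmax(-1, dot / (n1 * n2)))))
  pres <- dist < criteria@maxDist & ang > criteria@minAngle
  matrix(pres, nrow = nrow(pairs))
}

#' Detect hydrogen bonds in a single conformer
#'
#' A bond is present iff the hydrogen--acceptor distance is strictly below
#' the criterion distance and the donor--hydrogen--acceptor angle (measured
#' at the hydrogen) strictly above the criterion angle.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param pairs candidate pairs from \code{\link{enumeratePairs}} (or a
#'   compatible data.frame).
#' @param criteria an \linkS4class{HBondCriteria}.
#' @return the \code{pairs} data.frame with a logical \code{present} column.
#' @export
detectHBonds <- function(conformer, pairs,
                         criteria = hbondCriteria("medium_strong")) {
  stopifnot(is(conformer, "Conformer"))
  arr <- array(conformer@coords,
               dim = c(nrow(conformer@coords), 3, 1),
               dimnames = list(rownames(conformer@coords), NULL, NULL))
  # reuse the vectorised path through a 1-frame array
  fakeEns <- new("Ensemble", topology = .singleFrameTopologyStub(conformer),
                 coords = arr, frameIndex = 0L, timePs = NA_real_,
                 source = "conformer")
  pairs$present <- as.vector(.presenceMatrix(fakeEns, pairs, criteria))
  pairs
}

# Minimal topology stand-in so a bare conformer can flow through the
# array-based presence code; only the atom keys matter there.
.singleFrameTopologyStub <- function(conformer) {
  keys <- rownames(conformer@coords)
  parts <- strsplit(keys, ":", fixed = TRUE)
  resno <- as.integer(vapply(parts, `[`, "", 1))
  atom <- vapply(parts, `[`, "", 2)
  nres <- max(resno)
  new("PeptideTopology",
      residues = data.frame(name = rep("GLY", nres),
                            chirality = rep("achiral", nres),
                            nAminated = rep(FALSE, nres)),
      nTermProtonated = FALSE, cTermAmide = FALSE,
      atoms = data.frame(resno = resno, atom = atom),
      pseudoAcceptors = data.frame(resno = integer(0), atom = character(0)))
}

#' Hydrogen-bond populations over an ensemble
#'
#' Per-pair percentage of frames in which the bond is present. Optionally
#' filters out low-population rows (the reporting convention of keeping only
#' bonds above a population threshold) and can collapse the two hydrogens of
#' an amination NH2 donor into one row reporting the higher of the two
#' populations.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param pairs candidate pairs; defaults to
#'   \code{enumeratePairs(ensembleTopology(ensemble))}.
#' @param criteria an \linkS4class{HBondCriteria}.
#' @param minReport report threshold in percent; rows with population at or
#'   below it are dropped (use 0, the default, to keep everything).
#' @param combineNH2 collapse NBHB1/NBHB2 rows per (donor residue, acceptor)
#'   into a single row labelled \code{"<i>NBH2-..."} carrying the maximum of
#'   the two populations.
#' @return data.frame with columns \code{label}, \code{donor},
#'   \code{acceptor}, \code{criterion}, \code{population} (percent),
#'   \code{nPresent}, \code{nFrames}.
#' @export
hbondPopulations <- function(ensemble, pairs = NULL,
                             criteria = hbondCriteria("medium_strong"),
                             minReport = 0, combineNH2 = FALSE) {
  stopifnot(is(ensemble, "Ensemble"))
  if (nFrames(ensemble) < 1) stop("empty ensemble")
  if (is.null(pairs)) pairs <- enumeratePairs(ensemble@topology)
  pres <- .presenceMatrix(ensemble, pairs, criteria)
  nf <- ncol(pres)
  out <- data.frame(
    label = pairs$label,
    donor = paste0(pairs$donorRes, .donorLabel(pairs$donorH)),
    acceptor = paste0(pairs$acceptorRes, pairs$acceptorAtom),
    criterion = criteria@preset,
    population = 100 * rowSums(pres) / nf,
    nPresent = rowSums(pres),
    nFrames = nf)
  if (combineNH2) {
    isNB <- pairs$donorHeavy == "NB"
    if (any(isNB)) {
      nb <- out[isNB, , drop = FALSE]
      grp <- paste0(pairs$donorRes[isNB], "NBH2-", nb$acceptor)
      agg <- stats::aggregate(cbind(population, nPresent) ~ grp, data =
                                cbind(nb, grp = grp), FUN = max)
      comb <- data.frame(label = agg$grp,
                         donor = sub("-.*$", "", agg$grp),
                         acceptor = sub("^.*-", "", agg$grp),
                         criterion = criteria@preset,
                         population = agg$population,
                         nPresent = agg$nPresent, nFrames = nf)
      out <- rbind(out[!isNB, , drop = FALSE], comb)
    }
  }
  if (minReport > 0) out <- out[out$population > minReport, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' N-amination hydrogen-bond report: C6 and (i, i-2) bonds
#'
#' For every N-aminated residue i, reports the population of the
#' intraresidue C6 bond NBHB2(i)-O(i) (the NH2 hydrogen closing a
#' six-membered ring on the residue's own carbonyl) and, for i >= 3, of the
#' NBHB1(i)-O(i-2) bond. The weak criterion is the appropriate default for
#' these bonds.
#'
#' @param ensemble an \linkS4class{Ensemble} whose topology has N-aminated
#'   residues (an empty report is returned otherwise).
#' @param criteria an \linkS4class{HBondCriteria}; default weak.
#' @return data.frame with columns \code{label}, \code{class}
#'   (\code{"C6"} or \code{"i_minus_2"}), \code{population}, \code{nFrames}.
#' @export
aminationReport <- function(ensemble, criteria = hbondCriteria("weak")) {
  stopifnot(is(ensemble, "Ensemble"))
  top <- ensemble@topology
  sites <- which(top@residues$nAminated)
  empty <- data.frame(label = character(0), class = character(0),
                      population = numeric(0), nFrames = integer(0))
  if (!length(sites)) return(empty)
  rows <- list()
  for (i in sites) {
    rows[[length(rows) + 1]] <- data.frame(
      donorRes = i, donorHeavy = "NB", donorH = "HB2",
      acceptorRes = i, acceptorAtom = "O", class = "C6")
    if (i >= 3)
      rows[[length(rows) + 1]] <- data.frame(
        donorRes = i, donorHeavy = "NB", donorH = "HB1",
        acceptorRes = i - 2L, acceptorAtom = "O", class = "i_minus_2")
  }
  pairs <- do.call(rbind, rows)
  pairs$label <- paste0(pairs$donorRes, .donorLabel(pairs$donorH), "-",
                        pairs$acceptorRes, "O")
  pres <- .presenceMatrix(ensemble, pairs, criteria)
  data.frame(label = pairs$label, class = pairs$class,
             population = 100 * rowMeans(pres),
             nFrames = nFrames(ensemble))
}
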