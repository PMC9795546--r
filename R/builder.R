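# Internal-to-Cartesian chain construction (sequential natural-extension
# reference frame placement) and torsion measurement.

#' Construct a TorsionSet
#'
#' @param phi,psi,omega numeric vectors of backbone torsions in degrees, one
#'   per residue; \code{NA} marks undefined members (phi/omega of residue 1;
#'   psi of the last residue when there is no C-terminal amide nitrogen).
#'   \code{omega} defaults to 180 (trans) for all defined positions.
#' @return a \linkS4class{TorsionSet}.
#' @examples
#' torsionSet(phi = c(NA, -120), psi = c(130, 130))
#' @export
torsionSet <- function(phi, psi, omega = NULL) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (is.null(omega)) omega <- c(NA, rep(180, n - 1L))
  omega <- rep_len(omega, n)
  a <- cbind(phi = wrapAngle(phi), psi = wrapAngle(psi),
             omega = wrapAngle(omega))
  a[1, "phi"] <- NA
  a[1, "omega"] <- NA
  new("TorsionSet", angles = a)
}

#' Fully extended torsions (all angles 180 degrees)
#'
#' The standard extended-chain starting conformation: phi, psi and omega of
#' every residue set to 180.
#'
#' @param topology a \linkS4class{PeptideTopology}.
#' @return a \linkS4class{TorsionSet}.
#' @export
extendedTorsions <- function(topology) {
  n <- nResidues(topology)
  torsionSet(phi = rep(180, n), psi = rep(180, n), omega = rep(180, n))
}

# NeRF placement: D bonded to C, bond length r, angle(B,C,D) = theta,
# torsion(A,B,C,D) = tau (degrees, package sign convention).
.placeAtom <- function(A, B, C, r, theta, tau) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc * bc))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n * n))
  if (nn < 1e-12) stop("degenerate reference frame in chain extension")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  th <- theta * (pi / 180); ta <- tau * (pi / 180)
  C + r * (-cos(th) * bc + sin(th) * cos(ta) * m + sin(th) * sin(ta) * n)
}

# Row-wise NeRF over k placements: A, B, C are k x 3 matrices; r, theta,
# tau vectors of length k. Used to batch the per-residue decorations.
.placeAtomMat <- function(A, B, C, r, theta, tau) {
  bc <- C - B
  bc <- bc / .rowNorm(bc)
  n <- .cross(B - A, bc)
  nn <- .rowNorm(n)
  if (any(nn < 1e-12)) stop("degenerate reference frame in chain extension")
  n <- n / nn
  m <- .cross(n, bc)
  th <- theta * (pi / 180); ta <- tau * (pi / 180)
  C + r * (-cos(th) * bc + sin(th) * cos(ta) * m + sin(th) * sin(ta) * n)
}

#' Build Cartesian coordinates from backbone torsions
#'
#' Sequential internal-to-Cartesian chain extension with a fixed
#' internal-geometry table (standard peptide bond lengths and angles). The
#' measured backbone torsions of the result reproduce the input torsions to
#' numerical precision. N-aminated residues get the NB nitrogen placed
#' trigonally on the backbone N (replacing the amide hydrogen) and two HB
#' hydrogens completing a trigonal NH2; HB2 is oriented towards the
#' intraresidue carbonyl (the C6 contact) and HB1 towards the (i-2) carbonyl
#' side.
#'
#' @param topology a \linkS4class{PeptideTopology}.
#' @param torsions a \linkS4class{TorsionSet} covering all residues.
#' @param frameIndex,timePs frame metadata for the returned conformer.
#' @return a \linkS4class{Conformer} containing every roster atom.
#' @examples
#' top <- hairpinTopology()
#' conf <- buildConformer(top, extendedTorsions(top))
#' @export
buildConformer <- function(topology, torsions, frameIndex = 0L, timePs = NA_real_) {
  stopifnot(is(topology, "PeptideTopology"), is(torsions, "TorsionSet"))
  n <- nResidues(topology)
  if (nResidues(torsions) != n)
    stop("torsions must cover all ", n, " residues")
  res <- topology@residues
  tor <- torsions@angles
  g <- .GEOM
  keys <- atomKeys(topology)
  coords <- matrix(NA_real_, length(keys), 3, dimnames = list(keys, NULL))
  # fast (resno, atom) -> row lookup over the fixed backbone atom slots
  slots <- c("N", "H", "H1", "H2", "H3", "NB", "HB1", "HB2",
             "CA", "CB", "C", "O", "NT")
  idxTab <- matrix(NA_integer_, n, length(slots),
                   dimnames = list(NULL, slots))
  slotOf <- match(topology@atoms$atom, slots)
  backbone <- !is.na(slotOf)
  idxTab[cbind(topology@atoms$resno[backbone], slotOf[backbone])] <-
    which(backbone)
  put <- function(resno, atom, xyz) coords[idxTab[resno, atom], ] <<- xyz
  get1 <- function(resno, atom) coords[idxTab[resno, atom], ]

  # backbone: N, CA, C of residue 1 define the initial frame; the chain is
  # then grown sequentially (psi -> next N, omega -> next CA, phi -> next C)
  aN <- c(0, 0, 0)
  aCA <- c(g$b["NCA"], 0, 0)
  th <- .deg2rad(g$a["NCAC"])
  aC <- aCA + g$b["CAC"] * c(-cos(th), sin(th), 0)
  put(1, "N", aN); put(1, "CA", aCA); put(1, "C", aC)
  for (i in seq_len(n)) {
    N <- get1(i, "N"); CA <- get1(i, "CA"); C <- get1(i, "C")
    psi <- tor[i, "psi"]
    if (i < n || topology@cTermAmide) {
      if (is.na(psi)) psi <- 180
      nextN <- .placeAtom(N, CA, C, g$b["CN"], g$a["CACN"], psi)
      put(i + ifelse(i < n, 1L, 0L), if (i < n) "N" else "NT", nextN)
    }
    if (i < n) {
      om <- tor[i + 1, "omega"]; if (is.na(om)) om <- 180
      nextCA <- .placeAtom(CA, C, nextN, g$b["NCA"], g$a["CNCA"], om)
      phi <- tor[i + 1, "phi"]; if (is.na(phi)) phi <- 180
      nextC <- .placeAtom(C, nextN, nextCA, g$b["CAC"], g$a["NCAC"], phi)
      put(i + 1, "CA", nextCA); put(i + 1, "C", nextC)
    }
  }

  # decorations are batched row-wise now that the backbone frame exists
  sl <- function(s) match(s, slots)
  rowsOf <- function(resno, slot) coords[idxTab[cbind(resno, sl(slot))], ,
                                         drop = FALSE]
  bbN <- rowsOf(1:n, "N"); bbCA <- rowsOf(1:n, "CA"); bbC <- rowsOf(1:n, "C")
  psiAll <- ifelse(is.na(tor[, "psi"]), 180, tor[, "psi"])
  omAll <- ifelse(is.na(tor[, "omega"]), 180, tor[, "omega"])
  # carbonyl O anti to the following nitrogen
  coords[idxTab[cbind(1:n, sl("O"))], ] <-
    .placeAtomMat(bbN, bbCA, bbC, g$b["CO"], g$a["CACO"],
                  wrapAngle(psiAll + 180))
  # amide hydrogens / amination NB anti to CA(i) across the peptide N
  hTau <- wrapAngle(omAll + 180)
  ii <- if (n > 1) 2:n else integer(0)
  isAm <- res$nAminated[ii]
  isH <- !isAm & res$name[ii] != "PRO"
  if (any(isH)) {
    ih <- ii[isH]
    coords[idxTab[cbind(ih, sl("H"))], ] <-
      .placeAtomMat(bbCA[ih - 1, , drop = FALSE], bbC[ih - 1, , drop = FALSE],
                    bbN[ih, , drop = FALSE], g$b["NH"], g$a["CNH"], hTau[ih])
  }
  if (any(isAm)) {
    ia <- ii[isAm]
    NB <- .placeAtomMat(bbCA[ia - 1, , drop = FALSE],
                        bbC[ia - 1, , drop = FALSE],
                        bbN[ia, , drop = FALSE],
                        g$b["NNB"], g$a["CNNB"], hTau[ia])
    coords[idxTab[cbind(ia, sl("NB"))], ] <- NB
    # trigonal NH2: HB2 at the frozen amine-plane torsion, HB1 opposite
    coords[idxTab[cbind(ia, sl("HB2"))], ] <-
      .placeAtomMat(bbC[ia - 1, , drop = FALSE], bbN[ia, , drop = FALSE],
                    NB, g$b["NBHB"], g$a["NNBHB"], g$tauAmine)
    coords[idxTab[cbind(ia, sl("HB1"))], ] <-
      .placeAtomMat(bbC[ia - 1, , drop = FALSE], bbN[ia, , drop = FALSE],
                    NB, g$b["NBHB"], g$a["NNBHB"],
                    wrapAngle(g$tauAmine + 180))
  }
  # N-terminal hydrogens
  if (res$name[1] != "PRO") {
    if (topology@nTermProtonated) {
      coords[idxTab[cbind(1, sl(c("H1", "H2", "H3")))], ] <-
        .placeAtomMat(rbind(aC, aC, aC), rbind(aCA, aCA, aCA),
                      rbind(aN, aN, aN), g$b["NH"], g$a["CANH3"],
                      c(60, 180, -60))
    } else {
      put(1, "H", .placeAtom(aC, aCA, aN, g$b["NH"], g$a["CANH3"], 180))
    }
  }
  # CB off CA; torsion N-C-CA-CB fixes the chirality (sign flips for D)
  icb <- which(res$name != "GLY")
  if (length(icb)) {
    tauCB <- ifelse(res$chirality[icb] == "D", -g$tauCB, g$tauCB)
    coords[idxTab[cbind(icb, sl("CB"))], ] <-
      .placeAtomMat(bbN[icb, , drop = FALSE], bbC[icb, , drop = FALSE],
                    bbCA[icb, , drop = FALSE], g$b["CACB"], g$a["CCACB"],
                    tauCB)
  }

  # pseudo-acceptor stubs along the CA->CB direction
  pa <- topology@pseudoAcceptors
  if (nrow(pa)) {
    for (k in seq_len(nrow(pa))) {
      CA <- get1(pa$resno[k], "CA"); CB <- get1(pa$resno[k], "CB")
      row <- match(.atomKey(pa$resno[k], pa$atom[k]), keys)
      coords[row, ] <- CA + 2.5 * (CB - CA)
    }
  }

  if (anyNA(coords)) stop("internal error: unplaced atoms in build")
  new("Conformer", coords = coords, frameIndex = as.integer(frameIndex),
      timePs = as.numeric(timePs))
}

#' Measure backbone torsions of a conformer
#'
#' phi(i) over C(i-1)-N(i)-CA(i)-C(i); psi(i) over N(i)-CA(i)-C(i)-N(i+1)
#' (the C-terminal amide nitrogen NT serves as N(n+1) when present);
#' omega(i) over CA(i-1)-C(i-1)-N(i)-CA(i). Undefined terminal members are
#' \code{NA}.
#'
#' @param topology a \linkS4class{PeptideTopology}.
#' @param conformer a \linkS4class{Conformer} holding all backbone atoms.
#' @return a \linkS4class{TorsionSet}.
#' @export
measureTorsions <- function(topology, conformer) {
  n <- nResidues(topology)
  co <- if (is(conformer, "Conformer")) conformer@coords else conformer
  rows <- function(resno, atom) {
    key <- .atomKey(resno, atom)
    idx <- match(key, rownames(co))
    if (anyNA(idx)) stop("missing backbone atom: ", key[is.na(idx)][1])
    co[idx, , drop = FALSE]
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n > 1) {
    i <- 2:n
    phi[i] <- .dihedralMat(rows(i - 1, "C"), rows(i, "N"),
                           rows(i, "CA"), rows(i, "C"))
    omega[i] <- .dihedralMat(rows(i - 1, "CA"), rows(i - 1, "C"),
                             rows(i, "N"), rows(i, "CA"))
    psi[1:(n - 1)] <- .dihedralMat(rows(1:(n - 1), "N"), rows(1:(n - 1), "CA"),
                                   rows(1:(n - 1), "C"), rows(2:n, "N"))
  }
  if (.atomKey(n, "NT") %in% rownames(co))
    psi[n] <- .dihedralMat(rows(n, "N"), rows(n, "CA"), rows(n, "C"),
                           rows(n, "NT"))
  new("TorsionSet", angles = cbind(phi = phi, psi = psi, omega = omega))
}

#' Backbone torsion series over an ensemble
#'
#' Vectorised \code{\link{measureTorsions}} across frames.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @return a numeric array (residues x \{phi, psi, omega\} x frames), degrees.
#' @export
torsionSeries <- function(ensemble) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nResidues(ensemble)
  keys <- atomKeys(ensemble)
  arr <- ensemble@coords
  nf <- nFrames(ensemble)
  ser <- function(resno, atom) {
    idx <- match(.atomKey(resno, atom), keys)
    if (is.na(idx)) stop("missing backbone atom: ", .atomKey(resno, atom))
    m <- t(arr[idx, , , drop = TRUE])
    if (nf == 1L) m <- matrix(arr[idx, , 1], 1, 3)
    m
  }
  out <- array(NA_real_, dim = c(n, 3, nf),
               dimnames = list(NULL, c("phi", "psi", "omega"), NULL))
  for (i in seq_len(n)) {
    if (i > 1) {
      out[i, "phi", ] <- .dihedralMat(ser(i - 1, "C"), ser(i, "N"),
                                      ser(i, "CA"), ser(i, "C"))
      out[i, "omega", ] <- .dihedralMat(ser(i - 1, "CA"), ser(i - 1, "C"),
                                        ser(i, "N"), ser(i, "CA"))
    }
    nxtKey <- if (i < n) .atomKey(i + 1, "N") else .atomKey(n, "NT")
    if (nxtKey %in% keys)
      out[i, "psi", ] <- .dihedralMat(ser(i, "N"), ser(i, "CA"),
                                      ser(i, "C"),
                                      ser(if (i < n) i + 1 else n,
                                          if (i < n) "N" else "NT"))
  }
  out
}
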