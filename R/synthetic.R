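# Synthetic conformer ensembles with planted conformational-state structure:
# folded type I'/II' hairpins, frayed and register-shifted templates, and a
# Markov chain over state templates with Gaussian torsion jitter.

#' Canonical beta-turn centers
#'
#' (phi, psi) of turn residues i+1 and i+2: type I' is (60, 30) / (90, 0);
#' type II' is (60, -120) / (-80, 0).
#'
#' @return named list with entries \code{"I'"} and \code{"II'"}, each a
#'   2 x 2 matrix (rows i+1, i+2; columns phi, psi).
#' @export
turnCanon <- function() {
  list("I'" = matrix(c(60, 30, 90, 0), 2, 2, byrow = TRUE,
                     dimnames = list(c("i1", "i2"), c("phi", "psi"))),
       "II'" = matrix(c(60, -120, -80, 0), 2, 2, byrow = TRUE,
                      dimnames = list(c("i1", "i2"), c("phi", "psi"))))
}

# Strand backbone torsions for the idealised hairpin templates: per-residue
# antiparallel-beta values (positions 1-5 and 8-12; the turn overwrites its
# own two residues). Tuned once against the builder's fixed internal
# geometry so that, on the noiseless type II' template, all five
# cross-strand hydrogen bonds (3NH-10O, 5NH-8O, 8NH-5O, 10NH-3O, 12NH-1O)
# form under the weak criterion with the turn-flanking 8NH-5O medium-strong,
# the type I' template keeps 3NH-10O, 5NH-8O and 10NH-3O under the weak
# criterion, and the intraresidue C6 contact of N-aminated residues closes
# in the strand conformation; frozen afterwards as the versioned template.
# Interior strand residues stay in the beta region.
.STRAND <- list(
  resno = c(1:5, 8:12),
  phi = c(-47.62, -101.19, -101.02, -131.00, -171.84,
          -89.41, -141.86, -158.42, -108.82, -44.50),
  psi = c(170.79, 110.34, 118.02, 99.75, 119.16,
          114.27, 97.48, 137.03, 98.78, 178.15))

#' Idealised hairpin torsions with a chosen turn type and register
#'
#' Strand residues get antiparallel-beta torsions (frozen template values);
#' the two turn residues get the canonical type I' or II' beta-turn.
#' \code{registerShift = +1} moves the turn one residue towards the
#' N-terminus (turn at residues 5,6 instead of 6,7), reproducing the
#' register-shifted misfold in which the 7NH-4O hydrogen bond replaces
#' 8NH-5O; \code{-1} shifts the other way.
#'
#' @param topology the 12-residue hairpin topology
#'   (\code{\link{hairpinTopology}} family).
#' @param turnType \code{"I'"} or \code{"II'"}.
#' @param registerShift integer in \{-1, 0, 1\}.
#' @return a \linkS4class{TorsionSet}.
#' @examples
#' hairpinTorsions(hairpinTopology(), "II'")
#' @export
hairpinTorsions <- function(topology, turnType = c("II'", "I'"),
                            registerShift = 0L) {
  turnType <- match.arg(turnType)
  n <- nResidues(topology)
  if (n != 12)
    stop("hairpin templates are defined for the 12-residue topology")
  if (!registerShift %in% -1:1)
    stop("unsupported register shift: ", registerShift,
         " (must be -1, 0 or +1)")
  t1 <- 6L - as.integer(registerShift)   # turn residue i+1
  t2 <- t1 + 1L
  s <- .STRAND
  phi <- psi <- rep(NA_real_, n)
  phi[s$resno] <- s$phi; psi[s$resno] <- s$psi
  # a shifted turn leaves one of residues 6/7 as strand: take the nearest
  # template value
  for (i in which(is.na(phi))) {
    k <- which.min(abs(s$resno - i))
    phi[i] <- s$phi[k]; psi[i] <- s$psi[k]
  }
  canon <- turnCanon()[[turnType]]
  phi[t1] <- canon["i1", "phi"]; psi[t1] <- canon["i1", "psi"]
  phi[t2] <- canon["i2", "phi"]; psi[t2] <- canon["i2", "psi"]
  torsionSet(phi = phi, psi = psi, omega = rep(180, n))
}

#' Construct a conformational state template
#'
#' @param label state label.
#' @param torsions noiseless \linkS4class{TorsionSet} of the state.
#' @param jitterSigma Gaussian torsion jitter (degrees) applied per frame.
#' @return a \linkS4class{StateTemplate}.
#' @export
stateTemplate <- function(label, torsions, jitterSigma = 10) {
  new("StateTemplate", label = label, torsions = torsions,
      jitterSigma = as.numeric(jitterSigma))
}

#' Standard state templates for the hairpin study conditions
#'
#' Five states: folded type I' and type II' hairpins, a frayed state
#' (folded II' core with residues 1, 2, 11, 12 re-drawn uniformly -- terminal
#' fraying), the register-shifted (+1) misfold, and an unfolded state
#' (extended backbone with a large jitter).
#'
#' @param topology the 12-residue hairpin topology.
#' @param jitterSigma jitter (degrees) for the structured states; the
#'   unfolded state uses \code{unfoldedSigma}.
#' @param unfoldedSigma jitter for the unfolded state (degrees).
#' @param fraySeed seed for the uniform re-draw of the frayed template's
#'   terminal torsions (frozen draw; deterministic).
#' @return named list of \linkS4class{StateTemplate} objects with labels
#'   \code{folded_I}, \code{folded_II}, \code{frayed}, \code{misfold},
#'   \code{unfolded}.
#' @export
defaultStateTemplates <- function(topology, jitterSigma = 10,
                                  unfoldedSigma = 60, fraySeed = 20261001L) {
  tI <- hairpinTorsions(topology, "I'")
  tII <- hairpinTorsions(topology, "II'")
  fr <- tII@angles
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(fraySeed)
  for (i in c(1L, 2L, 11L, 12L)) {
    if (!is.na(fr[i, "phi"])) fr[i, "phi"] <- stats::runif(1, -180, 180)
    fr[i, "psi"] <- stats::runif(1, -180, 180)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  frayed <- new("TorsionSet", angles = fr)
  list(
    folded_I = stateTemplate("folded_I", tI, jitterSigma),
    folded_II = stateTemplate("folded_II", tII, jitterSigma),
    frayed = stateTemplate("frayed", frayed, jitterSigma),
    misfold = stateTemplate("misfold",
                            hairpinTorsions(topology, "II'", registerShift = 1L),
                            jitterSigma),
    unfolded = stateTemplate("unfolded", extendedTorsions(topology),
                             unfoldedSigma)
  )
}

#' Construct a Markov specification
#'
#' @param states list of \linkS4class{StateTemplate} objects.
#' @param transitionMatrix row-stochastic matrix over the states (in list
#'   order); rows must sum to 1 within 1e-12.
#' @param initialState label of the starting state.
#' @param nFrames number of frames.
#' @param seed integer RNG seed; the generated ensemble is a deterministic
#'   function of the spec.
#' @return a \linkS4class{MarkovSpec}.
#' @export
markovSpec <- function(states, transitionMatrix, initialState, nFrames, seed) {
  new("MarkovSpec", states = states,
      transitionMatrix = transitionMatrix,
      initialState = initialState, nFrames = as.integer(nFrames),
      seed = as.integer(seed))
}

#' Generate a synthetic conformer ensemble from a Markov state chain
#'
#' Draws a state path from the Markov chain, jitters each frame's template
#' torsions with independent Gaussian noise (sd = the state's jitterSigma;
#' undefined torsions stay undefined) and builds Cartesian coordinates for
#' every frame. The true state path is returned so downstream statistics can
#' be validated by parameter recovery.
#'
#' @param spec a \linkS4class{MarkovSpec}.
#' @param topology the \linkS4class{PeptideTopology} to build against.
#' @param source source-trajectory id stored on the frames.
#' @param dtPs time step between frames (ps) for the time stamps.
#' @return list with \code{ensemble} (an \linkS4class{Ensemble}) and
#'   \code{statePath} (character vector of true per-frame state labels).
#' @examples
#' top <- hairpinTopology()
#' st <- defaultStateTemplates(top)
#' sp <- markovSpec(st[c("folded_II", "unfolded")],
#'                  matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
#'                  "folded_II", nFrames = 10, seed = 1)
#' gen <- generateMarkovEnsemble(sp, top)
#' @export
generateMarkovEnsemble <- function(spec, topology, source = "markov",
                                   dtPs = 5) {
  stopifnot(is(spec, "MarkovSpec"))
  labs <- vapply(spec@states, function(s) s@label, character(1))
  k <- length(labs)
  P <- spec@transitionMatrix
  nf <- spec@nFrames
  set.seed(spec@seed)
  path <- integer(nf)
  path[1] <- match(spec@initialState, labs)
  if (nf > 1)
    for (t in 2:nf)
      path[t] <- sample.int(k, 1L, prob = P[path[t - 1], ])
  keys <- atomKeys(topology)
  arr <- array(NA_real_, dim = c(length(keys), 3, nf),
               dimnames = list(keys, NULL, NULL))
  for (t in seq_len(nf)) {
    st <- spec@states[[path[t]]]
    a <- st@torsions@angles
    if (st@jitterSigma > 0) {
      def <- !is.na(a)
      a[def] <- wrapAngle(a[def] + stats::rnorm(sum(def), 0, st@jitterSigma))
    }
    conf <- buildConformer(topology, new("TorsionSet", angles = a),
                           frameIndex = t - 1L, timePs = (t - 1) * dtPs)
    arr[, , t] <- conf@coords
  }
  ens <- new("Ensemble", topology = topology, coords = arr,
             frameIndex = seq_len(nf) - 1L,
             timePs = (seq_len(nf) - 1) * dtPs,
             source = rep(source, nf))
  list(ensemble = ens, statePath = labs[path])
}

#' Derive a self-consistent NOE restraint table from an ensemble
#'
#' For each atom pair the upper bound is set to the ensemble's
#' r^-6-averaged effective distance plus \code{slack}, so that by
#' construction the ensemble itself violates none of the restraints (for
#' positive slack).
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param pairs data.frame with columns \code{resA}, \code{atomA},
#'   \code{resB}, \code{atomB} (atom names may carry a trailing \code{*}
#'   wildcard for pseudoatom groups).
#' @param slack bound slack in nm (may be negative, for testing).
#' @return a restraint data.frame (\code{resA}, \code{atomA}, \code{resB},
#'   \code{atomB}, \code{upper}, \code{type}) suitable for
#'   \code{\link{checkViolations}}.
#' @export
makeNoeFixture <- function(ensemble, pairs, slack = 0.05) {
  stopifnot(is(ensemble, "Ensemble"))
  if (nFrames(ensemble) < 1) stop("empty ensemble")
  upper <- vapply(seq_len(nrow(pairs)), function(i)
    effectiveDistance(ensemble,
                      c(pairs$resA[i], pairs$atomA[i]),
                      c(pairs$resB[i], pairs$atomB[i])), numeric(1))
  data.frame(resA = as.integer(pairs$resA), atomA = pairs$atomA,
             resB = as.integer(pairs$resB), atomB = pairs$atomB,
             upper = upper + slack, type = "none")
}
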