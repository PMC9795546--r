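# Small fixtures built in code at test time.

hairpinTop <- function(aminated = integer(0)) hairpinTopology(aminated)

# A tiny ensemble of n jittered folded frames (fast to build).
smallFoldedEnsemble <- function(n = 5, sigma = 5, seed = 42,
                                topology = hairpinTopology()) {
  st <- list(stateTemplate("folded_II",
                           hairpinTorsions(topology, "II'"), sigma))
  gen <- generateMarkovEnsemble(
    markovSpec(st, matrix(1, 1, 1), "folded_II", nFrames = n, seed = seed),
    topology)
  gen$ensemble
}

# Ensemble wrapping explicit conformers (list of coordinate matrices).
ensembleFromCoords <- function(topology, coordList) {
  keys <- atomKeys(topology)
  arr <- array(NA_real_, c(length(keys), 3, length(coordList)),
               dimnames = list(keys, NULL, NULL))
  for (i in seq_along(coordList)) arr[, , i] <- coordList[[i]][keys, ]
  new("Ensemble", topology = topology, coords = arr,
      frameIndex = seq_along(coordList) - 1L,
      timePs = rep(NA_real_, length(coordList)),
      source = rep("test", length(coordList)))
}

# Two-state folded/unfolded Markov generator used by several suites.
twoStateGen <- function(pFold, nFrames, seed, sigma = 8,
                        topology = hairpinTopology()) {
  st <- defaultStateTemplates(topology, jitterSigma = sigma)
  P <- matrix(c(pFold, 1 - pFold, pFold, 1 - pFold), 2, 2, byrow = TRUE)
  generateMarkovEnsemble(
    markovSpec(st[c("folded_II", "unfolded")], P, "folded_II",
               nFrames = nFrames, seed = seed),
    topology)
}
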