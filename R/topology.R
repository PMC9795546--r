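# Peptide topology declaration: sequence, chirality, N-amination, atom roster.

.SUPPORTED_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                         "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "ORN",
                         "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Derive the full atom roster for a residue table.
.makeRoster <- function(res, nTermProtonated, cTermAmide, pseudoAcceptors) {
  n <- nrow(res)
  rows <- list()
  for (i in seq_len(n)) {
    atoms <- "N"
    if (i == 1L) {
      if (res$name[i] != "PRO")
        atoms <- c(atoms, if (nTermProtonated) c("H1", "H2", "H3") else "H")
    } else if (res$nAminated[i]) {
      atoms <- c(atoms, "NB", "HB1", "HB2")
    } else if (res$name[i] != "PRO") {
      atoms <- c(atoms, "H")
    }
    atoms <- c(atoms, "CA")
    if (res$name[i] != "GLY") atoms <- c(atoms, "CB")
    atoms <- c(atoms, "C", "O")
    if (i == n && cTermAmide) atoms <- c(atoms, "NT")
    rows[[i]] <- data.frame(resno = i, atom = atoms)
  }
  roster <- do.call(rbind, rows)
  if (nrow(pseudoAcceptors)) {
    if (any(res$name[pseudoAcceptors$resno] == "GLY"))
      stop("pseudo-acceptors need a CB direction; glycine has none")
    roster <- rbind(roster, data.frame(resno = pseudoAcceptors$resno,
                                       atom = pseudoAcceptors$atom))
  }
  rownames(roster) <- NULL
  roster
}

#' Declare a peptide topology
#'
#' @param sequence character vector of 3-letter residue codes (e.g.
#'   \code{c("ARG","TYR",...)}); ornithine (\code{"ORN"}) is accepted and
#'   treated as lysine-like at backbone level.
#' @param chirality "L", "D" or "achiral" per residue; glycine is forced to
#'   "achiral". A d-proline is declared as \code{name = "PRO"},
#'   \code{chirality = "D"}.
#' @param nAminated logical per residue: \code{TRUE} replaces the backbone
#'   amide hydrogen with an NH2 group (atoms NB, HB1, HB2).
#' @param nTermProtonated protonated N-terminus (NH3+, hydrogens H1/H2/H3).
#' @param cTermAmide amide C-terminus: adds the amide nitrogen \code{NT}
#'   (so psi of the final residue is defined); its hydrogens are not
#'   modelled and it is not a hydrogen-bond donor.
#' @param pseudoAcceptors optional data.frame (\code{resno}, \code{atom})
#'   declaring side-chain acceptor stubs placed along the CA->CB direction.
#' @return a \linkS4class{PeptideTopology}.
#' @examples
#' peptideTopology(c("GLY", "ALA"), chirality = c("achiral", "L"))
#' @export
peptideTopology <- function(sequence,
                            chirality = rep("L", length(sequence)),
                            nAminated = rep(FALSE, length(sequence)),
                            nTermProtonated = TRUE,
                            cTermAmide = TRUE,
                            pseudoAcceptors = NULL) {
  sequence <- toupper(sequence)
  unknown <- setdiff(sequence, .SUPPORTED_RESIDUES)
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(.SUPPORTED_RESIDUES, collapse = ", "))
  chirality[sequence == "GLY"] <- "achiral"
  res <- data.frame(name = sequence,
                    chirality = as.character(chirality),
                    nAminated = as.logical(nAminated))
  if (is.null(pseudoAcceptors))
    pseudoAcceptors <- data.frame(resno = integer(0), atom = character(0))
  roster <- .makeRoster(res, nTermProtonated, cTermAmide, pseudoAcceptors)
  new("PeptideTopology", residues = res,
      nTermProtonated = nTermProtonated, cTermAmide = cTermAmide,
      atoms = roster, pseudoAcceptors = pseudoAcceptors)
}

#' The 12-residue model beta-hairpin topology
#'
#' The Gellman-type hairpin H-Arg-Tyr-Val-Glu-Val-dPro-Gly-Orn-Lys-Ile-Leu-
#' Gln-NH2: a d-Pro6-Gly7 turn flanked by two antiparallel strands, with a
#' protonated N-terminus and an amide C-terminus. Backbone N-amination sites
#' can be switched on per residue.
#'
#' @param aminated integer vector of residue indices to N-aminate (e.g.
#'   \code{c(2, 4, 9, 11)} for the tetra-aminated variant); residue 1 and
#'   proline cannot be aminated.
#' @param pseudoAcceptors optional side-chain acceptor stubs, as in
#'   \code{\link{peptideTopology}}.
#' @return a \linkS4class{PeptideTopology}.
#' @examples
#' hairpinTopology()
#' hairpinTopology(aminated = c(2, 4, 9, 11))
#' @export
hairpinTopology <- function(aminated = integer(0), pseudoAcceptors = NULL) {
  seqs <- c("ARG", "TYR", "VAL", "GLU", "VAL", "PRO",
            "GLY", "ORN", "LYS", "ILE", "LEU", "GLN")
  chir <- rep("L", 12)
  chir[6] <- "D"
  amin <- rep(FALSE, 12)
  if (length(aminated)) {
    if (any(aminated %in% c(1L, 6L)))
      stop("residues 1 (NH3+) and 6 (proline) cannot be N-aminated")
    amin[aminated] <- TRUE
  }
  peptideTopology(seqs, chirality = chir, nAminated = amin,
                  nTermProtonated = TRUE, cTermAmide = TRUE,
                  pseudoAcceptors = pseudoAcceptors)
}

#' Read a peptide topology from a YAML config file
#'
#' Schema: a mapping with \code{residues} (a list of entries with
#' \code{name}, optional \code{chirality}, optional \code{aminated}),
#' optional booleans \code{n_term_protonated} and \code{c_term_amide}, and
#' an optional \code{pseudo_acceptors} list of \code{\{resno, atom\}}
#' entries. A d-proline is written as \code{name: PRO, chirality: D}.
#'
#' @param path path to the YAML file.
#' @return a \linkS4class{PeptideTopology}.
#' @export
readTopologyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$residues)) stop("topology config must list residues")
  name <- vapply(cfg$residues, function(r) toupper(r$name), character(1))
  chir <- vapply(cfg$residues, function(r)
    if (is.null(r$chirality)) "L" else r$chirality, character(1))
  amin <- vapply(cfg$residues, function(r)
    isTRUE(r$aminated), logical(1))
  pa <- NULL
  if (!is.null(cfg$pseudo_acceptors))
    pa <- data.frame(
      resno = vapply(cfg$pseudo_acceptors, function(p) as.integer(p$resno), 1L),
      atom = vapply(cfg$pseudo_acceptors, function(p) p$atom, character(1)))
  peptideTopology(name, chirality = chir, nAminated = amin,
                  nTermProtonated = !isFALSE(cfg$n_term_protonated),
                  cTermAmide = !isFALSE(cfg$c_term_amide),
                  pseudoAcceptors = pa)
}
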