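# Multi-model PDB reading/writing (via bio3d, with nm <-> Angstrom
# conversion at the boundary) and the end-to-end analysis pipeline.

# Documented alias table applied to incoming PDB atom names.
.ATOM_ALIASES <- c(HN = "H", "1H" = "H1", "2H" = "H2", "3H" = "H3",
                   HT1 = "H1", HT2 = "H2", HT3 = "H3")

#' Read a conformer ensemble from a (multi-model) PDB file
#'
#' One conformer per MODEL record (a single-model file yields an ensemble of
#' one). Atom names are mapped through a small alias table (HN -> H,
#' 1H/HT1 -> H1, ...); coordinates are converted from Angstrom to nm.
#' Every atom of the topology roster must be present in every model.
#'
#' @param path PDB file path.
#' @param topology the \linkS4class{PeptideTopology} the file must satisfy.
#' @param source source-trajectory id stored on the frames (default: file
#'   base name).
#' @return an \linkS4class{Ensemble}.
#' @export
readEnsemble <- function(path, topology, source = NULL) {
  if (is.null(source)) source <- sub("\\.pdb$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atomName <- pdb$atom$elety
  mapped <- .ATOM_ALIASES[atomName]
  atomName[!is.na(mapped)] <- mapped[!is.na(mapped)]
  fileKey <- .atomKey(pdb$atom$resno, atomName)
  wantKey <- atomKeys(topology)
  idx <- match(wantKey, fileKey)
  if (anyNA(idx))
    stop("PDB file is missing required atom(s): ",
         paste(utils::head(wantKey[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) " ..." else "")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  arr <- array(NA_real_, dim = c(length(wantKey), 3, nf),
               dimnames = list(wantKey, NULL, NULL))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    arr[, , f] <- m[idx, , drop = FALSE] / 10   # Angstrom -> nm
  }
  new("Ensemble", topology = topology, coords = arr,
      frameIndex = seq_len(nf) - 1L, timePs = rep(NA_real_, nf),
      source = rep(source, nf))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom; one MODEL per frame.
#'
#' @param ensemble an \linkS4class{Ensemble} (or single
#'   \linkS4class{Conformer} plus \code{topology}).
#' @param path output path.
#' @param topology required when writing a bare conformer.
#' @return the path, invisibly.
#' @export
writeEnsemble <- function(ensemble, path, topology = NULL) {
  if (is(ensemble, "Conformer")) {
    if (is.null(topology)) stop("writing a Conformer requires its topology")
    arr <- array(ensemble@coords, dim = c(nrow(ensemble@coords), 3, 1),
                 dimnames = list(rownames(ensemble@coords), NULL, NULL))
    ensemble <- new("Ensemble", topology = topology, coords = arr,
                    frameIndex = 0L, timePs = NA_real_, source = "conformer")
  }
  top <- ensemble@topology
  nf <- nFrames(ensemble)
  natom <- nrow(top@atoms)
  xyz <- matrix(NA_real_, nf, 3 * natom)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(ensemble@coords[, , f])) * 10   # nm -> Angstrom
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = top@atoms$resno,
                   resid = top@residues$name[top@atoms$resno],
                   elety = top@atoms$atom,
                   chain = rep("A", natom))
  invisible(path)
}

# One text report file with a reproducibility header.
.writeReport <- function(df, path, header = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML with keys: \code{topology} (inline mapping or a path to a topology
#' config), \code{input} (either \code{pdb: <path>} or \code{synth} with
#' \code{state_mix} (named occupancies), \code{n_frames},
#' \code{jitter_sigma}), \code{seed}, and optional \code{selection}
#' (residue range for RMSD/clustering, default 2-11),
#' \code{cluster_cutoff} (nm, default 0.1), \code{twist_atoms},
#' \code{restraints} (path), \code{min_report} (percent),
#' \code{output_dir}.
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.configText <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg
}

.configHash <- function(cfg) {
  cfg$.configText <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.topologyFromConfig <- function(tc) {
  if (is.character(tc)) return(readTopologyConfig(tc))
  if (!is.null(tc$hairpin)) {
    am <- if (is.null(tc$aminated)) integer(0) else as.integer(tc$aminated)
    return(hairpinTopology(aminated = am))
  }
  name <- vapply(tc$residues, function(r) toupper(r$name), character(1))
  chir <- vapply(tc$residues, function(r)
    if (is.null(r$chirality)) "L" else r$chirality, character(1))
  amin <- vapply(tc$residues, function(r) isTRUE(r$aminated), logical(1))
  peptideTopology(name, chirality = chir, nAminated = amin)
}

# Build the input ensemble declared by the config.
.ensembleFromConfig <- function(cfg, topology) {
  inp <- cfg$input
  if (!is.null(inp$pdb)) return(readEnsemble(inp$pdb, topology))
  if (is.null(inp$synth)) stop("config input must give 'pdb' or 'synth'")
  sy <- inp$synth
  mix <- unlist(sy$state_mix)
  if (abs(sum(mix) - 1) > 1e-9) stop("state_mix must sum to 1")
  templates <- defaultStateTemplates(topology,
    jitterSigma = if (is.null(sy$jitter_sigma)) 10 else sy$jitter_sigma)
  states <- templates[names(mix)]
  if (any(vapply(states, is.null, TRUE)))
    stop("unknown state(s) in state_mix; available: ",
         paste(names(templates), collapse = ", "))
  k <- length(states)
  # i.i.d. state draws: every row of the chain equals the target mix
  P <- matrix(rep(as.numeric(mix), k), k, k, byrow = TRUE)
  gen <- generateMarkovEnsemble(
    markovSpec(states, P, names(mix)[which.max(mix)],
               nFrames = sy$n_frames, seed = cfg$seed),
    topology, source = if (is.null(sy$source)) "synth" else sy$source)
  gen$ensemble
}

#' Run the full conformational-analysis pipeline
#'
#' Orchestrates the whole analysis set over one input ensemble: per-frame
#' backbone RMSD against a folded reference, hydrogen-bond population
#' tables under both criteria, the N-amination (C6 / i-2) report, turn-type
#' populations and flip counts, the hairpin twist series,
#' Ramachandran-region occupancies, Daura clustering, and (when restraints
#' are given) an NOE violation report. All outputs are TSV/JSON files in
#' the output directory; every file header records the package version,
#' config hash, seed and criteria, and the run is a pure function of
#' (config, inputs, seed).
#'
#' @param config a configuration list (\code{\link{readRunConfig}}) or a
#'   path to a YAML config.
#' @param outDir output directory (default \code{config$output_dir}).
#' @return invisibly, a list of the computed objects (ensemble, rmsd,
#'   hbond tables, turn summary, twist, rama, clusters, noe).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(outDir)) outDir <- config$output_dir
  if (is.null(outDir)) stop("no output directory configured")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$seed)) stop("config must declare a seed")
  hash <- .configHash(config)
  ver <- as.character(utils::packageVersion("hairpintools"))
  hdr <- function(extra = character()) c(
    paste0("hairpintools ", ver),
    paste0("config_hash: ", hash),
    paste0("seed: ", config$seed),
    extra)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  topology <- stage("topology", .topologyFromConfig(config$topology))
  ensemble <- stage("input", .ensembleFromConfig(config, topology))

  selResidues <- if (is.null(config$selection)) 2:11
                 else config$selection[1]:config$selection[2]
  sel <- backboneSelection(selResidues)
  reference <- stage("reference", {
    if (!is.null(config$reference_pdb))
      getConformer(readEnsemble(config$reference_pdb, topology), 1)
    else
      buildConformer(topology, hairpinTorsions(topology, "II'"))
  })
  out <- list(ensemble = ensemble)

  out$rmsd <- stage("rmsd", rmsdSeries(ensemble, reference, sel))
  .writeReport(data.frame(frame = ensemble@frameIndex,
                          rmsd_nm = sprintf("%.6f", out$rmsd)),
               file.path(outDir, "rmsd.tsv"),
               hdr(paste0("selection: backbone ",
                          paste(range(selResidues), collapse = "-"))))

  minRep <- if (is.null(config$min_report)) 0 else config$min_report
  for (preset in c("medium_strong", "weak")) {
    crit <- hbondCriteria(preset)
    tab <- stage(paste0("hbonds_", preset),
                 hbondPopulations(ensemble, criteria = crit,
                                  minReport = minRep))
    tab$population <- sprintf("%.4f", tab$population)
    .writeReport(tab, file.path(outDir, paste0("hbonds_", preset, ".tsv")),
                 hdr(sprintf("criteria: d < %g nm, angle > %g deg",
                             crit@maxDist, crit@minAngle)))
    out[[paste0("hbonds_", preset)]] <- tab
  }

  out$amination <- stage("amination", aminationReport(ensemble))
  am <- out$amination
  am$population <- sprintf("%.4f", am$population)
  .writeReport(am, file.path(outDir, "amination.tsv"),
               hdr("criteria: weak (d < 0.32 nm, angle > 90 deg)"))

  out$turns <- stage("turns", turnSummary(ensemble))
  .writeReport(data.frame(frame = ensemble@frameIndex,
                          label = out$turns$labels,
                          label_by_psi = out$turns$labelsByPsi),
               file.path(outDir, "turns.tsv"), hdr())
  out$twist <- stage("twist", {
    atoms <- if (is.null(config$twist_atoms))
      c("1:C", "12:N", "8:C", "5:N") else config$twist_atoms
    twistSeries(ensemble, atoms)
  })
  .writeReport(data.frame(frame = ensemble@frameIndex,
                          twist_deg = sprintf("%.4f", out$twist$angles)),
               file.path(outDir, "twist.tsv"), hdr())
  summaryJson <- list(
    turn_populations = as.list(round(out$turns$populations, 4)),
    turn_populations_by_psi = as.list(round(out$turns$populationsByPsi, 4)),
    flips = out$turns$flips, flips_by_psi = out$turns$flipsByPsi,
    mean_twist_deg = round(out$twist$mean, 4),
    config_hash = hash, seed = config$seed)
  jsonlite::write_json(summaryJson, file.path(outDir, "turn_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  out$rama <- stage("rama", ramaOccupancy(ensemble))
  rm2 <- out$rama
  for (cc in c("alpha", "beta", "other")) rm2[[cc]] <- sprintf("%.4f", rm2[[cc]])
  .writeReport(rm2, file.path(outDir, "rama.tsv"), hdr())

  cut <- if (is.null(config$cluster_cutoff)) 0.1 else config$cluster_cutoff
  out$clusters <- stage("cluster", dauraCluster(ensemble, sel, cutoff = cut))
  .writeReport(data.frame(frame = ensemble@frameIndex,
                          source = out$clusters@source,
                          cluster = out$clusters@membership),
               file.path(outDir, "clusters.tsv"),
               hdr(paste0("cutoff_nm: ", cut)))
  jsonlite::write_json(
    list(sizes = out$clusters@sizes,
         medoid_frames = ensemble@frameIndex[out$clusters@medoids],
         contributions = as.data.frame(round(out$clusters@contributions, 4)),
         config_hash = hash, seed = config$seed),
    file.path(outDir, "cluster_summary.json"),
    auto_unbox = TRUE, pretty = TRUE)

  if (!is.null(config$restraints)) {
    rst <- stage("noe", {
      r <- readRestraints(config$restraints)
      checkViolations(ensemble, r,
                      reportThreshold = if (is.null(config$noe_threshold))
                        0.05 else config$noe_threshold)
    })
    out$noe <- rst
    tb <- rst$table
    for (cc in c("upper", "correction", "effective", "violation"))
      tb[[cc]] <- sprintf("%.6f", as.numeric(tb[[cc]]))
    .writeReport(tb, file.path(outDir, "noe.tsv"),
                 hdr(c(sprintf("violation_threshold_nm: %g", rst$threshold),
                       paste0("pseudoatom_corrections: ",
                              paste(names(pseudoatomCorrections()),
                                    pseudoatomCorrections(),
                                    sep = "=", collapse = " ")))))
  }
  invisible(out)
}
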