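#' Write an ensemble as multi-model PDB plus frame metadata
#'
#' One `MODEL` record per frame; particles are written as CA (or backbone)
#' pseudo-atoms with native residue numbering and chain ids.  Frame
#' metadata (state label, prior and ground-truth weights) goes to a
#' sidecar CSV.
#'
#' @param ensemble an [Ensemble-class] with at least one frame.
#' @param path output prefix; writes `<path>.pdb` and `<path>_frames.csv`.
#' @return invisibly, the two file paths.
#' @export
writeEnsemble <- function(ensemble, path) {
  nf <- nFrames(ensemble)
  if (nf < 1) stop("cannot write an empty ensemble")
  np <- nParticles(ensemble)
  pdb <- file.path(paste0(path, ".pdb"))
  meta <- file.path(paste0(path, "_frames.csv"))
  con <- file(pdb, "w")
  on.exit(close(con), add = TRUE)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- ensemble@coords[, , f]
    nm4 <- ifelse(nchar(ensemble@atomName) < 4,
                  sprintf(" %-3s", ensemble@atomName), ensemble@atomName)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(np), nm4, "ALA", ensemble@chain, ensemble@resid,
      x[, 1], x[, 2], x[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  tw <- if (length(ensemble@trueWeights)) ensemble@trueWeights else NA_real_
  utils::write.csv(
    data.frame(frame = seq_len(nf), state = ensemble@states,
               prior_weight = ensemble@priorWeights, true_weight = tw),
    meta, row.names = FALSE)
  invisible(c(pdb = pdb, metadata = meta))
}

#' Read an ensemble from multi-model PDB (+ optional frame metadata)
#'
#' Topology (chain, residue, atom name) is taken from the first model and
#' must be shared by all models.  Without metadata, priors are uniform and
#' all frames carry a single state label.
#'
#' @param pdbPath multi-model PDB file.
#' @param metadataPath optional CSV with columns `frame`, `state`,
#'   `prior_weight` (and optionally `true_weight`); row count must match
#'   the frame count.
#' @return an [Ensemble-class].
#' @export
readEnsemble <- function(pdbPath, metadataPath = NULL) {
  if (!file.exists(pdbPath)) stop("no such file: ", pdbPath)
  b <- bio3d::read.pdb(pdbPath, multi = TRUE, verbose = FALSE)
  xyz <- b$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  np <- nrow(b$atom)
  nf <- nrow(xyz)
  if (ncol(xyz) != 3 * np)
    stop("topology mismatch across models: ", ncol(xyz) / 3,
         " coordinates vs ", np, " atoms")
  co <- array(NA_real_, c(np, 3, nf))
  for (f in seq_len(nf))
    co[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  states <- rep("I", nf)
  priors <- rep(1 / nf, nf)
  tw <- numeric()
  if (!is.null(metadataPath)) {
    md <- utils::read.csv(metadataPath)
    if (nrow(md) != nf)
      stop("metadata has ", nrow(md), " rows but the PDB has ", nf, " frames")
    states <- as.character(md$state)
    priors <- md$prior_weight / sum(md$prior_weight)
    if (!is.null(md$true_weight) && !anyNA(md$true_weight))
      tw <- md$true_weight / sum(md$true_weight)
  }
  Ensemble(co, b$atom$chain, b$atom$resno, trimws(b$atom$elety),
           states, priors, tw)
}

# ---- pipeline configuration -------------------------------------------------

pipelineDefaults <- function() {
  list(
    seed = 1L,                 # master RNG seed
    chainLength = 311L,
    nFramesPerState = 200L,
    compaction = 0.025,        # complex growth attraction
    stateWeights = c(I = 0.4, II = 0.3, III = 0.2, IV = 0.1),
    noiseSd = 0,               # PRE observable noise
    field = 600, tauc = 29e-9, taui = 500e-12, td = 10e-3,
    r2red = 40, cap = 450,
    nRotamers = 16L,
    smooth = TRUE, loessSpan = 0.2,
    errorScale = 1, errorFloor = 0.05, errorMode = "inverse",
    thetaGridMax = 1e4, thetaGridMin = 1e-2, thetaGridN = 20L,
    elbowTol = 0.05,
    window = 4L, minGap = 4L,
    pcComponents = 50L,
    umapFraction = 0.1, umapNeighbors = 15L, umapMinDist = 0.1,
    knnK = 15L, louvainResolution = 1,
    clusterThreshold = 0.01,
    contactCutoff = 8,
    specHigh = 0.6, specLow = 0.2,
    entropyBins = 35L, temperature = 310,
    titration = TRUE, receptorConc = 100,
    ligandSeries = c(10, 20, 40, 60, 80, 100, 150, 200, 300),
    titrationNoiseSd = 0,
    kdTrue = c(LD1 = 17, LD2 = 7, LD4 = 13),
    doLandscape = TRUE, doEntropy = TRUE,
    writeEnsembles = FALSE)
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.  The
#' returned configuration carries a `provenance` attribute marking every
#' value `"default"` or `"user"`.
#'
#' @param config named list of overrides (possibly empty).
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config = list()) {
  defs <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- defs
  prov <- rep("default", length(defs)); names(prov) <- names(defs)
  for (k in names(config)) { out[[k]] <- config[[k]]; prov[k] <- "user" }
  if (abs(sum(out$stateWeights) - 1) > 1e-8) stop("stateWeights must sum to 1")
  attr(out, "provenance") <- prov
  out
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file with a flat object of overrides.
#' @return validated configuration (see [validatePipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validatePipelineConfig(as.list(cfg))
}
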