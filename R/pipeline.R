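#' Run the full synthetic-to-results analysis pipeline
#'
#' Generates (or reuses) a multi-state complex ensemble, back-calculates
#' PRE observables, prepares the experimental table, reweights by BME with
#' a theta scan, and runs the landscape, contact, entropy and titration
#' analyses.  All result tables are written as CSV under `outdir` together
#' with a machine-readable `summary.json` that logs every tunable actually
#' used (with default/user provenance).
#'
#' @param config list of configuration overrides (see
#'   [validatePipelineConfig()]); may already be validated.
#' @param outdir output directory (created if needed).
#' @param ensemble optionally, an existing [Ensemble-class] to analyse in
#'   place of synthetic generation.
#' @param preTable optionally, an existing experimental PRE table
#'   (data.frame `site`, `chain`, `residue`, `ratio`).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("prens_run_"),
                        ensemble = NULL, preTable = NULL) {
  cfg <- if (is.null(attr(config, "provenance")))
    validatePipelineConfig(config) else config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(parameters = cfg[order(names(cfg))],
                  provenance = as.list(attr(cfg, "provenance")))
  constants <- physicalConstants(field = cfg$field, tauc = cfg$tauc,
                                 taui = cfg$taui, td = cfg$td,
                                 r2red = cfg$r2red, cap = cfg$cap)
  truth <- groundTruth(stateWeights = cfg$stateWeights, kdTrue = cfg$kdTrue,
                       noiseSd = cfg$noiseSd, seed = cfg$seed)

  # -- ensemble ---------------------------------------------------------------
  ens <- stage("simulate", {
    if (is.null(ensemble)) {
      ch <- chainSpec(length = cfg$chainLength, compaction = cfg$compaction)
      sampleComplexEnsemble(ch, defaultComplexStates(), truth,
                            nFramesPerState = cfg$nFramesPerState)
    } else ensemble
  })
  if (cfg$writeEnsembles)
    stage("simulate", writeEnsemble(ens, file.path(outdir, "ensemble")))

  # -- forward PRE ------------------------------------------------------------
  sites <- defaultLabelSites()
  pre <- stage("pre-forward", {
    if (is.null(preTable)) {
      synthesizePRE(ens, sites, truth, constants, nRotamers = cfg$nRotamers)
    } else {
      list(table = preTable,
           profiles = computeGamma2Profiles(ens, sites, constants,
                                            nRotamers = cfg$nRotamers))
    }
  })
  utils::write.csv(pre$table, file.path(outdir, "pre_table.csv"),
                   row.names = FALSE)

  # -- prep -------------------------------------------------------------------
  prepped <- stage("prep", preparePRETable(
    pre$table, constants, smooth = cfg$smooth, span = cfg$loessSpan,
    errorScale = cfg$errorScale, errorFloor = cfg$errorFloor,
    errorMode = cfg$errorMode, cap = cfg$cap))
  utils::write.csv(prepped, file.path(outdir, "pre_prepared.csv"),
                   row.names = FALSE)

  # -- BME reweighting --------------------------------------------------------
  grid <- 10^seq(log10(cfg$thetaGridMax), log10(cfg$thetaGridMin),
                 length.out = cfg$thetaGridN)
  rw <- stage("reweight", bmeReweight(ens, pre$profiles, prepped,
                                      theta = "scan", grid = grid,
                                      elbowTol = cfg$elbowTol,
                                      cap = cfg$cap))
  fit <- rw$fit
  w <- refinedWeights(fit)
  utils::write.csv(rw$scan, file.path(outdir, "theta_scan.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(w), state = stateLabels(ens),
               prior = priorWeights(ens), weight = w),
    file.path(outdir, "weights.csv"), row.names = FALSE)
  summary$reweight <- list(
    selectedTheta = rw$selected, chi2 = fit@chi2, chi2Prior = fit@chi2Prior,
    neff = fit@neff,
    stateContributions = as.list(fit@stateContributions))
  if (length(trueWeights(ens)))
    summary$reweight$trueStateWeights <-
      as.list(stateContributions(trueWeights(ens), stateLabels(ens)))

  # -- radius of gyration -----------------------------------------------------
  rg <- stage("rg", radiusOfGyration(ens, weights = w))
  utils::write.csv(rg$summary, file.path(outdir, "rg_summary.csv"),
                   row.names = FALSE)
  summary$rg <- list(weightedMean = rg$summary$mean[rg$summary$state == "all"])

  # -- landscape --------------------------------------------------------------
  if (cfg$doLandscape) {
    lm <- stage("landscape", {
      m <- segmentFeatures(ens, chain = "A", window = cfg$window,
                           minGap = cfg$minGap)
      m <- reducePCA(m, cfg$pcComponents)
      m <- embedUMAP(m, subsampleFraction = cfg$umapFraction,
                     seed = cfg$seed, nNeighbors = cfg$umapNeighbors,
                     minDist = cfg$umapMinDist)
      clusterConformations(m, kNeighbors = cfg$knnK,
                           resolution = cfg$louvainResolution,
                           seed = cfg$seed)
    })
    contr <- clusterContributions(lm, w, threshold = cfg$clusterThreshold)
    km <- kmeansOnEmbedding(lm, seed = cfg$seed)
    val <- stage("landscape",
                 validateClustering(km, lm@clusters, nShuffles = 1000L,
                                    seed = cfg$seed))
    utils::write.csv(
      data.frame(frame = seq_len(nrow(lm@embedding)),
                 x = lm@embedding[, 1], y = lm@embedding[, 2],
                 cluster = lm@clusters),
      file.path(outdir, "landscape.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(cluster = names(contr$contributions),
                 contribution = contr$contributions),
      file.path(outdir, "cluster_contributions.csv"), row.names = FALSE)
    summary$landscape <- list(
      nFeatures = ncol(lm@features), nClusters = length(unique(lm@clusters)),
      topClusters = length(contr$topClusters),
      topShare = contr$cumulativeTopShare,
      ari = val$ari, ami = val$ami,
      nullMeanAri = unname(val$nullMean["ari"]))
  }

  # -- contacts ---------------------------------------------------------------
  cm <- stage("contacts", {
    intra <- contactFrequencyMap(ens, w, scope = "intra",
                                 cutoff = cfg$contactCutoff,
                                 window = cfg$window, byState = TRUE)
    inter <- contactFrequencyMap(ens, w, scope = "inter",
                                 cutoff = cfg$contactCutoff,
                                 window = cfg$window, byState = TRUE)
    prof <- interactionProfile(ens, w, cutoff = cfg$contactCutoff,
                               window = cfg$window)
    spec <- stateSpecificContacts(inter$states, highThresh = cfg$specHigh,
                                  lowThresh = cfg$specLow, topN = 3)
    list(intra = intra, inter = inter, prof = prof, spec = spec)
  })
  writeContactMap <- function(map, path) {
    long <- do.call(rbind, lapply(c(list(all = map$frequency), map$states),
      function(fr) {
        idx <- which(!is.na(fr), arr.ind = TRUE)
        data.frame(segA = idx[, 1], segB = idx[, 2], frequency = fr[idx])
      }))
    long$state <- rep(c("all", names(map$states)),
                      times = vapply(c(list(map$frequency), map$states),
                                     function(fr) sum(!is.na(fr)), integer(1)))
    utils::write.csv(long, path, row.names = FALSE)
  }
  writeContactMap(cm$intra, file.path(outdir, "contacts_intra.csv"))
  writeContactMap(cm$inter, file.path(outdir, "contacts_inter.csv"))
  utils::write.csv(cm$prof$perResidueA,
                   file.path(outdir, "interaction_profile_chainA.csv"),
                   row.names = FALSE)
  utils::write.csv(cm$spec, file.path(outdir, "state_specific_contacts.csv"),
                   row.names = FALSE)
  summary$contacts <- list(nStateSpecific = nrow(cm$spec))

  # -- entropy ----------------------------------------------------------------
  if (cfg$doEntropy) {
    ent <- stage("entropy", {
      tor <- extractTorsions(ens, chain = "A")
      byState <- entropyByState(tor, w, stateLabels(ens),
                                nBins = cfg$entropyBins,
                                temperature = cfg$temperature)
      interFreq <- interChainResidueFrequency(ens, w, cfg$contactCutoff,
                                              cfg$window)
      cmp <- lapply(byState, entropyContactComparison,
                    contactFrequency = interFreq,
                    low = cfg$specLow, high = cfg$specHigh)
      list(byState = byState, cmp = cmp)
    })
    entTab <- do.call(rbind, lapply(names(ent$byState), function(s)
      cbind(state = s, ent$byState[[s]]@profile)))
    utils::write.csv(entTab, file.path(outdir, "entropy_profiles.csv"),
                     row.names = FALSE)
    summary$entropy <- lapply(ent$cmp, function(x)
      list(p = x$p, significance = x$significance, tested = x$tested))
  }

  # -- titration --------------------------------------------------------------
  if (cfg$titration) {
    tit <- stage("titrate", {
      ser <- synthesizeTitration(cfg$kdTrue, cfg$receptorConc,
                                 cfg$ligandSeries, cfg$titrationNoiseSd,
                                 seed = cfg$seed)
      fits <- fitKdSeries(ser)
      list(series = ser, fits = fits, summary = motifKdSummary(fits))
    })
    utils::write.csv(tit$fits, file.path(outdir, "titration_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(tit$summary, file.path(outdir, "titration_summary.csv"),
                     row.names = FALSE)
    summary$titration <- lapply(split(tit$summary, tit$summary$motif),
      function(d) list(kdMean = d$kdMean, kdSd = d$kdSd, n = d$n))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# weighted per-residue inter-chain contact frequency (chain A residues)
interChainResidueFrequency <- function(ensemble, weights, cutoff, window) {
  prof <- interactionProfile(ensemble, weights, cutoff = cutoff,
                             window = window)
  structure(prof$perResidueA$probability,
            names = as.character(prof$perResidueA$residue))
}
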