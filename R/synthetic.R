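#' Specification of the disordered chain
#'
#' Coarse one-bead-per-residue model of the 311-residue disordered chain,
#' with helical LD-motif segments treated as rigid ideal helices.  Default
#' motif boundaries approximate LD1 (3-14), LD2 (144-155) and LD4 (263-274).
#'
#' @param length residue count (default 311).
#' @param helicalSegments named list of `c(start, end)` residue ranges.
#' @param bondLength consecutive-bead distance in Angstrom (default 3.8).
#' @param excludedVolumeRadius hard-sphere bead radius in Angstrom
#'   (default 2.0; non-bonded beads may not come closer than twice this).
#' @param compaction growth bias: negative values push the walk away from
#'   the running centroid (expansion), positive pull toward an attraction
#'   point.  The default 0 leaves a plain self-avoiding walk.
#' @return list of class `ChainSpec`.
#' @export
chainSpec <- function(length = 311L,
                      helicalSegments = list(LD1 = c(3L, 14L),
                                             LD2 = c(144L, 155L),
                                             LD4 = c(263L, 274L)),
                      bondLength = 3.8, excludedVolumeRadius = 2.0,
                      compaction = 0) {
  length <- as.integer(length)
  stopifnot(length >= 1, bondLength > 0, excludedVolumeRadius > 0)
  helicalSegments <- helicalSegments[
    vapply(helicalSegments, function(s) s[1] >= 1 && s[2] <= length, logical(1))]
  if (base::length(helicalSegments) > 1) {
    b <- do.call(rbind, helicalSegments)
    b <- b[order(b[, 1]), , drop = FALSE]
    if (any(b[-1, 1] <= b[-nrow(b), 2]))
      stop("helical segments must be non-overlapping")
  }
  for (s in helicalSegments)
    if (s[2] < s[1]) stop("helical segment end before start")
  structure(list(length = length, helicalSegments = helicalSegments,
                 bondLength = bondLength,
                 excludedVolumeRadius = excludedVolumeRadius,
                 compaction = compaction),
            class = "ChainSpec")
}

#' Rigid receptor proxy: a four-helix bundle of bead rods
#'
#' Four ideal-helix C-alpha rods (alpha1-alpha4) arranged as an antiparallel
#' bundle, numbered 916-1040 so that the standard label sites (984, 1006 on
#' the alpha2/alpha3 face; 1018, 1040 on the alpha1/alpha4 face) resolve on
#' it.  Two anchor points, one per binding face, sit just outside the
#' bundle surface.
#'
#' @return list with `coords` (125 x 3), `resid`, `anchors` (list with
#'   `a14`, `a23` coordinates).
#' @export
receptorProxy <- function() {
  rod <- function(base, dir, len) {
    u <- dir / sqrt(sum(dir^2))
    v <- if (abs(u[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    k <- seq_len(len) - 1
    tw <- 100 * pi / 180
    matrix(base, len, 3, byrow = TRUE) +
      outer(1.5 * k, u) + 2.3 * (outer(cos(tw * k) - 1, v) + outer(sin(tw * k), w))
  }
  co <- rbind(
    rod(c( 7.5,  7.5, -24), c(0, 0,  1), 32),  # alpha1: 916-947
    rod(c(-7.5,  7.5,  22.5), c(0, 0, -1), 31),# alpha2: 948-978
    rod(c(-7.5, -7.5, -22.5), c(0, 0,  1), 31),# alpha3: 979-1009
    rod(c( 7.5, -7.5,  22.5), c(0, 0, -1), 31) # alpha4: 1010-1040
  )
  list(coords = co, resid = 916:1040,
       anchors = list(a14 = c(13.5, 0, 0), a23 = c(-13.5, 0, 0)))
}

#' Specification of one bound state
#'
#' Each state anchors exactly two helical motifs, one on each binding face
#' of the receptor proxy.
#'
#' @param stateId one of `"I"`, `"II"`, `"III"`, `"IV"` (free-form allowed).
#' @param anchoredMotifs named character vector mapping motif name to face,
#'   e.g. `c(LD1 = "a14", LD2 = "a23")`.
#' @return list of class `ComplexStateSpec`.
#' @export
complexStateSpec <- function(stateId, anchoredMotifs) {
  if (length(anchoredMotifs) != 2L)
    stop("exactly two motifs must be anchored per state")
  if (anyDuplicated(unname(anchoredMotifs)))
    stop("the two anchored motifs must sit on distinct faces")
  if (!all(anchoredMotifs %in% c("a14", "a23")))
    stop("faces must be 'a14' or 'a23'")
  structure(list(stateId = stateId, anchoredMotifs = anchoredMotifs),
            class = "ComplexStateSpec")
}

#' The four-state layout with LD2 always bound
#'
#' State I: LD1 on alpha1/alpha4, LD2 on alpha2/alpha3.  State II: LD4 on
#' alpha1/alpha4, LD2 on alpha2/alpha3.  State III: LD2 on alpha1/alpha4,
#' LD1 on alpha2/alpha3.  State IV: LD2 on alpha1/alpha4, LD4 on
#' alpha2/alpha3.
#'
#' @return list of four [complexStateSpec()] objects.
#' @export
defaultComplexStates <- function() {
  list(complexStateSpec("I",   c(LD1 = "a14", LD2 = "a23")),
       complexStateSpec("II",  c(LD4 = "a14", LD2 = "a23")),
       complexStateSpec("III", c(LD2 = "a14", LD1 = "a23")),
       complexStateSpec("IV",  c(LD2 = "a14", LD4 = "a23")))
}

#' Ground-truth parameters for synthetic data
#'
#' @param stateWeights named probabilities per state (sum to 1).
#' @param kdTrue named dissociation constants per motif (concentration units).
#' @param noiseSd relative (multiplicative) noise on observables.
#' @param seed integer RNG seed.
#' @return list of class `GroundTruth`.
#' @export
groundTruth <- function(stateWeights = c(I = 0.25, II = 0.25, III = 0.25, IV = 0.25),
                        kdTrue = c(LD1 = 17, LD2 = 7, LD4 = 13),
                        noiseSd = 0, seed = 1L) {
  stopifnot(all(stateWeights >= 0), abs(sum(stateWeights) - 1) < 1e-8,
            noiseSd >= 0, all(kdTrue > 0))
  structure(list(stateWeights = stateWeights, kdTrue = kdTrue,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "GroundTruth")
}

growChain <- function(spec, helixMat, anchorMat, obstacles, kappa, attract,
                      anchorTol = 6, maxTries = 300L, maxRestarts = 60L) {
  if (is.null(helixMat)) helixMat <- matrix(integer(), 0, 2)
  if (is.null(anchorMat)) anchorMat <- matrix(NaN, nrow(helixMat), 3)
  if (is.null(obstacles)) obstacles <- matrix(numeric(), 0, 3)
  cpp_grow_chain(spec$length, spec$bondLength,
                 2 * spec$excludedVolumeRadius, 3.5,
                 helixMat, anchorMat, anchorTol, obstacles,
                 kappa, as.numeric(attract), maxTries, maxRestarts)
}

#' Sample an unbound (apo) chain ensemble
#'
#' Self-avoiding coarse-chain conformations with helical segments emitted as
#' rigid ideal helices; deterministic for a fixed seed.
#'
#' @param spec a [chainSpec()].
#' @param nFrames number of frames (>= 1).
#' @param seed integer RNG seed.
#' @return an [Ensemble-class] (chain `"A"`, state `"apo"`).
#' @export
sampleApoEnsemble <- function(spec = defaultApoChainSpec(), nFrames = 100L,
                              seed = 1L) {
  stopifnot(nFrames >= 1)
  set.seed(seed)
  hm <- if (length(spec$helicalSegments))
    do.call(rbind, lapply(spec$helicalSegments, as.integer)) else NULL
  co <- array(NA_real_, c(spec$length, 3, nFrames))
  for (f in seq_len(nFrames))
    co[, , f] <- growChain(spec, hm, NULL, NULL, spec$compaction, c(0, 0, 0))
  Ensemble(co, rep("A", spec$length), seq_len(spec$length),
           states = rep("apo", nFrames))
}

#' Sample a multi-state bound-complex ensemble
#'
#' For each state the chain is grown around the rigid receptor proxy with
#' the state's two motifs anchored, one per binding face; frames are tagged
#' with the state id and carry ground-truth weights (the state weight spread
#' uniformly over that state's frames).
#'
#' @param chain a [chainSpec()]; `compaction` should be positive here (pull
#'   toward the receptor; default used by [defaultComplexChainSpec()]).
#' @param states list of [complexStateSpec()].
#' @param truth a [groundTruth()]; its `stateWeights` must cover the states.
#' @param nFramesPerState frames per state.
#' @param anchorTol anchoring tolerance in Angstrom (default 6).
#' @return an [Ensemble-class] with chains `"A"` (disordered) and `"B"`
#'   (receptor) and `trueWeights` set.
#' @export
sampleComplexEnsemble <- function(chain = defaultComplexChainSpec(),
                                  states = defaultComplexStates(),
                                  truth = groundTruth(),
                                  nFramesPerState = 100L, anchorTol = 6) {
  stopifnot(length(states) >= 1, nFramesPerState >= 1)
  rec <- receptorProxy()
  set.seed(truth$seed)
  hm <- do.call(rbind, lapply(chain$helicalSegments, as.integer))
  nb <- chain$length
  nf <- length(states) * nFramesPerState
  co <- array(NA_real_, c(nb + nrow(rec$coords), 3, nf))
  stLab <- character(nf)
  tw <- numeric(nf)
  f <- 0L
  for (s in states) {
    am <- matrix(NaN, nrow(hm), 3)
    for (m in names(s$anchoredMotifs)) {
      i <- match(m, names(chain$helicalSegments))
      if (is.na(i)) stop("state ", s$stateId, ": motif ", m,
                         " not defined in the chain spec")
      am[i, ] <- rec$anchors[[s$anchoredMotifs[[m]]]]
    }
    wState <- truth$stateWeights[[s$stateId]]
    if (is.null(wState)) stop("no ground-truth weight for state ", s$stateId)
    for (k in seq_len(nFramesPerState)) {
      f <- f + 1L
      ch <- tryCatch(
        growChain(chain, hm, am, rec$coords, chain$compaction, c(0, 0, 0),
                  anchorTol = anchorTol),
        error = function(e) stop("state ", s$stateId, ": ", conditionMessage(e)))
      co[, , f] <- rbind(ch, rec$coords)
      stLab[f] <- s$stateId
      tw[f] <- wState / nFramesPerState
    }
  }
  Ensemble(co, c(rep("A", nb), rep("B", nrow(rec$coords))),
           c(seq_len(nb), rec$resid), states = stLab,
           trueWeights = tw / sum(tw))
}

#' Chain specs tuned to the experimental compaction targets
#'
#' `defaultApoChainSpec()` carries a mild centroid repulsion calibrated so
#' the unbound ensemble mean radius of gyration falls in the 52-59 A band
#' seen by SAXS and simulation; `defaultComplexChainSpec()` carries a weak
#' attraction toward the receptor calibrated so the weighted mean Rg of the
#' complex falls near the 35 A SAXS estimate.
#'
#' @param compaction growth bias (defaults -0.07 apo, 0.025 complex).
#' @return a [chainSpec()].
#' @export
defaultComplexChainSpec <- function(compaction = 0.025) {
  chainSpec(compaction = compaction)
}

#' @rdname defaultComplexChainSpec
#' @export
defaultApoChainSpec <- function(compaction = -0.07) {
  chainSpec(compaction = compaction)
}

#' Synthesize experimental-style PRE tables from an ensemble
#'
#' Applies the package's own forward model with the ground-truth frame
#' weights, converts to intensity ratios, and adds multiplicative Gaussian
#' noise clipped to `[0, 1.2]`.
#'
#' @param ensemble an [Ensemble-class] with `trueWeights` (falls back to
#'   prior weights).
#' @param sites list of [spinLabelSite()].
#' @param truth a [groundTruth()] (uses `noiseSd` and `seed`).
#' @param constants a [physicalConstants()].
#' @param ... forwarded to [computeGamma2Profiles()].
#' @return list with `table` (data.frame: site, chain, residue, ratio),
#'   `profiles` (per-site [Gamma2Profile-class]) and `trueGamma2`
#'   (list of noise-free averaged profiles).
#' @export
synthesizePRE <- function(ensemble, sites = defaultLabelSites(),
                          truth = groundTruth(),
                          constants = physicalConstants(), ...) {
  w <- if (length(trueWeights(ensemble))) trueWeights(ensemble)
       else priorWeights(ensemble)
  profiles <- computeGamma2Profiles(ensemble, sites, constants, ...)
  set.seed(truth$seed + 7L)
  tabs <- list(); trueG <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    gbar <- gamma2Ensemble(pr, w)
    ratio <- gamma2ToIntensity(gbar, constants)
    if (truth$noiseSd > 0)
      ratio <- ratio * (1 + stats::rnorm(length(ratio), 0, truth$noiseSd))
    ratio <- pmin(pmax(ratio, 0), 1.2)
    tabs[[nm]] <- data.frame(site = nm, chain = pr@site$chain,
                             residue = pr@residues, ratio = ratio)
    trueG[[nm]] <- gbar
  }
  list(table = do.call(rbind, tabs), profiles = profiles, trueGamma2 = trueG)
}

#' Single-site binding with receptor depletion
#'
#' Fraction of receptor bound at total ligand `L`, total receptor `P` and
#' dissociation constant `Kd`, from the quadratic solution of the
#' mass-balance equations:
#' \deqn{f_b = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P}}
#'
#' @param L total ligand concentration(s).
#' @param P total receptor concentration.
#' @param kd dissociation constant.
#' @return fraction bound in `[0, 1]`.
#' @export
fractionBound <- function(L, P, kd) {
  s <- P + L + kd
  (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
}

#' Synthesize a titration series
#'
#' Per-residue intensity retention `I/I0 = 1 - fb(L)` under the depletion
#' isotherm, with multiplicative Gaussian noise.
#'
#' @param kdTrue named per-motif dissociation constants.
#' @param receptorConc fixed labeled-chain concentration `P` (default 100).
#' @param ligandSeries added-ligand concentrations (default the 9-point
#'   10-300 ladder: 10, 20, 40, 60, 80, 100, 150, 200, 300).
#' @param noiseSd relative noise (default 0).
#' @param seed RNG seed.
#' @param motifResidues named list of residue numbers per motif (default the
#'   [chainSpec()] motif segments).
#' @return data.frame of class `TitrationSeries`: `residue`, `motif`, `L`,
#'   `ratio` (I/I0).
#' @export
synthesizeTitration <- function(kdTrue = c(LD1 = 17, LD2 = 7, LD4 = 13),
                                receptorConc = 100,
                                ligandSeries = c(10, 20, 40, 60, 80, 100, 150, 200, 300),
                                noiseSd = 0, seed = 1L,
                                motifResidues = NULL) {
  stopifnot(receptorConc > 0, all(ligandSeries >= 0), noiseSd >= 0)
  if (is.null(motifResidues)) {
    seg <- chainSpec()$helicalSegments
    motifResidues <- lapply(seg[names(kdTrue)], function(s) seq(s[1], s[2]))
  }
  set.seed(seed)
  rows <- list()
  for (m in names(kdTrue)) {
    for (r in motifResidues[[m]]) {
      fb <- fractionBound(ligandSeries, receptorConc, kdTrue[[m]])
      ratio <- 1 - fb
      if (noiseSd > 0) ratio <- ratio * (1 + stats::rnorm(length(ratio), 0, noiseSd))
      rows[[length(rows) + 1L]] <- data.frame(residue = r, motif = m,
                                              L = ligandSeries, ratio = ratio)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("TitrationSeries", class(out))
  attr(out, "receptorConc") <- receptorConc
  out
}
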