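#' Per-frame segment contact indicators
#'
#' Two segments are in contact when their minimum inter-particle distance is
#' at or below `cutoff`.  For intra-chain maps, short-range pairs (two or
#' fewer segments apart) are omitted.
#'
#' @param ensemble an [Ensemble-class].
#' @param frame frame index.
#' @param chainA,chainB chains of the two segment sets (`chainB = chainA`
#'   for intra-chain).
#' @param cutoff contact distance in Angstrom (default 8, a CA-CA contact
#'   radius for coarse models).
#' @param window segment width (default 4).
#' @return logical matrix `nSegA x nSegB`; intra-chain short-range entries
#'   are `NA`.
#' @export
frameContacts <- function(ensemble, frame, chainA = "A", chainB = chainA,
                          cutoff = 8, window = 4L) {
  m <- contactIndicatorMatrix(ensemble, chainA, chainB, cutoff, window,
                              frames = frame)
  out <- matrix(m$contact[, 1] > 0, m$nSegA, m$nSegB)
  if (chainA == chainB) out[m$shortRange] <- NA
  out
}

# shared machinery: min distances for all (segA, segB) pairs and frames
contactIndicatorMatrix <- function(ensemble, chainA, chainB, cutoff, window,
                                   frames = NULL) {
  idxA <- particleIndices(ensemble, chain = chainA, atomName = "CA")
  idxB <- particleIndices(ensemble, chain = chainB, atomName = "CA")
  if (!length(idxA) || !length(idxB)) stop("unknown chain in contact scheme")
  resA <- ensemble@resid[idxA]; resB <- ensemble@resid[idxB]
  segA <- segmentScheme(resA, window)
  segB <- segmentScheme(resB, window)
  nA <- nrow(segA); nB <- nrow(segB)
  intra <- chainA == chainB
  # bead indices relative to the combined subset
  sub <- c(idxA, if (!intra) idxB)
  co <- ensemble@coords[sub, , , drop = FALSE]
  if (!is.null(frames)) co <- co[, , frames, drop = FALSE]
  offB <- if (intra) 0L else length(idxA)
  aStart <- match(segA[, 1], resA); aEnd <- match(segA[, 2], resA)
  bStart <- match(segB[, 1], resB) + offB; bEnd <- match(segB[, 2], resB) + offB
  pairs <- as.matrix(expand.grid(a = seq_len(nA), b = seq_len(nB)))
  segStart <- c(aStart, bStart); segEnd <- c(aEnd, bEnd)
  prIdx <- cbind(pairs[, 1], pairs[, 2] + nA)
  D <- cpp_segpair_mindist(as.numeric(co), dim(co),
                           as.integer(segStart - 1L), as.integer(segEnd - 1L),
                           prIdx - 1L)
  shortRange <- if (intra)
    matrix(abs(outer(seq_len(nA), seq_len(nB), "-")) <= 2, nA, nB)
  else matrix(FALSE, nA, nB)
  list(contact = (D <= cutoff) * 1, dist = D, pairs = pairs,
       nSegA = nA, nSegB = nB, segA = segA, segB = segB,
       shortRange = shortRange)
}

#' Weighted contact frequency map
#'
#' Frequency of each segment pair being in contact, averaged over frames
#' with the supplied weights; per-state maps restrict and renormalize the
#' weights within each state.
#'
#' @param ensemble an [Ensemble-class].
#' @param weights normalized frame weights (default priors).
#' @param scope `"intra"` (within `chainA`) or `"inter"` (chain A vs B).
#' @param chainA,chainB chains (defaults `"A"`, `"B"`).
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @param window segment width (default 4).
#' @param byState also compute per-state maps (default FALSE).
#' @return list of class `ContactMap`: `frequency` (matrix in `[0, 1]`),
#'   `segA`, `segB`, `scope`, `cutoff`, and `states` (named list of per-state
#'   maps) when requested.  Intra-chain short-range entries are `NA`.
#' @export
contactFrequencyMap <- function(ensemble, weights = NULL,
                                scope = c("intra", "inter"), chainA = "A",
                                chainB = "B", cutoff = 8, window = 4L,
                                byState = FALSE) {
  scope <- match.arg(scope)
  if (is.null(weights)) weights <- priorWeights(ensemble)
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized")
  cb <- if (scope == "intra") chainA else chainB
  m <- contactIndicatorMatrix(ensemble, chainA, cb, cutoff, window)
  toMap <- function(w) {
    fr <- matrix(drop(m$contact %*% w), m$nSegA, m$nSegB)
    if (scope == "intra") fr[m$shortRange] <- NA
    fr
  }
  out <- list(frequency = toMap(weights), segA = m$segA, segB = m$segB,
              scope = scope, cutoff = cutoff)
  if (byState) {
    st <- stateLabels(ensemble)
    out$states <- lapply(split(seq_along(weights), st), function(i) {
      wTot <- sum(weights[i])
      if (wTot <= 0) stop("zero total weight in a state")
      w <- numeric(length(weights)); w[i] <- weights[i] / wTot
      toMap(w)
    })
  }
  class(out) <- "ContactMap"
  out
}

#' Interaction-probability profile
#'
#' For each segment of either chain, the weighted fraction of frames in
#' which it contacts any segment of the partner chain, with a per-residue
#' expansion.
#'
#' @param ensemble an [Ensemble-class].
#' @param weights normalized frame weights (default priors).
#' @param chainA,chainB the two chains (defaults `"A"`, `"B"`).
#' @param cutoff contact cutoff (default 8 Angstrom).
#' @param window segment width (default 4).
#' @return list of class `InteractionProfile` with per-chain data.frames
#'   (`segment`, `first`, `last`, `probability`) and `perResidue`
#'   expansions.
#' @export
interactionProfile <- function(ensemble, weights = NULL, chainA = "A",
                               chainB = "B", cutoff = 8, window = 4L) {
  if (is.null(weights)) weights <- priorWeights(ensemble)
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized")
  m <- contactIndicatorMatrix(ensemble, chainA, chainB, cutoff, window)
  # any-partner indicator per segment and frame (rows of `contact` are
  # (segA, segB) pairs in expand.grid order)
  anyA <- (rowsum(m$contact, m$pairs[, 1]) > 0) * 1
  anyB <- (rowsum(m$contact, m$pairs[, 2]) > 0) * 1
  profile <- function(anyC, segs) {
    p <- drop(anyC %*% weights)
    data.frame(segment = seq_len(nrow(segs)), first = segs[, 1],
               last = segs[, 2], probability = p)
  }
  pa <- profile(anyA, m$segA); pb <- profile(anyB, m$segB)
  expand <- function(p) {
    do.call(rbind, lapply(seq_len(nrow(p)), function(i)
      data.frame(residue = p$first[i]:p$last[i], probability = p$probability[i])))
  }
  structure(list(chainA = pa, chainB = pb,
                 perResidueA = expand(pa), perResidueB = expand(pb),
                 cutoff = cutoff), class = "InteractionProfile")
}

#' State-specific contacts
#'
#' A segment pair is specific to state `s` when its frequency there is at
#' least `highThresh` and its maximum frequency over the other states is at
#' most `lowThresh`.
#'
#' @param stateMaps named list of per-state frequency matrices (e.g. the
#'   `states` element of [contactFrequencyMap()]).
#' @param highThresh in-state frequency floor (default 0.6).
#' @param lowThresh out-of-state frequency ceiling (default 0.2).
#' @param topN optionally keep only the `topN` highest-frequency specific
#'   contacts per state.
#' @return data.frame: `state`, `segA`, `segB`, `frequency`, `maxOther`,
#'   ranked within state.
#' @export
stateSpecificContacts <- function(stateMaps, highThresh = 0.6,
                                  lowThresh = 0.2, topN = NULL) {
  if (length(stateMaps) < 2) stop("need at least two states")
  out <- list()
  for (s in names(stateMaps)) {
    fr <- stateMaps[[s]]
    others <- stateMaps[names(stateMaps) != s]
    maxOther <- Reduce(pmax, others)
    hit <- which(!is.na(fr) & fr >= highThresh &
                   (is.na(maxOther) | maxOther <= lowThresh), arr.ind = TRUE)
    if (!nrow(hit)) next
    d <- data.frame(state = s, segA = hit[, 1], segB = hit[, 2],
                    frequency = fr[hit], maxOther = maxOther[hit])
    d <- d[order(-d$frequency), ]
    if (!is.null(topN)) d <- utils::head(d, topN)
    out[[s]] <- d
  }
  if (!length(out))
    return(data.frame(state = character(), segA = integer(), segB = integer(),
                      frequency = numeric(), maxOther = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
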