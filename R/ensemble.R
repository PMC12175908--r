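#' Construct an Ensemble
#'
#' @param coords numeric array `nParticles x 3 x nFrames` (Angstrom).
#' @param chain character vector of chain identifiers per particle.
#' @param resid integer vector of native residue numbers per particle.
#' @param atomName character vector of particle names (default all `"CA"`).
#' @param states character vector of per-frame state labels (default `"I"`).
#' @param priorWeights per-frame prior weights; default uniform.
#' @param trueWeights optional ground-truth frame weights.
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(coords, chain, resid, atomName = NULL, states = NULL,
                     priorWeights = NULL, trueWeights = numeric()) {
  if (length(dim(coords)) == 2L) dim(coords) <- c(dim(coords), 1L)
  nf <- dim(coords)[3]
  np <- dim(coords)[1]
  if (is.null(atomName)) atomName <- rep("CA", np)
  if (is.null(states)) states <- rep("I", nf)
  if (is.null(priorWeights)) priorWeights <- rep(1 / nf, nf)
  new("Ensemble", coords = coords, chain = as.character(chain),
      resid = as.integer(resid), atomName = atomName,
      states = as.character(states), priorWeights = priorWeights,
      trueWeights = as.numeric(trueWeights))
}

#' Accessors for Ensemble objects
#'
#' @param x an [Ensemble-class].
#' @param frame frame index.
#' @param chain chain identifier; `NULL` for all particles.
#' @param value replacement prior weights (normalized check applies).
#' @name Ensemble-accessors
NULL

#' @rdname Ensemble-accessors
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])

#' @rdname Ensemble-accessors
#' @export
setMethod("nParticles", "Ensemble", function(x) dim(x@coords)[1])

#' @rdname Ensemble-accessors
#' @export
setMethod("frameCoords", "Ensemble", function(x, frame) {
  x@coords[, , frame, drop = TRUE]
})

#' @rdname Ensemble-accessors
#' @export
setMethod("stateLabels", "Ensemble", function(x) x@states)

#' @rdname Ensemble-accessors
#' @export
setMethod("priorWeights", "Ensemble", function(x) x@priorWeights)

#' @rdname Ensemble-accessors
#' @export
setMethod("priorWeights<-", "Ensemble", function(x, value) {
  x@priorWeights <- value
  validObject(x)
  x
})

#' @rdname Ensemble-accessors
#' @export
setMethod("trueWeights", "Ensemble", function(x) x@trueWeights)

#' @rdname Ensemble-accessors
#' @export
setMethod("chainIds", "Ensemble", function(x) unique(x@chain))

#' @rdname Ensemble-accessors
#' @export
setMethod("residueNumbers", "Ensemble", function(x, chain) {
  unique(x@resid[x@chain == chain])
})

#' @export
setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat("Ensemble:", d[3], "frames,", d[1], "particles\n")
  for (ch in chainIds(object)) {
    r <- range(object@resid[object@chain == ch])
    cat("  chain", ch, ":", sum(object@chain == ch), "particles, residues",
        r[1], "-", r[2], "\n")
  }
  st <- table(object@states)
  cat("  states:", paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
  if (length(object@trueWeights)) cat("  ground-truth frame weights stored\n")
})

#' Particle indices for a selection
#'
#' @param x an [Ensemble-class].
#' @param chain chain id or `NULL` for all.
#' @param resid residue numbers or `NULL` for all.
#' @param atomName particle names or `NULL` for all.
#' @return integer indices into the particle dimension.
#' @export
particleIndices <- function(x, chain = NULL, resid = NULL, atomName = NULL) {
  keep <- rep(TRUE, nParticles(x))
  if (!is.null(chain)) keep <- keep & x@chain %in% chain
  if (!is.null(resid)) keep <- keep & x@resid %in% resid
  if (!is.null(atomName)) keep <- keep & x@atomName %in% atomName
  which(keep)
}

#' Subset an ensemble by frames
#'
#' Frame weights (prior and ground-truth) are renormalized over the kept
#' frames.
#'
#' @param x an [Ensemble-class].
#' @param frames integer frame indices to keep.
#' @return An [Ensemble-class].
#' @export
subsetFrames <- function(x, frames) {
  pw <- x@priorWeights[frames]
  tw <- if (length(x@trueWeights)) x@trueWeights[frames] else numeric()
  Ensemble(x@coords[, , frames, drop = FALSE], x@chain, x@resid, x@atomName,
           x@states[frames], pw / sum(pw),
           if (length(tw)) tw / sum(tw) else tw)
}

#' Refined frame weights of a BME fit
#'
#' @param x a [BMEResult-class].
#' @return numeric vector of refined weights.
#' @rdname refinedWeights
#' @export
setMethod("refinedWeights", "BMEResult", function(x) x@weights)

#' @export
setMethod("show", "BMEResult", function(object) {
  cat(sprintf("BMEResult: theta = %.4g, chi2 = %.4g (prior %.4g), Neff = %.1f\n",
              object@theta, object@chi2, object@chi2Prior, object@neff))
  if (length(object@stateContributions)) {
    cat("  state contributions:",
        paste(sprintf("%s = %.3f", names(object@stateContributions),
                      object@stateContributions), collapse = ", "), "\n")
  }
})

#' @export
setMethod("show", "LandscapeModel", function(object) {
  cat("LandscapeModel:", nrow(object@features), "frames,",
      ncol(object@features), "segment-pair features,",
      ncol(object@pcScores), "PCs\n")
  if (length(object@clusters))
    cat("  clusters:", length(unique(object@clusters)),
        sprintf("(%s)", object@clusterMethod), "\n")
})

#' @export
setMethod("show", "EntropyProfile", function(object) {
  cat("EntropyProfile:", nrow(object@profile), "residue rows,",
      object@nBins, "bins, T =", object@temperature, "K\n")
})
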