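#' @useDynLib PREnsemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Ensemble of conformations for a one- or two-chain system
#'
#' Frames of 3D coordinates (in Angstrom) for named chains, one row per
#' particle (coarse bead or backbone atom), with a state label and a prior
#' weight per frame.  Native author residue numbering is preserved in
#' `resid`; particles are identified by `(chain, resid, atomName)`.
#'
#' @slot coords numeric array, `nParticles x 3 x nFrames`.
#' @slot chain character, chain identifier per particle (e.g. `"A"`, `"B"`).
#' @slot resid integer, native residue number per particle.
#' @slot atomName character, particle name per particle (`"CA"` for coarse
#'   beads; `"N"`, `"CA"`, `"C"`, `"O"` for backbone frames).
#' @slot states character, state label per frame (e.g. `"I"` to `"IV"`).
#' @slot priorWeights numeric, prior frame weight \eqn{w_j^0}; non-negative,
#'   sums to 1.
#' @slot trueWeights numeric, optional ground-truth frame weights (length 0
#'   when unknown); used by the synthetic generator.
#'
#' @export
setClass("Ensemble",
  representation(coords = "array", chain = "character", resid = "integer",
                 atomName = "character", states = "character",
                 priorWeights = "numeric", trueWeights = "numeric"),
  validity = function(object) {
    d <- dim(object@coords)
    msg <- character()
    if (length(d) != 3L || d[2] != 3L)
      msg <- c(msg, "coords must be an nParticles x 3 x nFrames array")
    np <- d[1]; nf <- d[3]
    if (length(object@chain) != np) msg <- c(msg, "chain length != nParticles")
    if (length(object@resid) != np) msg <- c(msg, "resid length != nParticles")
    if (length(object@atomName) != np) msg <- c(msg, "atomName length != nParticles")
    if (length(object@states) != nf) msg <- c(msg, "states length != nFrames")
    if (length(object@priorWeights) != nf)
      msg <- c(msg, "priorWeights length != nFrames")
    else {
      if (any(object@priorWeights < 0)) msg <- c(msg, "priorWeights must be non-negative")
      if (nf > 0 && abs(sum(object@priorWeights) - 1) > 1e-8)
        msg <- c(msg, "priorWeights must sum to 1")
    }
    if (length(object@trueWeights) && length(object@trueWeights) != nf)
      msg <- c(msg, "trueWeights length != nFrames")
    if (length(msg)) msg else TRUE
  })

#' Per-frame PRE rates for one spin-label site
#'
#' Matrix of back-calculated transverse PRE rates \eqn{\Gamma_2} (s^-1),
#' residues of the observed chain by frames, for a single spin-label site.
#'
#' @slot site list with `chain`, `resid`, `label` describing the label site.
#' @slot residues integer, native residue numbers of the observed chain rows.
#' @slot gamma2 numeric matrix, residues x frames, \eqn{\Gamma_2 \ge 0}.
#' @slot cap numeric, the truncation ceiling used downstream (s^-1).
#'
#' @export
setClass("Gamma2Profile",
  representation(site = "list", residues = "integer", gamma2 = "matrix",
                 cap = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@gamma2) != length(object@residues))
      msg <- c(msg, "gamma2 rows != residues length")
    if (any(object@gamma2 < 0)) msg <- c(msg, "gamma2 must be non-negative")
    if (length(object@cap) != 1L || object@cap <= 0) msg <- c(msg, "cap must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Result of a Bayesian maximum-entropy reweighting fit
#'
#' @slot theta numeric, the entropy/fit trade-off parameter.
#' @slot lambda numeric, one Lagrange multiplier per experimental row.
#' @slot weights numeric, refined frame weights (non-negative, sum 1).
#' @slot priors numeric, prior frame weights.
#' @slot chi2 numeric, variance-scaled mean square error at the optimum.
#' @slot chi2Prior numeric, the same statistic under the prior weights.
#' @slot cost numeric, dual cost at the optimum.
#' @slot neff numeric, Kish effective sample size of the refined weights.
#' @slot stateContributions numeric, named aggregate weight per state (sums to 1).
#' @slot convergence list with `gradNorm`, `iterations`, `converged`.
#'
#' @export
setClass("BMEResult",
  representation(theta = "numeric", lambda = "numeric", weights = "numeric",
                 priors = "numeric", chi2 = "numeric", chi2Prior = "numeric",
                 cost = "numeric", neff = "numeric",
                 stateContributions = "numeric", convergence = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
    if (length(object@chi2) && object@chi2 < 0) msg <- c(msg, "chi2 must be >= 0")
    if (length(object@stateContributions) &&
        abs(sum(object@stateContributions) - 1) > 1e-6)
      msg <- c(msg, "state contributions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Reduced-dimension model of the bound-chain conformational landscape
#'
#' Holds the segment-pair distance features, the principal-component basis,
#' the 2-D embedding, cluster labels and weighted cluster contributions.
#'
#' @slot segments integer matrix, `nSegments x 2` first/last residue (native
#'   numbering) of each 4-residue window.
#' @slot pairs integer matrix, retained segment pairs (`nFeatures x 2`).
#' @slot features numeric matrix, frames x features (minimum CA distances, A).
#' @slot pcBasis numeric matrix, features x nPC rotation.
#' @slot pcScores numeric matrix, frames x nPC.
#' @slot pcSdev numeric, component standard deviations (non-increasing).
#' @slot center numeric, feature means used for centering.
#' @slot trainIdx integer, frames used to train the 2-D embedding.
#' @slot embedding numeric matrix, frames x 2.
#' @slot clusters integer, cluster label per frame.
#' @slot clusterMethod character, `"louvain"` or `"kmeans"`.
#' @slot contributions numeric, named weighted contribution per cluster.
#'
#' @export
setClass("LandscapeModel",
  representation(segments = "matrix", pairs = "matrix", features = "matrix",
                 pcBasis = "matrix", pcScores = "matrix", pcSdev = "numeric",
                 center = "numeric", trainIdx = "integer", embedding = "matrix",
                 clusters = "integer", clusterMethod = "character",
                 contributions = "numeric"))

#' Residue-wise torsion-angle conformational entropy profile
#'
#' @slot profile data.frame with columns `residue`, `S` (nats), `ST`
#'   (J/mol; S x R x T) and optionally `state`.
#' @slot perTorsion data.frame with columns `residue`, `torsion`, `S`.
#' @slot nBins integer, histogram bin count per torsion.
#' @slot binWidth numeric, bin width in radians.
#' @slot temperature numeric, temperature in K for the energy form.
#'
#' @export
setClass("EntropyProfile",
  representation(profile = "data.frame", perTorsion = "data.frame",
                 nBins = "integer", binWidth = "numeric",
                 temperature = "numeric"))
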