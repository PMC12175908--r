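#' Extract torsion angles from an ensemble
#'
#' With full backbone frames (N, CA, C particles) the proper phi/psi
#' dihedrals are computed (omega is excluded as essentially rigid);
#' side-chain chi angles are included when the required atoms are present.
#' For coarse CA-only ensembles a pseudo-dihedral per residue (the torsion
#' of four consecutive CA beads, centred on the bond i..i+1) is used
#' instead.  Terminal residues yield only the defined subset; missing
#' torsions are absent rather than zero.
#'
#' @param ensemble an [Ensemble-class].
#' @param chain chain to analyze (default `"A"`).
#' @return list of class `TorsionSet`: `angles` is a named list (per
#'   torsion id `"<residue>:<name>"`) of per-frame angle vectors (radians,
#'   wrapped to `[-pi, pi)`), plus `residue` and `torsion` lookup vectors.
#' @export
extractTorsions <- function(ensemble, chain = "A") {
  nm <- ensemble@atomName[ensemble@chain == chain]
  backbone <- all(c("N", "CA", "C") %in% nm)
  nf <- nFrames(ensemble)
  angles <- list(); residue <- integer(); torsion <- character()
  # vectorized dihedral over frames: a,b,c,d are nf x 3 trajectories
  vecDihedral <- function(a, b, c, d) {
    b1 <- b - a; b2 <- c - b; b3 <- d - c
    cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    b2n <- sqrt(rowSums(b2^2))
    x <- rowSums(n1 * n2)
    y <- rowSums(cross(n1, n2) * (b2 / b2n))
    wrapAngle(atan2(y, x))
  }
  traj <- function(i) t(ensemble@coords[i, , ])
  addTorsion <- function(r, name, idx4) {
    vals <- vecDihedral(traj(idx4[1]), traj(idx4[2]), traj(idx4[3]),
                        traj(idx4[4]))
    id <- paste0(r, ":", name)
    angles[[id]] <<- vals
    residue <<- c(residue, r)
    torsion <<- c(torsion, name)
  }
  res <- sort(unique(ensemble@resid[ensemble@chain == chain]))
  if (backbone) {
    at <- function(r, a) particleIndices(ensemble, chain, r, a)[1]
    for (r in res) {
      iN <- at(r, "N"); iCA <- at(r, "CA"); iC <- at(r, "C")
      if (anyNA(c(iN, iCA, iC))) next
      iCprev <- if ((r - 1) %in% res) at(r - 1, "C") else NA
      iNnext <- if ((r + 1) %in% res) at(r + 1, "N") else NA
      if (!is.na(iCprev)) addTorsion(r, "phi", c(iCprev, iN, iCA, iC))
      if (!is.na(iNnext)) addTorsion(r, "psi", c(iN, iCA, iC, iNnext))
    }
  } else {
    ca <- particleIndices(ensemble, chain = chain, atomName = "CA")
    ca <- ca[order(ensemble@resid[ca])]
    n <- length(ca)
    if (n >= 4) {
      for (k in 2:(n - 2))
        addTorsion(res[k], "zeta", ca[(k - 1):(k + 2)])
    }
  }
  structure(list(angles = angles, residue = residue, torsion = torsion,
                 nFrames = nf), class = "TorsionSet")
}

#' Shannon entropy of one torsion angle
#'
#' Histogram estimator over `nBins` equal bins of `[-pi, pi)` with
#' reweighted bin probabilities, including the discretization and
#' undersampling corrections:
#' \deqn{S = -\left[\sum_i P_i \ln(P_i h) + \frac{n-1}{2N}\right]}
#' (`h` = bin width in radians, `N` = frame count).  Empty bins contribute
#' zero.  `correction = "additive"` gives the conventional Miller-Madow
#' form (the finite-sample term added instead); `"none"` drops it.
#'
#' @param angles per-frame angles in radians.
#' @param weights frame weights (default uniform); normalized internally.
#' @param nBins bin count (default 35).
#' @param correction `"printed"` (default), `"additive"` or `"none"`.
#' @param nEff frame count used in the undersampling term (default the
#'   number of frames; set to an effective sample size to switch
#'   conventions).
#' @return entropy in nats.
#' @export
torsionEntropy <- function(angles, weights = NULL, nBins = 35L,
                           correction = c("printed", "additive", "none"),
                           nEff = NULL) {
  correction <- match.arg(correction)
  N <- length(angles)
  stopifnot(N >= 1)
  if (is.null(weights)) weights <- rep(1 / N, N)
  weights <- weights / sum(weights)
  if (is.null(nEff)) nEff <- N
  h <- 2 * pi / nBins
  bin <- pmin(floor((wrapAngle(angles) + pi) / h) + 1L, nBins)
  P <- vapply(split(weights, factor(bin, levels = seq_len(nBins))), sum,
              numeric(1))
  nz <- P > 0
  plug <- -sum(P[nz] * log(P[nz] * h))
  corr <- (nBins - 1) / (2 * nEff)
  switch(correction,
         printed = plug - corr,
         additive = plug + corr,
         none = plug)
}

#' Residue-wise entropy profile
#'
#' Entropies of all torsions of a residue are summed to the residue-wise
#' conformational entropy; the energy form is `ST = S * R * T` with
#' `R = 8.314 J/(mol K)`.
#'
#' @param torsions a `TorsionSet` from [extractTorsions()].
#' @param weights frame weights (default uniform).
#' @param nBins histogram bins per torsion (default 35).
#' @param temperature in Kelvin (default 310).
#' @param correction,nEff forwarded to [torsionEntropy()].
#' @return an [EntropyProfile-class].
#' @export
residueEntropyProfile <- function(torsions, weights = NULL, nBins = 35L,
                                  temperature = 310,
                                  correction = "printed", nEff = NULL) {
  R <- 8.314
  perT <- data.frame(
    residue = torsions$residue, torsion = torsions$torsion,
    S = vapply(torsions$angles, torsionEntropy, numeric(1),
               weights = weights, nBins = nBins, correction = correction,
               nEff = nEff))
  rownames(perT) <- NULL
  S <- tapply(perT$S, perT$residue, sum)
  prof <- data.frame(residue = as.integer(names(S)), S = as.numeric(S),
                     ST = as.numeric(S) * R * temperature)
  rownames(prof) <- NULL
  new("EntropyProfile", profile = prof, perTorsion = perT,
      nBins = as.integer(nBins), binWidth = 2 * pi / nBins,
      temperature = temperature)
}

#' Per-state entropy profiles
#'
#' Restricts and renormalizes the frame weights within each state and
#' recomputes the residue-wise profile, yielding one entropy track per
#' bound configuration.
#'
#' @param torsions a `TorsionSet`.
#' @param weights refined frame weights.
#' @param states per-frame state labels.
#' @param ... forwarded to [residueEntropyProfile()].
#' @return named list of [EntropyProfile-class], one per state.
#' @export
entropyByState <- function(torsions, weights, states, ...) {
  out <- list()
  for (s in unique(states)) {
    w <- ifelse(states == s, weights, 0)
    if (sum(w) <= 0) stop("zero total weight in state ", s)
    out[[s]] <- residueEntropyProfile(torsions, weights = w / sum(w), ...)
  }
  out
}

#' Entropy comparison between contact classes
#'
#' Classifies residues into low (`< low`) and high (`> high`) contact
#' frequency groups for a given per-residue contact frequency track, and
#' compares their entropies with a two-sided Wilcoxon rank-sum test.
#' Groups with fewer than 3 members are flagged and not tested.
#'
#' @param profile an [EntropyProfile-class] (or its `profile` data.frame).
#' @param contactFrequency named numeric, per-residue contact frequency in
#'   `[0, 1]` (names are residue numbers).
#' @param low,high classification thresholds (defaults 0.2 and 0.6).
#' @return list: `groups` (data.frame residue, S, ST, class), `p`
#'   (Wilcoxon p-value or NA), `significance` (`"**"` p<=0.01, `"*"`
#'   0.01-0.05, `"NS"` >0.05), `tested`.
#' @export
entropyContactComparison <- function(profile, contactFrequency, low = 0.2,
                                     high = 0.6) {
  prof <- if (is(profile, "EntropyProfile")) profile@profile else profile
  cf <- contactFrequency[as.character(prof$residue)]
  cls <- ifelse(is.na(cf), NA,
                ifelse(cf < low, "low", ifelse(cf > high, "high", NA)))
  groups <- cbind(prof, class = cls)
  lowS <- prof$S[!is.na(cls) & cls == "low"]
  highS <- prof$S[!is.na(cls) & cls == "high"]
  if (length(lowS) < 3 || length(highS) < 3) {
    return(list(groups = groups, p = NA_real_, significance = NA_character_,
                tested = FALSE))
  }
  p <- stats::wilcox.test(lowS, highS, exact = FALSE)$p.value
  sig <- if (p <= 0.01) "**" else if (p <= 0.05) "*" else "NS"
  list(groups = groups, p = p, significance = sig, tested = TRUE)
}
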