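#' Physical constants and acquisition parameters for PRE back-calculation
#'
#' Bundles the SI constants and the NMR parameters entering the
#' Solomon-Bloembergen transverse PRE rate, and derives the proton Larmor
#' angular frequency and the combined label correlation time
#' `1/taut = 1/tauc + 1/taui`.
#'
#' @param field spectrometer 1H frequency in MHz (default 600).
#' @param tauc rotational correlation time of the complex in seconds
#'   (default 29 ns, the molecular-weight estimate for a 47.8 kDa complex).
#' @param taui spin-label correlation time in seconds (default 500 ps).
#' @param td total INEPT transfer time in seconds (default 10 ms).
#' @param r2red diamagnetic transverse relaxation rate in s^-1 (default 40).
#' @param cap truncation ceiling for Gamma2 in s^-1 (default 450).
#' @return list of class `PhysicalConstants` including the dipolar
#'   `prefactor` (m^6 s^-2), `omegaI` (rad/s) and `taut` (s).
#' @export
physicalConstants <- function(field = 600, tauc = 29e-9, taui = 500e-12,
                              td = 10e-3, r2red = 40, cap = 450) {
  stopifnot(field > 0, tauc > 0, taui > 0, td > 0, r2red > 0, cap > 0)
  mu0_4pi <- 1e-7                      # T m / A
  gammaI  <- 2.6752218744e8            # rad s^-1 T^-1
  g       <- 2.00231930436             # electron g-factor
  muB     <- 9.2740100783e-24          # J / T
  Se      <- 0.5
  structure(list(
    field = field,
    omegaI = 2 * pi * field * 1e6,
    tauc = tauc, taui = taui,
    taut = 1 / (1 / tauc + 1 / taui),
    td = td, r2red = r2red, cap = cap,
    gammaI = gammaI, g = g, muB = muB, Se = Se,
    prefactor = (1 / 15) * mu0_4pi^2 * gammaI^2 * g^2 * muB^2 * Se * (Se + 1)
  ), class = "PhysicalConstants")
}

#' Rotational correlation time from molecular weight
#'
#' Empirical scaling rule for globular proteins in aqueous solution,
#' tau_c ~ 0.6 ns per kDa; a 47.8 kDa complex gives 28.7 ns (29 ns rounded).
#'
#' @param massKDa molecular weight in kDa.
#' @param nsPerKDa slope of the empirical rule (default 0.6 ns/kDa).
#' @return tau_c estimate in nanoseconds.
#' @export
rotationalCorrelationTime <- function(massKDa, nsPerKDa = 0.6) {
  stopifnot(massKDa > 0)
  massKDa * nsPerKDa
}

#' Define a spin-label attachment site
#'
#' @param chain chain identifier carrying the label.
#' @param resid native residue number of the engineered cysteine.
#' @param label label chemistry tag (default `"MTSL"`).
#' @return list of class `SpinLabelSite`.
#' @export
spinLabelSite <- function(chain, resid, label = "MTSL") {
  structure(list(chain = chain, resid = as.integer(resid), label = label),
            class = "SpinLabelSite")
}

#' Default receptor spin-label layout
#'
#' Four sites on the receptor chain, two probing each binding face
#' (984 and 1006 near the alpha2/alpha3 face; 1018 and 1040 near the
#' alpha1/alpha4 face), following the E984C / Q1006C / K1018C / Q1040C
#' design.
#'
#' @param chain receptor chain id (default `"B"`).
#' @return list of [spinLabelSite()] objects.
#' @export
defaultLabelSites <- function(chain = "B") {
  lapply(c(984L, 1006L, 1018L, 1040L), function(r) spinLabelSite(chain, r))
}

# deterministic Fibonacci grid on a spherical cap around `axis`
fibonacciCone <- function(K, axis, coneHalf) {
  axis <- axis / sqrt(sum(axis^2))
  t <- if (abs(axis[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  v <- c(t[2] * axis[3] - t[3] * axis[2],
         t[3] * axis[1] - t[1] * axis[3],
         t[1] * axis[2] - t[2] * axis[1])
  v <- v / sqrt(sum(v^2))
  w <- c(axis[2] * v[3] - axis[3] * v[2],
         axis[3] * v[1] - axis[1] * v[3],
         axis[1] * v[2] - axis[2] * v[1])
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(K) - 1L
  ct <- 1 - (1 - cos(coneHalf)) * ((k + 0.5) / K)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- golden * k
  outer(ct, axis) + st * (outer(cos(ph), v) + outer(sin(ph), w))
}

#' Place pseudo-rotamer electron positions for a spin label
#'
#' Generates `nRotamers` candidate electron (nitroxide-midpoint) positions on
#' a tether-length spherical cap oriented away from the host chain, and
#' weights them by Boltzmann factors of a soft-sphere clash energy against
#' all other particles.  A fully buried candidate receives negligible
#' weight.  The construction is deterministic for a given frame.
#'
#' @param ensemble an [Ensemble-class].
#' @param frame frame index.
#' @param site a [spinLabelSite()].
#' @param nRotamers number of candidate positions (default 16).
#' @param tether electron-to-backbone tether length in Angstrom (default 8,
#'   a three-bond MTSL arm).
#' @param coneHalf cap half-angle in radians (default 75 deg).
#' @param clashSigma soft-sphere radius in Angstrom (default 3.5).
#' @param clashEps soft-sphere energy scale in kT (default 2).
#' @return list of class `RotamerCloud` with `positions` (K x 3), `probs`,
#'   `attach` and the site.
#' @export
placeLabelRotamers <- function(ensemble, frame, site, nRotamers = 16,
                               tether = 8, coneHalf = 75 * pi / 180,
                               clashSigma = 3.5, clashEps = 2) {
  idx <- particleIndices(ensemble, chain = site$chain, resid = site$resid)
  if (!length(idx))
    stop("attachment residue ", site$resid, " not found in chain ", site$chain)
  idx <- idx[1]
  xyz <- ensemble@coords[, , frame, drop = FALSE]
  dim(xyz) <- dim(ensemble@coords)[1:2]
  at <- xyz[idx, ]
  host <- which(ensemble@chain == site$chain)
  cen <- colMeans(xyz[host, , drop = FALSE])
  axis <- at - cen
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(1, 0, 0)
  dirs <- fibonacciCone(nRotamers, axis, coneHalf)
  pos <- sweep(dirs * tether, 2, at, "+")
  excl <- particleIndices(ensemble, chain = site$chain,
                          resid = (site$resid - 1L):(site$resid + 1L))
  other <- setdiff(seq_len(nrow(xyz)), excl)
  E <- numeric(nRotamers)
  if (length(other)) {
    for (k in seq_len(nRotamers)) {
      r2 <- rowSums(sweep(xyz[other, , drop = FALSE], 2, pos[k, ])^2)
      r2 <- pmax(r2, 1e-4)
      s2 <- clashSigma^2 / r2
      s2 <- s2[s2 > 0.04]
      E[k] <- clashEps * sum((s2^3)^2)
    }
  }
  p <- exp(-(E - min(E)))
  structure(list(positions = pos, probs = p / sum(p), attach = at,
                 site = site), class = "RotamerCloud")
}

#' Solomon-Bloembergen Gamma2 for one frame
#'
#' Computes the transverse PRE rate
#' \deqn{\Gamma_2 = \frac{1}{15}\left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_I^2 g^2 \mu_B^2 S_e(S_e+1)\,[4J(0) + 3J(\omega_I)]}
#' with the spectral density
#' \deqn{J(\omega) = \langle r^{-6}\rangle\left[\frac{S^2\tau_c}
#'   {1+\omega^2\tau_c^2} + \frac{(1-S^2)\tau_t}{1+\omega^2\tau_t^2}\right]}
#' where the order parameter factorizes as `S2 = S2radial * S2angular`,
#' `S2radial = <r^-3>^2 / <r^-6>`, and the angular part is the second-rank
#' tensor order parameter of the electron-proton unit vectors averaged over
#' rotamers (weighted by `p_k r_k^-3`).
#'
#' @param cloud a `RotamerCloud` from [placeLabelRotamers()].
#' @param amidePositions numeric `n x 3` matrix of amide proton positions (A).
#' @param constants a [physicalConstants()] list.
#' @return numeric Gamma2 per row of `amidePositions` (s^-1), with
#'   attributes `S2`, `S2angular`, `S2radial`.
#' @export
gamma2Frame <- function(cloud, amidePositions, constants) {
  if (is.null(dim(amidePositions))) amidePositions <- matrix(amidePositions, ncol = 3)
  K <- nrow(cloud$positions)
  n <- nrow(amidePositions)
  g2 <- s2a <- s2r <- numeric(n)
  p <- cloud$probs
  om <- constants$omegaI
  dc <- constants$tauc / (1 + om^2 * constants$tauc^2)
  dt <- constants$taut / (1 + om^2 * constants$taut^2)
  for (i in seq_len(n)) {
    d <- matrix(amidePositions[i, ], K, 3, byrow = TRUE) - cloud$positions
    rA <- sqrt(rowSums(d^2))
    if (any(rA < 1e-6)) stop("coincident electron and proton positions")
    rA <- pmax(rA, 1e-3)
    rm <- rA * 1e-10
    r3 <- rm^-3; r6 <- rm^-6
    m3 <- sum(p * r3); m6 <- sum(p * r6)
    e <- d / rA
    q <- p * r3 / m3
    M <- crossprod(e * sqrt(q))          # sum_k q_k e e^T
    s2a[i] <- min(max(1.5 * sum(M^2) - 0.5, 0), 1)
    s2r[i] <- m3^2 / m6
    S2 <- s2a[i] * s2r[i]
    J0 <- m6 * (S2 * constants$tauc + (1 - S2) * constants$taut)
    Jw <- m6 * (S2 * dc + (1 - S2) * dt)
    g2[i] <- constants$prefactor * (4 * J0 + 3 * Jw)
  }
  structure(g2, S2 = s2a * s2r, S2angular = s2a, S2radial = s2r)
}

#' Ensemble-averaged Gamma2
#'
#' Weighted average over frames, `Gamma2_i = sum_j w_j Gamma2_{i,j}`.
#'
#' @param profile a [Gamma2Profile-class] or a residues x frames matrix.
#' @param weights frame weights summing to 1.
#' @return numeric averaged Gamma2 per residue.
#' @export
gamma2Ensemble <- function(profile, weights) {
  m <- if (is(profile, "Gamma2Profile")) profile@gamma2 else profile
  if (ncol(m) != length(weights))
    stop("weight length (", length(weights), ") != frame count (", ncol(m), ")")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  drop(m %*% weights)
}

#' Gamma2 to HSQC intensity ratio
#'
#' Exponential attenuation of the amide magnetization during the INEPT
#' period: `ratio = R2red exp(-Gamma2 td) / (R2red + Gamma2)`.
#'
#' @param gamma2 numeric Gamma2 values (s^-1), `>= 0`.
#' @param constants a [physicalConstants()] list (uses `r2red`, `td`).
#' @return intensity ratios in (0, 1].
#' @export
gamma2ToIntensity <- function(gamma2, constants) {
  stopifnot(all(gamma2 >= 0))
  constants$r2red * exp(-gamma2 * constants$td) / (constants$r2red + gamma2)
}

#' Invert an intensity ratio to Gamma2
#'
#' The forward map is strictly decreasing in Gamma2, so the inverse is found
#' by bracketed bisection on `[0, cap]`.  Ratios `>= 1` map to 0; ratios at
#' or below the value attained at the cap (and non-positive ratios) are
#' truncated to the cap, mirroring the ceiling used to stabilize
#' reweighting.
#'
#' @param ratio numeric intensity ratios.
#' @param constants a [physicalConstants()] list.
#' @param cap truncation ceiling in s^-1 (default `constants$cap`).
#' @return numeric Gamma2 (s^-1) with attribute `capped` (logical).
#' @export
intensityToGamma2 <- function(ratio, constants, cap = constants$cap) {
  n <- length(ratio)
  out <- numeric(n)
  capped <- logical(n)
  rAtCap <- gamma2ToIntensity(cap, constants)
  for (i in seq_len(n)) {
    x <- ratio[i]
    if (is.na(x)) { out[i] <- NA_real_; next }
    if (x >= 1) { out[i] <- 0; next }
    if (x <= rAtCap) { out[i] <- cap; capped[i] <- TRUE; next }
    lo <- 0; hi <- cap
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (gamma2ToIntensity(mid, constants) > x) lo <- mid else hi <- mid
    }
    out[i] <- (lo + hi) / 2
  }
  attr(out, "capped") <- capped
  out
}

#' Back-calculate per-frame Gamma2 profiles for spin-label sites
#'
#' Batch path over all frames (compiled kernel) using the same pseudo-rotamer
#' construction and Solomon-Bloembergen expressions as
#' [placeLabelRotamers()] + [gamma2Frame()].
#'
#' @param ensemble an [Ensemble-class].
#' @param sites list of [spinLabelSite()] (default [defaultLabelSites()]).
#' @param constants a [physicalConstants()] list.
#' @param observedChain chain whose amides are observed (default `"A"`).
#' @param nRotamers,tether,coneHalf,clashSigma,clashEps rotamer-cloud
#'   parameters, as in [placeLabelRotamers()].
#' @return named list of [Gamma2Profile-class], one per site.
#' @export
computeGamma2Profiles <- function(ensemble, sites = defaultLabelSites(),
                                  constants = physicalConstants(),
                                  observedChain = "A", nRotamers = 16,
                                  tether = 8, coneHalf = 75 * pi / 180,
                                  clashSigma = 3.5, clashEps = 2) {
  protonIdx <- particleIndices(ensemble, chain = observedChain, atomName = "CA")
  residues <- ensemble@resid[protonIdx]
  out <- list()
  for (s in sites) {
    aidx <- particleIndices(ensemble, chain = s$chain, resid = s$resid)
    if (!length(aidx))
      stop("label site residue ", s$resid, " not found in chain ", s$chain)
    cidx <- which(ensemble@chain == s$chain)
    eidx <- particleIndices(ensemble, chain = s$chain,
                            resid = (s$resid - 1L):(s$resid + 1L))
    G <- cpp_gamma2_site(as.numeric(ensemble@coords), dim(ensemble@coords),
                         protonIdx - 1L, aidx[1] - 1L, cidx - 1L, eidx - 1L,
                         as.integer(nRotamers), tether, coneHalf,
                         clashSigma, clashEps, constants$prefactor,
                         constants$tauc, constants$taut, constants$omegaI)
    out[[paste0(s$chain, s$resid)]] <-
      new("Gamma2Profile", site = unclass(s), residues = as.integer(residues),
          gamma2 = G, cap = constants$cap)
  }
  out
}
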