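#' Smooth experimental PRE intensity profiles
#'
#' Per-site LOESS of the intensity ratio over residue number (span 0.2 by
#' default), the standard pre-processing step before converting ratios to
#' Gamma2 for reweighting.  Smoothed values are clipped to `[0, 1.2]`; raw
#' values are retained.  Sites with fewer than `minPoints` usable rows are
#' passed through unsmoothed with a warning.
#'
#' @param table data.frame with columns `site`, `residue`, `ratio`.
#' @param span LOESS span (default 0.2).
#' @param minPoints minimum rows per site (default 5).
#' @return the table with an added `smoothed` column.
#' @export
smoothExperimental <- function(table, span = 0.2, minPoints = 5) {
  table$smoothed <- NA_real_
  for (s in unique(table$site)) {
    i <- which(table$site == s & !is.na(table$ratio))
    if (length(i) < minPoints) {
      warning("site ", s, ": fewer than ", minPoints,
              " points; left unsmoothed")
      table$smoothed[i] <- table$ratio[i]
      next
    }
    # loess needs enough points in the local window
    sp <- max(span, min(1, 5 / length(i)))
    fit <- stats::loess(ratio ~ residue, data = table[i, ], span = sp,
                        degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    table$smoothed[i] <- pmin(pmax(stats::predict(fit), 0), 1.2)
  }
  table
}

#' Attach an error model to a PRE table
#'
#' Inverse-intensity variance model `sigma_i^2 = scale / max(ratio_i, floor)`
#' (in Gamma2^2 units), so weak peaks (strong PREs) carry larger assumed
#' error; a constant-variance mode is available.
#'
#' @param table data.frame with `ratio` (and optionally `smoothed`).
#' @param scale variance scale (default 1).
#' @param floor lower clamp on the ratio (default 0.05).
#' @param mode `"inverse"` (default) or `"constant"`.
#' @return the table with an added `sigma2` column.
#' @export
buildErrorModel <- function(table, scale = 1, floor = 0.05,
                            mode = c("inverse", "constant")) {
  mode <- match.arg(mode)
  r <- if (!is.null(table$smoothed) && !all(is.na(table$smoothed)))
    table$smoothed else table$ratio
  table$sigma2 <- if (mode == "constant") rep(scale, nrow(table))
                  else scale / pmax(r, floor)
  table
}

#' Prepare a PRE table for reweighting
#'
#' Smooths (optionally), converts intensity ratios to capped Gamma2 via the
#' inverse of the forward intensity map, and attaches the error model.
#'
#' @param table data.frame with `site`, `chain`, `residue`, `ratio`.
#' @param constants a [physicalConstants()].
#' @param smooth apply [smoothExperimental()] first (default TRUE).
#' @param span LOESS span.
#' @param errorScale,errorFloor,errorMode forwarded to [buildErrorModel()].
#' @param cap Gamma2 ceiling (default `constants$cap`).
#' @return the table with `smoothed`, `gamma2exp`, `capped`, `sigma2`.
#' @export
preparePRETable <- function(table, constants = physicalConstants(),
                            smooth = TRUE, span = 0.2, errorScale = 1,
                            errorFloor = 0.05, errorMode = "inverse",
                            cap = constants$cap) {
  if (smooth) table <- smoothExperimental(table, span = span)
  else table$smoothed <- table$ratio
  g <- intensityToGamma2(table$smoothed, constants, cap = cap)
  table$gamma2exp <- as.numeric(g)
  table$capped <- attr(g, "capped")
  buildErrorModel(table, scale = errorScale, floor = errorFloor,
                  mode = errorMode)
}

#' Variance-scaled mean square error
#'
#' `chi2 = (1/m) sum (Gamma2exp - Gamma2pred)^2 / sigma2`.
#'
#' @param predicted,experimental numeric vectors of Gamma2.
#' @param sigma2 per-row variances.
#' @return chi-squared per data point.
#' @export
chi2Stat <- function(predicted, experimental, sigma2) {
  m <- length(experimental)
  if (m == 0L) stop("no experimental rows")
  if (length(predicted) != m || length(sigma2) != m)
    stop("length mismatch between predicted, experimental and sigma2")
  mean((experimental - predicted)^2 / sigma2)
}

# Dual cost and gradient in preconditioned coordinates.
#
# The dual is invariant under shifting each observable row and its target by
# the same constant, and reparametrizing lambda_i = nu_i / s_i turns the
# penalty into a diagonal quadratic with coefficients theta * sigma_i^2 /
# s_i^2.  Centering rows by their prior means and scaling to unit prior
# standard deviation makes the Hessian (a prior covariance of the scaled
# rows plus the diagonal penalty) well conditioned.
bmeDual <- function(B, y, pen, logw0) {
  list(
    fn = function(nu) {
      a <- logw0 - drop(crossprod(B, nu))
      M <- max(a)
      logZ <- M + log(sum(exp(a - M)))
      logZ + sum(nu * y) + sum(pen / 2 * nu^2)
    },
    gr = function(nu) {
      a <- logw0 - drop(crossprod(B, nu))
      M <- max(a)
      w <- exp(a - M); w <- w / sum(w)
      y - drop(B %*% w) + pen * nu
    },
    weights = function(nu) {
      a <- logw0 - drop(crossprod(B, nu))
      M <- max(a)
      w <- exp(a - M)
      w / sum(w)
    })
}

#' Fit refined frame weights by maximum entropy (BME dual)
#'
#' Minimizes the convex dual cost
#' \deqn{C(\lambda) = \log Z(\lambda) + \sum_i \lambda_i \Gamma_{2,i}^{exp}
#'   + \frac{\theta}{2}\sum_i \lambda_i^2 \sigma_i^2}
#' by L-BFGS with the analytic gradient, then forms
#' \eqn{w_j = w_j^0 \exp(-\sum_i \lambda_i \Gamma_{2,i,j}) / Z}.
#'
#' @param gammaMatrix numeric `m x nFrames` matrix of per-frame Gamma2
#'   (rows ordered as `gammaExp`).
#' @param gammaExp experimental Gamma2 per row.
#' @param sigma2 error variances per row.
#' @param theta trade-off parameter (> 0).
#' @param priors prior frame weights (default uniform).
#' @param states optional per-frame state labels for aggregate
#'   contributions.
#' @param lambda0 warm-start multipliers (default 0).
#' @param gradTol convergence threshold on the gradient norm (default 1e-8,
#'   evaluated on the sigma-scaled problem).
#' @param maxit L-BFGS iteration budget per restart (default 4000).
#' @param restarts additional warm restarts if not converged (default 2).
#' @param strict error (instead of warn) when the gradient norm target is
#'   missed (default FALSE).
#' @param capMatrix also cap the calculated frame Gamma2 at `cap` before
#'   fitting (default FALSE: the truncation applies to the experimental
#'   values only, and capping the per-frame predictions makes an otherwise
#'   consistent target unreachable).
#' @param cap ceiling used when `capMatrix` (default 450).
#' @return a [BMEResult-class].
#' @export
fitWeights <- function(gammaMatrix, gammaExp, sigma2, theta,
                       priors = NULL, states = NULL, lambda0 = NULL,
                       gradTol = 1e-8, maxit = 4000L, restarts = 2L,
                       strict = FALSE, capMatrix = FALSE, cap = 450) {
  m <- length(gammaExp)
  nf <- ncol(gammaMatrix)
  stopifnot(nrow(gammaMatrix) == m, length(sigma2) == m, all(sigma2 > 0),
            theta >= 0)
  if (is.null(priors)) priors <- rep(1 / nf, nf)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  G <- if (capMatrix) pmin(gammaMatrix, cap) else gammaMatrix
  # precondition: center rows by their prior means (a dual invariance) and
  # scale to unit prior standard deviation; the penalty stays exact
  priorMean <- drop(G %*% priors)
  priorVar <- drop((G - priorMean)^2 %*% priors)
  sc <- sqrt(priorVar)
  sc <- pmax(sc, 1e-8 * max(sc, 1))
  B <- (G - priorMean) / sc
  y <- (gammaExp - priorMean) / sc
  pen <- theta * sigma2 / sc^2
  logw0 <- log(pmax(priors, 1e-300))
  dual <- bmeDual(B, y, pen, logw0)
  nu <- if (is.null(lambda0)) rep(0, m) else lambda0 * sc
  it <- 0L
  for (r in 0:restarts) {
    opt <- stats::optim(nu, dual$fn, dual$gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 100))
    nu <- opt$par
    it <- it + opt$counts[1]
    if (sqrt(sum(dual$gr(nu)^2)) < gradTol) break
  }
  gn <- sqrt(sum(dual$gr(nu)^2))
  conv <- gn < gradTol
  if (!conv) {
    msg <- sprintf("BME dual not converged to gradTol: |grad| = %.3g", gn)
    if (strict) stop(msg) else if (gn > 1e-3 * max(1, sqrt(sum(y^2)))) warning(msg)
  }
  w <- dual$weights(nu)
  pred <- drop(G %*% w)
  stateContr <- if (!is.null(states)) {
    agg <- tapply(w, states, sum)
    structure(as.numeric(agg) / sum(agg), names = names(agg))
  } else numeric()
  new("BMEResult", theta = theta, lambda = nu / sc, weights = w,
      priors = priors, chi2 = chi2Stat(pred, gammaExp, sigma2),
      chi2Prior = chi2Stat(drop(G %*% priors), gammaExp, sigma2),
      cost = dual$fn(nu), neff = 1 / sum(w^2),
      stateContributions = stateContr,
      convergence = list(gradNorm = gn, iterations = unname(it),
                         converged = conv))
}

#' Scan the entropy/fit trade-off parameter
#'
#' Fits at each theta of a decreasing grid with warm starts, records
#' chi-squared and the relative entropy of the refined weights, and selects
#' the largest theta beyond which a further 10-fold decrease improves
#' chi-squared by less than `elbowTol` (relative).
#'
#' @param gammaMatrix,gammaExp,sigma2,priors,states as in [fitWeights()].
#' @param grid decreasing theta grid (default 20 points, 1e4 to 1e-2,
#'   logarithmic).
#' @param elbowTol relative chi-squared improvement per decade below which
#'   the curve is considered flat (default 0.05).
#' @param ... forwarded to [fitWeights()].
#' @return list with `scan` (data.frame theta, chi2, entropy, neff,
#'   converged), `selected` theta, and `fit` (the [BMEResult-class] at the
#'   selected theta).
#' @export
thetaScan <- function(gammaMatrix, gammaExp, sigma2, priors = NULL,
                      states = NULL, grid = 10^seq(4, -2, length.out = 20),
                      elbowTol = 0.05, ...) {
  grid <- sort(grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  lam <- NULL
  rows <- list()
  for (i in seq_along(grid)) {
    f <- tryCatch(
      fitWeights(gammaMatrix, gammaExp, sigma2, grid[i], priors = priors,
                 states = states, lambda0 = lam, ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(theta = grid[i], chi2 = NA, entropy = NA,
                              neff = NA, converged = FALSE)
      next
    }
    fits[[i]] <- f
    lam <- f@lambda
    rel <- sum(f@weights * log(pmax(f@weights, 1e-300) / pmax(f@priors, 1e-300)))
    rows[[i]] <- data.frame(theta = grid[i], chi2 = f@chi2, entropy = rel,
                            neff = f@neff,
                            converged = f@convergence$converged)
  }
  scan <- do.call(rbind, rows)
  sel <- selectThetaElbow(scan$theta, scan$chi2, elbowTol)
  list(scan = scan, selected = sel,
       fit = fits[[which(scan$theta == sel)[1]]])
}

#' Elbow selection on a chi-squared vs theta curve
#'
#' Selects the largest theta such that decreasing theta by one decade
#' improves chi-squared by less than `elbowTol` relative (chi-squared at
#' theta/10 is interpolated on the log-theta grid).
#'
#' @param theta decreasing grid.
#' @param chi2 chi-squared at each grid point.
#' @param elbowTol relative improvement threshold (default 0.05).
#' @return the selected theta.
#' @export
selectThetaElbow <- function(theta, chi2, elbowTol = 0.05) {
  ok <- is.finite(chi2)
  th <- theta[ok]; ch <- chi2[ok]
  if (length(th) < 2) return(th[1])
  o <- order(th, decreasing = TRUE)
  th <- th[o]; ch <- ch[o]
  chiAt <- stats::approxfun(log10(th), ch, rule = 2)
  for (i in seq_along(th)) {
    drop10 <- ch[i] - chiAt(log10(th[i]) - 1)
    if (ch[i] <= 0 || drop10 / max(ch[i], .Machine$double.eps) < elbowTol)
      return(th[i])
  }
  th[length(th)]
}

#' Aggregate refined weights per state
#'
#' @param result a [BMEResult-class] (or numeric weights).
#' @param states per-frame state labels.
#' @return named numeric summing to 1.
#' @export
stateContributions <- function(result, states) {
  w <- if (is(result, "BMEResult")) result@weights else result
  if (length(states) != length(w)) stop("state labels must cover every frame")
  if (anyNA(states)) stop("unlabelled frames present")
  agg <- tapply(w, states, sum)
  structure(as.numeric(agg) / sum(agg), names = names(agg))
}

#' Reweight an ensemble against a PRE table
#'
#' End-to-end convenience wrapper: matches prepared experimental rows to the
#' per-site Gamma2 profiles, assembles the row-by-frame matrix, runs the
#' theta scan (or a fixed theta) and returns the selected fit with per-state
#' contributions.
#'
#' @param ensemble an [Ensemble-class].
#' @param profiles named list of [Gamma2Profile-class] (one per site).
#' @param preTable a table from [preparePRETable()].
#' @param theta `"scan"` (default) or a fixed positive value.
#' @param grid theta grid when scanning.
#' @param ... forwarded to [fitWeights()].
#' @return list with `fit` ([BMEResult-class]), `scan` (or NULL), `rows`
#'   (the matched table).
#' @export
bmeReweight <- function(ensemble, profiles, preTable, theta = "scan",
                        grid = 10^seq(4, -2, length.out = 20), ...) {
  keep <- !is.na(preTable$gamma2exp) & preTable$sigma2 > 0
  tab <- preTable[keep, ]
  Gs <- list()
  for (i in seq_len(nrow(tab))) {
    pr <- profiles[[tab$site[i]]]
    if (is.null(pr)) stop("no Gamma2 profile for site ", tab$site[i])
    j <- match(tab$residue[i], pr@residues)
    if (is.na(j)) stop("residue ", tab$residue[i], " missing from profile ",
                       tab$site[i])
    Gs[[i]] <- pr@gamma2[j, ]
  }
  G <- do.call(rbind, Gs)
  pri <- priorWeights(ensemble)
  st <- stateLabels(ensemble)
  if (identical(theta, "scan")) {
    sc <- thetaScan(G, tab$gamma2exp, tab$sigma2, priors = pri, states = st,
                    grid = grid, ...)
    list(fit = sc$fit, scan = sc$scan, selected = sc$selected, rows = tab)
  } else {
    fit <- fitWeights(G, tab$gamma2exp, tab$sigma2, theta, priors = pri,
                      states = st, ...)
    list(fit = fit, scan = NULL, selected = theta, rows = tab)
  }
}
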