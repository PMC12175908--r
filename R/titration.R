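#' Fraction-bound series from intensity retention
#'
#' `fb(L) = 1 - I/I0`, clipped to `[0, 1]`; the zero-ligand point is forced
#' to exactly 0.
#'
#' @param series a `TitrationSeries` data.frame (`residue`, `L`, `ratio`).
#' @return the series with an added `fb` column.
#' @export
fractionBoundSeries <- function(series) {
  if (is.null(series$ratio)) stop("missing I/I0 column")
  fb <- pmin(pmax(1 - series$ratio, 0), 1)
  fb[series$L == 0] <- 0
  series$fb <- fb
  series
}

#' Fit a dissociation constant per residue
#'
#' Least-squares fit of the single-site depletion isotherm
#' [fractionBound()] to the per-residue `fb(L)` curve, with receptor
#' depletion retained because the fixed receptor concentration is
#' comparable to the fitted constants.  `Kd` is optimized on a log scale
#' within `(1e-3, 1e6)`; an optional saturation amplitude `fbMax` can be
#' co-fitted.
#'
#' @param L ligand concentrations.
#' @param fb fraction bound at each `L`.
#' @param P total receptor concentration.
#' @param fitAmplitude also fit a scale `fbMax` (default FALSE).
#' @return list with `kd`, `fbMax`, `rss`, `converged`.
#' @export
fitKd <- function(L, fb, P, fitAmplitude = FALSE) {
  ok <- is.finite(L) & is.finite(fb)
  L <- L[ok]; fb <- fb[ok]
  if (sum(fb > 0 & L > 0) < 3)
    return(list(kd = NA_real_, fbMax = NA_real_, rss = NA_real_,
                converged = FALSE))
  rssFun <- function(logKd, amp = 1) {
    pred <- amp * fractionBound(L, P, 10^logKd)
    sum((fb - pred)^2)
  }
  if (!fitAmplitude) {
    opt <- stats::optimize(rssFun, interval = c(-3, 6))
    # refine around the coarse optimum
    opt2 <- stats::optimize(rssFun, interval = opt$minimum + c(-0.5, 0.5))
    if (opt2$objective < opt$objective) opt <- opt2
    return(list(kd = 10^opt$minimum, fbMax = 1, rss = opt$objective,
                converged = TRUE))
  }
  o <- stats::optim(c(log10(P), 1),
                    function(p) rssFun(p[1], p[2]),
                    method = "L-BFGS-B", lower = c(-3, 0.1),
                    upper = c(6, 1.5))
  list(kd = 10^o$par[1], fbMax = o$par[2], rss = o$value,
       converged = o$convergence == 0)
}

#' Fit dissociation constants for a titration series
#'
#' Runs [fitKd()] for every residue of the series.
#'
#' @param series a `TitrationSeries` (after [fractionBoundSeries()]; the
#'   `fb` column is added if absent).
#' @param P receptor concentration (default the series attribute).
#' @param fitAmplitude forwarded to [fitKd()].
#' @return data.frame: `residue`, `motif`, `kd`, `rss`, `converged`.
#' @export
fitKdSeries <- function(series, P = attr(series, "receptorConc"),
                        fitAmplitude = FALSE) {
  if (is.null(series$fb)) series <- fractionBoundSeries(series)
  if (is.null(P)) stop("receptor concentration unknown")
  rows <- lapply(split(series, series$residue), function(d) {
    f <- fitKd(d$L, d$fb, P, fitAmplitude)
    data.frame(residue = d$residue[1],
               motif = if (!is.null(d$motif)) d$motif[1] else NA,
               kd = f$kd, rss = f$rss, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-motif Kd summary
#'
#' Mean +/- sample (n-1) standard deviation of the per-residue estimates in
#' each motif; unconverged residues are excluded.
#'
#' @param fits data.frame from [fitKdSeries()].
#' @param motifMap optional named list residue-numbers-per-motif (defaults
#'   to the `motif` column).
#' @return data.frame of class `BindingFit`: `motif`, `kdMean`, `kdSd`,
#'   `n`, `residues`.
#' @export
motifKdSummary <- function(fits, motifMap = NULL) {
  if (!is.null(motifMap)) {
    fits$motif <- NA_character_
    for (m in names(motifMap))
      fits$motif[fits$residue %in% motifMap[[m]]] <- m
  }
  fits <- fits[fits$converged & !is.na(fits$kd) & !is.na(fits$motif), ]
  rows <- lapply(split(fits, fits$motif), function(d) {
    if (nrow(d) < 2) stop("motif ", d$motif[1], ": need >= 2 residues")
    data.frame(motif = d$motif[1], kdMean = mean(d$kd),
               kdSd = stats::sd(d$kd), n = nrow(d),
               residues = paste(d$residue, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("BindingFit", class(out))
  out
}
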