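#' Segment scheme over a chain
#'
#' Consecutive non-overlapping `window`-residue segments; the final partial
#' window is retained (a 311-residue chain gives 78 segments).
#'
#' @param residues integer vector of residue numbers (native numbering).
#' @param window segment width in residues (default 4).
#' @return integer matrix `nSegments x 2` (first, last residue).
#' @export
segmentScheme <- function(residues, window = 4L) {
  n <- length(residues)
  if (n < window) stop("chain shorter than one segment window")
  starts <- seq(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  cbind(first = residues[starts], last = residues[ends])
}

#' Retained segment pairs
#'
#' Pairs `(a, b)` with more than two segments strictly in between
#' (`b - a >= 4`), dropping strongly correlated short-range pairs; for 78
#' segments this leaves 2775 pairs.
#'
#' @param nSegments number of segments.
#' @param minGap minimum index difference (default 4).
#' @return integer matrix `nPairs x 2` of segment indices.
#' @export
segmentPairs <- function(nSegments, minGap = 4L) {
  if (nSegments < minGap + 1L) return(matrix(integer(), 0, 2))
  idx <- which(outer(seq_len(nSegments), seq_len(nSegments),
                     function(a, b) b - a >= minGap), arr.ind = TRUE)
  unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
}

#' Segment-pair minimum-distance features
#'
#' For every frame, the minimum CA-CA distance between each retained pair of
#' 4-residue windows of the disordered chain (2775 features for a
#' 311-residue chain).
#'
#' @param ensemble an [Ensemble-class].
#' @param chain chain to featurize (default `"A"`).
#' @param window segment width (default 4).
#' @param minGap minimum segment-index separation of retained pairs
#'   (default 4, i.e. more than two segments in between).
#' @return a [LandscapeModel-class] with `segments`, `pairs` and `features`
#'   filled.
#' @export
segmentFeatures <- function(ensemble, chain = "A", window = 4L, minGap = 4L) {
  idx <- particleIndices(ensemble, chain = chain, atomName = "CA")
  res <- ensemble@resid[idx]
  segs <- segmentScheme(res, window)
  nseg <- nrow(segs)
  pr <- segmentPairs(nseg, minGap)
  segStart <- match(segs[, 1], res)
  segEnd <- match(segs[, 2], res)
  sub <- ensemble@coords[idx, , , drop = FALSE]
  D <- if (nrow(pr)) {
    t(cpp_segpair_mindist(as.numeric(sub), dim(sub),
                          as.integer(segStart - 1L), as.integer(segEnd - 1L),
                          pr - 1L))
  } else matrix(numeric(), nFrames(ensemble), 0)
  new("LandscapeModel", segments = segs, pairs = pr, features = D,
      pcBasis = matrix(numeric(), 0, 0), pcScores = matrix(numeric(), 0, 0),
      pcSdev = numeric(), center = numeric(), trainIdx = integer(),
      embedding = matrix(numeric(), 0, 0), clusters = integer(),
      clusterMethod = character(), contributions = numeric())
}

#' Principal components of the feature matrix
#'
#' Centered (unscaled) PCA keeping the top `nComponents`; constant features
#' are dropped before decomposition.
#'
#' @param model a [LandscapeModel-class] with features.
#' @param nComponents components to keep (default 50, truncated to the
#'   available rank).
#' @return the model with `pcBasis`, `pcScores`, `pcSdev`, `center` filled.
#' @export
reducePCA <- function(model, nComponents = 50L) {
  X <- model@features
  if (nrow(X) < 2) stop("need at least 2 frames for PCA")
  keep <- which(apply(X, 2, stats::sd) > 0)
  if (!length(keep)) stop("all features are constant")
  p <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(p$rotation))
  basis <- matrix(0, ncol(X), k)
  basis[keep, ] <- p$rotation[, seq_len(k)]
  ctr <- numeric(ncol(X))
  ctr[keep] <- p$center
  model@pcBasis <- basis
  model@pcScores <- p$x[, seq_len(k), drop = FALSE]
  model@pcSdev <- p$sdev[seq_len(k)]
  model@center <- ctr
  model
}

#' Two-dimensional embedding of the landscape
#'
#' UMAP trained on a seeded random subsample of frames (10% by default),
#' with the remaining frames projected into the trained space.  Training
#' frames keep their fitted coordinates.
#'
#' @param model a [LandscapeModel-class] with PC scores.
#' @param subsampleFraction fraction of frames used for training
#'   (default 0.1; raised with a warning if it would give < 50 frames).
#' @param seed RNG seed (embedding is deterministic given the seed).
#' @param nNeighbors,minDist UMAP hyperparameters (defaults 15, 0.1).
#' @return the model with `trainIdx` and `embedding` filled.
#' @export
embedUMAP <- function(model, subsampleFraction = 0.1, seed = 42L,
                      nNeighbors = 15L, minDist = 0.1) {
  X <- model@pcScores
  if (!nrow(X)) stop("run reducePCA() first")
  n <- nrow(X)
  nTrain <- max(2L, round(subsampleFraction * n))
  if (nTrain < 50L && n >= 50L) {
    warning("training subset below 50 frames; raising subsample fraction")
    nTrain <- 50L
  }
  nTrain <- min(nTrain, n)
  set.seed(seed)
  tr <- sort(sample.int(n, nTrain))
  nb <- min(nNeighbors, nTrain - 1L)
  fit <- uwot::umap(X[tr, , drop = FALSE], n_neighbors = nb,
                    min_dist = minDist, n_threads = 1, n_sgd_threads = 0,
                    ret_model = TRUE)
  emb <- matrix(NA_real_, n, 2)
  emb[tr, ] <- fit$embedding
  rest <- setdiff(seq_len(n), tr)
  if (length(rest)) {
    set.seed(seed + 1L)
    emb[rest, ] <- uwot::umap_transform(X[rest, , drop = FALSE], fit,
                                        n_threads = 1, n_sgd_threads = 0)
  }
  model@trainIdx <- tr
  model@embedding <- emb
  model
}

#' Graph-community clustering of conformations
#'
#' K-nearest-neighbour graph on the top-PC coordinates with Louvain
#' community detection; deterministic under the seed.
#'
#' @param model a [LandscapeModel-class] with PC scores.
#' @param kNeighbors KNN connectivity (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed.
#' @return the model with `clusters` and `clusterMethod` filled.
#' @export
clusterConformations <- function(model, kNeighbors = 15L, resolution = 1,
                                 seed = 42L) {
  X <- model@pcScores
  if (!nrow(X)) stop("run reducePCA() first")
  n <- nrow(X)
  if (n == 1L) {
    model@clusters <- 1L; model@clusterMethod <- "louvain"; return(model)
  }
  k <- min(kNeighbors, n - 1L)
  nn <- FNN::get.knn(X, k = k)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.index)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  model@clusters <- as.integer(igraph::membership(cl))
  model@clusterMethod <- "louvain"
  model
}

#' Weighted cluster contributions
#'
#' Contribution of cluster `c` is the summed refined weight of its frames;
#' clusters are ranked and the top set (`> threshold`) reported with its
#' cumulative share.
#'
#' @param clusters integer cluster label per frame (or a
#'   [LandscapeModel-class]).
#' @param weights normalized frame weights.
#' @param threshold top-set contribution threshold (default 0.01).
#' @return list with `contributions` (named, descending), `topClusters`,
#'   `cumulativeTopShare`.
#' @export
clusterContributions <- function(clusters, weights, threshold = 0.01) {
  if (is(clusters, "LandscapeModel")) clusters <- clusters@clusters
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized")
  contr <- tapply(weights, clusters, sum)
  contr <- sort(structure(as.numeric(contr), names = names(contr)),
                decreasing = TRUE)
  top <- names(contr)[contr > threshold]
  list(contributions = contr, topClusters = top,
       cumulativeTopShare = sum(contr[top]))
}

#' Representative frame per cluster
#'
#' The frame nearest to its cluster centroid in embedding coordinates.
#'
#' @param model a [LandscapeModel-class] with embedding and clusters.
#' @return named integer vector, frame index per cluster.
#' @export
clusterRepresentatives <- function(model) {
  if (!nrow(model@embedding) || !length(model@clusters))
    stop("embedding and clusters required")
  vapply(split(seq_len(nrow(model@embedding)), model@clusters), function(i) {
    ctr <- colMeans(model@embedding[i, , drop = FALSE])
    i[which.min(rowSums(sweep(model@embedding[i, , drop = FALSE], 2, ctr)^2))]
  }, integer(1))
}

# contingency table of two integer labelings, as a dense matrix
labelContingency <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  R <- max(a); C <- max(b)
  matrix(tabulate(a + R * (b - 1L), nbins = R * C), R, C)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (expectation 0 under
#' random permutation, 1 for identical partitions).
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjustedRand <- function(a, b) {
  ct <- labelContingency(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  expd <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - expd
  if (den == 0) return(NaN)   # degenerate (e.g. single cluster both sides)
  (sij - expd) / den
}

# mutual information (nats) and entropies from a contingency table
miFromContingency <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  nz <- which(ct > 0)
  i <- ((nz - 1) %% nrow(ct)) + 1
  j <- ((nz - 1) %/% nrow(ct)) + 1
  mi <- sum(ct[nz] / n * log(n * ct[nz] / (a[i] * b[j])))
  list(mi = mi, hu = -sum(a[a > 0] / n * log(a[a > 0] / n)),
       hv = -sum(b[b > 0] / n * log(b[b > 0] / n)), a = a, b = b, n = n)
}

# expected mutual information under the hypergeometric permutation model
expectedMI <- function(a, b, n) {
  emi <- 0
  lf <- lfactorial
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / n * log(n * nij / (ai * bj))
      lp <- lf(ai) + lf(bj) + lf(n - ai) + lf(n - bj) - lf(n) -
        lf(nij) - lf(ai - nij) - lf(bj - nij) - lf(n - ai - bj + nij)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information corrected by its expectation under the hypergeometric
#' permutation model and normalized by the arithmetic mean of the two
#' partition entropies.
#'
#' @param a,b label vectors of equal length.
#' @return AMI in `[-1, 1]` (1 for identical partitions).
#' @export
adjustedMI <- function(a, b) {
  ct <- labelContingency(a, b)
  s <- miFromContingency(ct)
  emi <- expectedMI(s$a, s$b, s$n)
  den <- (s$hu + s$hv) / 2 - emi
  if (abs(den) < .Machine$double.eps) return(NaN)
  (s$mi - emi) / den
}

#' Permutation validation of two clusterings
#'
#' ARI and AMI between the partitions, with null distributions generated by
#' randomly shuffling the first labeling (`nShuffles` times); the
#' chance-corrected indices have null mean ~ 0.
#'
#' @param labelsA,labelsB cluster labels of equal length (e.g. K-means on
#'   the embedding vs. Louvain on PC space).
#' @param nShuffles permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `ari`, `ami`, `null` (data.frame of shuffled ari/ami),
#'   `nullMean`, `nullSd`, `pValue` (empirical, one-sided), `degenerate`.
#' @export
validateClustering <- function(labelsA, labelsB, nShuffles = 10000L,
                               seed = 7L) {
  if (length(labelsA) != length(labelsB)) stop("label lengths differ")
  degenerate <- length(unique(labelsA)) < 2 || length(unique(labelsB)) < 2
  ari <- adjustedRand(labelsA, labelsB)
  ami <- adjustedMI(labelsA, labelsB)
  fb <- as.integer(factor(labelsB))
  fa <- as.integer(factor(labelsA))
  # margins are permutation-invariant: precompute the AMI correction once
  ct0 <- labelContingency(fa, fb)
  s0 <- miFromContingency(ct0)
  emi <- expectedMI(s0$a, s0$b, s0$n)
  denAMI <- (s0$hu + s0$hv) / 2 - emi
  sa <- sum(choose(s0$a, 2)); sb <- sum(choose(s0$b, 2))
  expd <- sa * sb / choose(s0$n, 2)
  denARI <- (sa + sb) / 2 - expd
  set.seed(seed)
  nullAri <- nullAmi <- numeric(nShuffles)
  R <- nrow(ct0)
  for (k in seq_len(nShuffles)) {
    ap <- fa[sample.int(length(fa))]
    ct <- matrix(tabulate(ap + R * (fb - 1L), nbins = R * ncol(ct0)),
                 R, ncol(ct0))
    nz <- which(ct > 0)
    i <- ((nz - 1) %% R) + 1
    j <- ((nz - 1) %/% R) + 1
    mi <- sum(ct[nz] / s0$n * log(s0$n * ct[nz] / (s0$a[i] * s0$b[j])))
    nullAmi[k] <- (mi - emi) / denAMI
    nullAri[k] <- (sum(choose(ct[nz], 2)) - expd) / denARI
  }
  list(ari = ari, ami = ami,
       null = data.frame(ari = nullAri, ami = nullAmi),
       nullMean = c(ari = mean(nullAri), ami = mean(nullAmi)),
       nullSd = c(ari = stats::sd(nullAri), ami = stats::sd(nullAmi)),
       pValue = c(ari = (sum(nullAri >= ari) + 1) / (nShuffles + 1),
                  ami = (sum(nullAmi >= ami) + 1) / (nShuffles + 1)),
       degenerate = degenerate)
}

#' K-means clustering on the embedding (validation partition)
#'
#' @param model a [LandscapeModel-class] with embedding.
#' @param k number of clusters (default: the number of graph communities).
#' @param seed RNG seed.
#' @return integer labels per frame.
#' @export
kmeansOnEmbedding <- function(model, k = NULL, seed = 42L) {
  if (!nrow(model@embedding)) stop("run embedUMAP() first")
  if (is.null(k)) k <- length(unique(model@clusters))
  set.seed(seed)
  stats::kmeans(model@embedding, centers = k, nstart = 10,
                iter.max = 100)$cluster
}

#' Radius of gyration of ensemble frames
#'
#' Per-frame Rg over a particle selection (unit masses), with weighted
#' summary statistics overall and per state.
#'
#' @param ensemble an [Ensemble-class].
#' @param weights frame weights (default priors).
#' @param chain chain id(s) for the selection; `NULL` selects all particles.
#' @param resid optional residue subset.
#' @return list with `perFrame` (numeric) and `summary` (data.frame per
#'   state and overall: weighted mean, quartiles).
#' @export
radiusOfGyration <- function(ensemble, weights = NULL, chain = NULL,
                             resid = NULL) {
  idx <- particleIndices(ensemble, chain = chain, resid = resid)
  if (!length(idx)) stop("empty selection")
  if (is.null(weights)) weights <- priorWeights(ensemble)
  x <- ensemble@coords[idx, , , drop = FALSE]
  nf <- dim(x)[3]
  rg <- vapply(seq_len(nf), function(f) rgFrame(x[, , f]), numeric(1))
  st <- stateLabels(ensemble)
  summarise <- function(sel) {
    w <- weights[sel] / sum(weights[sel])
    q <- weightedQuantile(rg[sel], w, c(0.25, 0.5, 0.75))
    data.frame(mean = sum(w * rg[sel]), q25 = q[1], median = q[2], q75 = q[3])
  }
  perState <- do.call(rbind, lapply(split(seq_len(nf), st), summarise))
  perState <- cbind(state = rownames(perState), perState)
  overall <- cbind(state = "all", summarise(seq_len(nf)))
  rownames(perState) <- rownames(overall) <- NULL
  list(perFrame = rg, summary = rbind(overall, perState))
}

# weighted quantiles (type-4 style interpolation on the weighted ECDF)
weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}
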