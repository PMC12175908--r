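test_that("segment partitioning retains the final partial window", {
  s311 <- segmentScheme(1:311, 4)
  expect_equal(nrow(s311), 78)
  expect_equal(s311[78, ], c(first = 309, last = 311))
  expect_equal(nrow(segmentScheme(1:16, 4)), 4)
  expect_error(segmentScheme(1:3, 4), "shorter")
})

test_that("retained pair counts match brute force and the closed form", {
  expect_equal(nrow(segmentPairs(78)), 2775)
  expect_equal(nrow(segmentPairs(4)), 0)
  # brute force over a range of segment counts
  for (n in c(4:12, 20, 50, 100)) {
    brute <- sum(outer(1:n, 1:n, function(a, b) b - a >= 4))
    expect_equal(nrow(segmentPairs(n)), brute)
    if (n >= 4) expect_equal(brute, n * (n - 1) / 2 - (3 * n - 6))
  }
})

test_that("segment features are minimum inter-window CA distances", {
  ap <- tinyApo()
  m <- segmentFeatures(ap, "A")
  expect_equal(ncol(m@features), 2775)
  expect_true(all(m@features > 0))
  # brute-force check a few entries
  x <- frameCoords(ap, 2)
  for (p in c(1, 500, 2775)) {
    a <- m@pairs[p, 1]; b <- m@pairs[p, 2]
    ia <- m@segments[a, 1]:m@segments[a, 2]
    ib <- m@segments[b, 1]:m@segments[b, 2]
    D <- as.matrix(dist(rbind(x[ia, , drop = FALSE], x[ib, , drop = FALSE])))
    ref <- min(D[seq_along(ia), length(ia) + seq_along(ib)])
    expect_equal(m@features[2, p], ref, tolerance = 1e-6)
  }
})

blobModel <- function(n = 150, sep = 60, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 20), n, 20),
             matrix(rnorm(n * 20, mean = sep / sqrt(20)), n, 20))
  m <- new("LandscapeModel", features = X,
           segments = matrix(integer(), 0, 2), pairs = matrix(integer(), 0, 2),
           pcBasis = matrix(numeric(), 0, 0), pcScores = matrix(numeric(), 0, 0),
           pcSdev = numeric(), center = numeric(), trainIdx = integer(),
           embedding = matrix(numeric(), 0, 0), clusters = integer(),
           clusterMethod = character(), contributions = numeric())
  list(model = reducePCA(m, 10), truth = rep(1:2, each = n))
}

test_that("PCA behaves like a nested centered projection", {
  ap <- tinyApo()
  m <- segmentFeatures(ap, "A")
  m50 <- reducePCA(m, 50)
  expect_true(all(diff(m50@pcSdev) <= 1e-9))
  expect_lte(ncol(m50@pcScores), 50)
  # planar data has ~zero variance beyond the second component
  set.seed(2)
  plane <- cbind(rnorm(40), rnorm(40)) %*% matrix(rnorm(10), 2, 5)
  mp <- blobModel()$model    # reuse scaffolding
  mp@features <- plane
  mp <- reducePCA(mp, 5)
  expect_lt(mp@pcSdev[3] / mp@pcSdev[1], 1e-10)
  # rotation invariance of the spectrum
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  mq <- mp; mq@features <- plane %*% Q
  mq <- reducePCA(mq, 5)
  expect_equal(mq@pcSdev, mp@pcSdev, tolerance = 1e-8)
})

test_that("two separated blobs embed as separated islands, reproducibly", {
  bm <- blobModel()
  m1 <- embedUMAP(bm$model, subsampleFraction = 0.3, seed = 5)
  m2 <- embedUMAP(bm$model, subsampleFraction = 0.3, seed = 5)
  expect_identical(m1@embedding, m2@embedding)
  expect_true(all(is.finite(m1@embedding)))
  # island separation: inter-blob distance exceeds intra-blob 95th percentile
  e <- m1@embedding
  c1 <- colMeans(e[bm$truth == 1, ]); c2 <- colMeans(e[bm$truth == 2, ])
  intra <- quantile(sqrt(rowSums((e[bm$truth == 1, ] -
                                    matrix(c1, sum(bm$truth == 1), 2,
                                           byrow = TRUE))^2)), 0.95)
  expect_gt(sqrt(sum((c1 - c2)^2)), intra)
})

test_that("graph communities recover planted blobs exactly", {
  bm <- blobModel()
  m <- clusterConformations(bm$model, seed = 9)
  expect_equal(length(unique(m@clusters)), 2)
  expect_equal(adjustedRand(m@clusters, bm$truth), 1)
  # identical frames collapse to one cluster
  one <- bm$model
  one@features <- matrix(1, 60, 5)
  one@pcScores <- matrix(0, 60, 2)
  m1 <- clusterConformations(one, seed = 9)
  expect_equal(length(unique(m1@clusters)), 1)
  # determinism
  expect_identical(clusterConformations(bm$model, seed = 9)@clusters,
                   m@clusters)
})

test_that("cluster contributions are weighted sums that always normalize", {
  cl <- c(1, 1, 2, 2, 3)
  w <- c(0.1, 0.2, 0.3, 0.3, 0.1)
  cc <- clusterContributions(cl, w)
  expect_equal(sum(cc$contributions), 1, tolerance = 1e-12)
  expect_equal(unname(cc$contributions[["3"]]), 0.1)
  all1 <- clusterContributions(c(1, 1, 1), c(0.2, 0.5, 0.3))
  expect_equal(unname(all1$contributions), 1)
  expect_equal(all1$topClusters, "1")
  # uniform weights, equal sizes -> equal contributions
  eq <- clusterContributions(rep(1:4, each = 5), rep(0.05, 20))
  expect_true(all(abs(eq$contributions - 0.25) < 1e-12))
  set.seed(3)
  for (rep in 1:5) {
    w <- runif(20); w <- w / sum(w)
    expect_equal(sum(clusterContributions(rep(1:4, 5), w)$contributions), 1,
                 tolerance = 1e-12)
  }
})

test_that("ARI and AMI match references and are 1 for identical partitions", {
  a <- rep(1:3, times = c(5, 7, 8))
  expect_equal(adjustedRand(a, a), 1)
  expect_equal(adjustedMI(a, a), 1, tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRand(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("permutation nulls of the chance-corrected indices centre on zero", {
  set.seed(21)
  a <- sample(1:4, 300, replace = TRUE)
  b <- sample(1:5, 300, replace = TRUE)
  v <- validateClustering(a, b, nShuffles = 2000, seed = 3)
  se <- v$nullSd / sqrt(2000)
  expect_lt(abs(v$nullMean["ari"]), 4 * se["ari"] + 1e-4)
  expect_lt(abs(v$nullMean["ami"]), 4 * se["ami"] + 1e-4)
  expect_false(v$degenerate)
  vd <- validateClustering(rep(1, 10), rep(1:2, 5), nShuffles = 10, seed = 1)
  expect_true(vd$degenerate)
})

test_that("weighted radius of gyration summarizes per state", {
  cx <- tinyComplex()
  rg <- radiusOfGyration(cx, weights = trueWeights(cx))
  expect_equal(length(rg$perFrame), nFrames(cx))
  expect_true(all(c("all", "I", "II", "III", "IV") %in% rg$summary$state))
  # closed form for a selection of two beads
  e <- toyEnsemble(list(rbind(c(0, 0, 0), c(10, 0, 0))), c("A", "A"), 1:2)
  expect_equal(radiusOfGyration(e)$perFrame, 5)
  expect_error(radiusOfGyration(cx, chain = "Z"), "empty selection")
})
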