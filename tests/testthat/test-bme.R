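test_that("two-frame one-constraint fit matches the analytic solution", {
  G <- matrix(c(10, 50), 1, 2)
  f <- fitWeights(G, 40, 1, theta = 1e-8)
  expect_equal(f@weights, c(0.25, 0.75), tolerance = 1e-6)
  expect_lt(f@chi2, 1e-8)
})

test_that("three-frame fit matches an independent 1-D max-entropy solver", {
  G <- matrix(c(10, 30, 60), 1, 3)
  target <- 25
  # oracle: w ~ exp(-lambda G), solve sum w G = target by root finding
  mfun <- function(l) {
    w <- exp(-l * G[1, ]); w <- w / sum(w); sum(w * G[1, ]) - target
  }
  lam <- uniroot(mfun, c(-1, 1), tol = 1e-14)$root
  wRef <- exp(-lam * G[1, ]); wRef <- wRef / sum(wRef)
  f <- fitWeights(G, target, 1, theta = 1e-9)
  expect_equal(f@weights, wRef, tolerance = 1e-6)
})

test_that("a huge theta returns the priors and a consistent prior is a fixed point", {
  G <- matrix(c(10, 50, 20, 80), 2, 2)
  pri <- c(0.3, 0.7)
  f <- fitWeights(G, c(40, 60), c(1, 1), theta = 1e9, priors = pri)
  expect_equal(f@weights, pri, tolerance = 1e-6)
  # experimental equal to prior averages: lambda = 0, chi2 = 0
  gexp <- drop(G %*% pri)
  f0 <- fitWeights(G, gexp, c(1, 1), theta = 1, priors = pri)
  expect_equal(f0@lambda, c(0, 0), tolerance = 1e-6)
  expect_lt(f0@chi2, 1e-10)
})

test_that("weights are normalized and non-negative by construction", {
  set.seed(8)
  for (rep in 1:5) {
    m <- sample(2:6, 1); nf <- sample(5:40, 1)
    G <- matrix(runif(m * nf, 0, 300), m, nf)
    gexp <- runif(m, 0, 300)
    f <- fitWeights(G, gexp, runif(m, 0.5, 5), theta = 10^runif(1, -2, 2))
    expect_true(all(f@weights >= 0))
    expect_equal(sum(f@weights), 1, tolerance = 1e-9)
  }
})

test_that("chi-squared statistic has the printed closed forms", {
  expect_equal(chi2Stat(40, 30, 25), 4.0)
  expect_equal(chi2Stat(c(1, 2), c(1, 2), c(1, 1)), 0)
  # linear in 1/sigma2: doubling all sigma2 halves chi2
  p <- c(10, 20); e <- c(12, 25); s <- c(2, 3)
  expect_equal(chi2Stat(p, e, 2 * s), chi2Stat(p, e, s) / 2)
  expect_error(chi2Stat(numeric(), numeric(), numeric()), "no experimental")
})

test_that("chi2 is non-increasing and entropy increasing along a theta scan", {
  set.seed(11)
  nf <- 60
  G <- rbind(runif(nf, 0, 200), runif(nf, 0, 200), runif(nf, 50, 400))
  gexp <- c(150, 40, 300)    # inconsistent with uniform prior
  sc <- thetaScan(G, gexp, c(1, 1, 1), grid = 10^seq(3, -2, length.out = 12))
  ch <- sc$scan$chi2
  expect_true(all(diff(ch) <= pmax(1e-6 * abs(ch[-length(ch)]), 1e-9)))
  expect_true(all(diff(sc$scan$entropy) >= -1e-8))
  expect_true(sc$selected %in% sc$scan$theta)
})

test_that("the elbow rule picks the knee of a two-plateau curve", {
  th <- 10^seq(4, -2, length.out = 25)
  # steadily improving until theta = 1, flat plateau below: knee at 1
  chi <- 10 + 90 * pmax(0, log10(th))
  sel <- selectThetaElbow(th, chi, 0.05)
  expect_equal(log10(sel), 0, tolerance = 0.3)
  # flat curve: keeps the largest theta
  expect_equal(selectThetaElbow(th, rep(5, 25)), th[1])
})

test_that("state contributions aggregate refined weights", {
  st <- c("I", "I", "II", "III")
  expect_equal(unname(stateContributions(c(1, 0, 0, 0), st)), c(1, 0, 0))
  expect_equal(unname(stateContributions(rep(0.25, 4), st)), c(0.5, 0.25, 0.25))
  expect_error(stateContributions(rep(0.25, 4), c(st[1:3], NA)), "unlabelled")
})

test_that("LOESS smoothing preserves constants and lines, flattens spikes", {
  res <- 1:40
  tab <- data.frame(site = "s1", residue = res, ratio = rep(0.7, 40))
  expect_equal(smoothExperimental(tab)$smoothed, rep(0.7, 40), tolerance = 1e-9)
  lin <- data.frame(site = "s1", residue = res,
                    ratio = 0.2 + 0.01 * res)
  expect_equal(smoothExperimental(lin)$smoothed, lin$ratio, tolerance = 1e-6)
  spike <- data.frame(site = "s1", residue = res, ratio = rep(0.5, 40))
  spike$ratio[20] <- 1.0
  sm <- smoothExperimental(spike)$smoothed
  expect_lt(sm[20], 0.9)          # pulled toward the neighbours
  expect_gt(sm[20], 0.5)
  # too few points: passed through with a warning
  few <- data.frame(site = "s2", residue = 1:3, ratio = c(0.1, 0.2, 0.3))
  expect_warning(out <- smoothExperimental(few), "fewer than")
  expect_equal(out$smoothed, few$ratio)
})

test_that("the inverse-intensity error model has the documented form", {
  tab <- data.frame(ratio = c(0.1, 0.5, 0.01))
  out <- buildErrorModel(tab, scale = 1, floor = 0.05)
  expect_equal(out$sigma2[1] / out$sigma2[2], 5)        # 1/0.1 vs 1/0.5
  expect_equal(out$sigma2[3], 1 / 0.05)                 # floor engaged
  cst <- buildErrorModel(tab, scale = 2, mode = "constant")
  expect_true(all(cst$sigma2 == 2))
})

test_that("state populations are recovered from zero-noise PREs (reduced size)", {
  cx <- tinyComplex()
  pre <- synthesizePRE(cx, truth = tinyTruth())
  prepped <- preparePRETable(pre$table, smooth = FALSE)
  rw <- suppressWarnings(
    bmeReweight(cx, pre$profiles, prepped, theta = 0.1))
  truthW <- stateContributions(trueWeights(cx), stateLabels(cx))
  got <- rw$fit@stateContributions[names(truthW)]
  expect_lt(max(abs(got - truthW)), 0.1)
  expect_lt(rw$fit@chi2, rw$fit@chi2Prior)
})
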