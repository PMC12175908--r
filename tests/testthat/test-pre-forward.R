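kk <- physicalConstants()

test_that("dipolar prefactor matches an independent hand plug-in", {
  # (1/15) (mu0/4pi)^2 gammaI^2 g^2 muB^2 Se(Se+1), SI constants typed fresh
  ref <- (1 / 15) * (1e-7)^2 * (2.6752218744e8)^2 * (2.00231930436)^2 *
    (9.2740100783e-24)^2 * 0.75
  expect_equal(kk$prefactor, ref, tolerance = 1e-12)
  expect_equal(kk$prefactor, 1.234e-44, tolerance = 1e-3)
})

test_that("single-rotamer Gamma2 at 20 A matches the closed form", {
  cloud <- list(positions = matrix(0, 1, 3), probs = 1)
  g <- gamma2Frame(cloud, matrix(c(20, 0, 0), 1, 3), kk)
  # independent evaluation: S2 = 1, J(w) = r^-6 tauc/(1+w^2 tauc^2)
  r6 <- (20e-10)^-6
  tc <- 29e-9; om <- 2 * pi * 600e6
  ref <- kk$prefactor * r6 * (4 * tc + 3 * tc / (1 + om^2 * tc^2))
  expect_equal(as.numeric(g), ref, tolerance = 1e-10)
  expect_equal(as.numeric(g), 22.4, tolerance = 0.1 / 22.4)
  expect_equal(attr(g, "S2"), 1)
  expect_equal(attr(g, "S2radial"), 1)
  expect_equal(attr(g, "S2angular"), 1)
})

test_that("Gamma2 vanishes at large distance and is linear in <r^-6>", {
  cloud <- list(positions = matrix(0, 1, 3), probs = 1)
  gFar <- gamma2Frame(cloud, matrix(c(1e4, 0, 0), 1, 3), kk)
  expect_lt(as.numeric(gFar), 1e-10)
  g1 <- as.numeric(gamma2Frame(cloud, matrix(c(20, 0, 0), 1, 3), kk))
  g2 <- as.numeric(gamma2Frame(cloud, matrix(c(20 / 2^(1 / 6), 0, 0), 1, 3), kk))
  expect_equal(g2 / g1, 2, tolerance = 1e-9)  # halving r^6 doubles Gamma2
})

test_that("intensity map follows the exponential INEPT attenuation", {
  expect_equal(gamma2ToIntensity(0, kk), 1.0)
  expect_equal(gamma2ToIntensity(450, kk), 9.07e-4, tolerance = 1e-3)
  expect_equal(gamma2ToIntensity(22.37, kk), 0.513, tolerance = 1e-3)
  # strictly decreasing
  g <- seq(0, 450, length.out = 500)
  expect_true(all(diff(gamma2ToIntensity(g, kk)) < 0))
})

test_that("intensity inversion round-trips and caps", {
  g <- seq(0, 449.9, length.out = 200)
  back <- intensityToGamma2(gamma2ToIntensity(g, kk), kk)
  expect_true(all(abs(back - g) < 1e-6))
  expect_equal(as.numeric(intensityToGamma2(1.0, kk)), 0)
  expect_equal(as.numeric(intensityToGamma2(1.1, kk)), 0)   # ratios > 1 -> 0
  inv <- intensityToGamma2(1e-4, kk)
  expect_equal(as.numeric(inv), 450)
  expect_true(attr(inv, "capped"))
})

test_that("rotamer clouds satisfy the order-parameter invariants", {
  cx <- tinyComplex()
  for (f in c(1, 40, 95)) {
    cloud <- placeLabelRotamers(cx, f, spinLabelSite("B", 1006))
    expect_equal(sum(cloud$probs), 1, tolerance = 1e-12)
    expect_true(all(cloud$probs >= 0))
    idx <- particleIndices(cx, chain = "A")
    g <- gamma2Frame(cloud, cx@coords[idx[seq(1, 311, 10)], , f], kk)
    s2a <- attr(g, "S2angular"); s2r <- attr(g, "S2radial")
    expect_true(all(s2a >= 0 & s2a <= 1 + 1e-12))
    expect_true(all(s2r > 0 & s2r <= 1 + 1e-12))
    expect_equal(attr(g, "S2"), s2a * s2r, tolerance = 1e-12)
    expect_true(all(g >= 0))
  }
})

test_that("an isolated residue gives uniform rotamer weights", {
  e <- toyEnsemble(list(matrix(c(0, 0, 0), 1, 3)), "A", 1L)
  cloud <- placeLabelRotamers(e, 1, spinLabelSite("A", 1), nRotamers = 12)
  expect_equal(cloud$probs, rep(1 / 12, 12), tolerance = 1e-12)
})

test_that("a single-point label has unit order parameters", {
  e <- toyEnsemble(list(matrix(c(0, 0, 0), 1, 3)), "A", 1L)
  cloud <- placeLabelRotamers(e, 1, spinLabelSite("A", 1), nRotamers = 1)
  g <- gamma2Frame(cloud, matrix(c(15, 3, 2), 1, 3), kk)
  expect_equal(attr(g, "S2angular"), 1)
  expect_equal(attr(g, "S2radial"), 1)
})

test_that("buried rotamer candidates get negligible Boltzmann weight", {
  # dense shell of blockers on the +x side of the attachment residue
  set.seed(4)
  sh <- matrix(rnorm(3 * 300), 300, 3)
  sh <- 8 * sh / sqrt(rowSums(sh^2))
  sh <- sh[sh[, 1] > 2 & sh[, 2] > 0.5, ]  # blockers on one flank only
  xyz <- rbind(c(0, 0, 0), c(-3.8, 0, 0), sh + rep(c(0, 0, 0), each = nrow(sh)))
  e <- toyEnsemble(list(xyz), c("A", "A", rep("B", nrow(sh))),
                   c(1L, 2L, seq_len(nrow(sh)) + 100L))
  cloud <- placeLabelRotamers(e, 1, spinLabelSite("A", 1), nRotamers = 24)
  expect_lt(min(cloud$probs) / max(cloud$probs), 1e-6)
})

test_that("ensemble averaging of Gamma2 respects the weights", {
  m <- matrix(c(10, 50, 20, 40), 2, 2)   # 2 residues x 2 frames
  expect_equal(gamma2Ensemble(m, c(1, 0)), c(10, 50))   # residue rows, frame cols
  expect_equal(gamma2Ensemble(m, c(0.25, 0.75)), c(0.25 * 10 + 0.75 * 20,
                                                   0.25 * 50 + 0.75 * 40))
  expect_equal(gamma2Ensemble(matrix(c(10, 50), 1), c(0.25, 0.75)), 40)
  expect_error(gamma2Ensemble(m, c(1, 0, 0)), "frame count")
  expect_error(gamma2Ensemble(m, c(0.7, 0.7)), "sum to 1")
})

test_that("the batch kernel equals the per-frame reference path", {
  cx <- tinyComplex()
  site <- spinLabelSite("B", 984)
  prof <- computeGamma2Profiles(cx, list(site), kk)[[1]]
  idx <- particleIndices(cx, chain = "A", atomName = "CA")
  for (f in c(2, 17, 80)) {
    cloud <- placeLabelRotamers(cx, f, site)
    ref <- gamma2Frame(cloud, cx@coords[idx, , f], kk)
    expect_equal(prof@gamma2[, f], as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("the correlation-time estimator reproduces the 29 ns value", {
  expect_equal(round(rotationalCorrelationTime(47.8)), 29)
  expect_equal(rotationalCorrelationTime(10), 6)
})
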