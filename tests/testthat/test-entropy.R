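test_that("uniform and delta torsion distributions hit the closed forms", {
  h <- 2 * pi / 35
  # uniform over the 35 bins, effectively infinite sampling
  ang <- rep(seq(-pi + h / 2, pi - h / 2, length.out = 35), 40)
  sU <- torsionEntropy(ang, nEff = 1e12)
  expect_equal(sU, log(35 / h), tolerance = 1e-9)
  expect_equal(sU, 5.273, tolerance = 1e-3)
  # all mass in one bin
  sD <- torsionEntropy(rep(0.1, 50), nEff = 1e12)
  expect_equal(sD, -log(h), tolerance = 1e-9)
  expect_equal(sD, 1.718, tolerance = 1e-3)
  # finite-sample correction exactly as printed: subtract (n-1)/(2N)
  s1000 <- torsionEntropy(ang, nEff = 1000)
  expect_equal(s1000, log(35 / h) - 34 / 2000, tolerance = 1e-9)
  expect_equal(s1000, 5.256, tolerance = 1e-3)
  # the conventional additive form is available as a switch
  expect_equal(torsionEntropy(ang, nEff = 1000, correction = "additive"),
               log(35 / h) + 34 / 2000, tolerance = 1e-9)
})

test_that("entropy is maximal for uniform bin probabilities", {
  set.seed(5)
  h <- 2 * pi / 35
  uni <- rep(seq(-pi + h / 2, pi - h / 2, length.out = 35), 10)
  sU <- torsionEntropy(uni, correction = "none")
  for (rep in 1:10) {
    ang <- runif(350, -pi, pi)
    w <- runif(350); w <- w / sum(w)
    expect_lte(torsionEntropy(ang, weights = w, correction = "none"),
               sU + 1e-9)
  }
})

test_that("uniform weights reproduce the unweighted estimator", {
  set.seed(6)
  ang <- runif(200, -pi, pi)
  expect_identical(torsionEntropy(ang),
                   torsionEntropy(ang, weights = rep(1 / 200, 200)))
})

test_that("phi/psi extraction recovers a built ideal helix", {
  n <- 10
  phi <- rep(-57 * pi / 180, n); psi <- rep(-47 * pi / 180, n)
  bb <- buildBackbone(phi, psi)
  e <- toyEnsemble(list(bb$coords, bb$coords), rep("A", 3 * n), bb$resid,
                   atomName = bb$atomName, states = c("I", "I"))
  tor <- extractTorsions(e, "A")
  phiRows <- tor$torsion == "phi"
  expect_true(all(abs(unlist(lapply(tor$angles[phiRows], unique)) -
                        (-57 * pi / 180)) < 1e-6))
  psiRows <- tor$torsion == "psi" & tor$residue < n
  expect_true(all(abs(unlist(lapply(tor$angles[psiRows], unique)) -
                        (-47 * pi / 180)) < 1e-6))
  # termini: residue 1 has no phi, residue n has no psi
  expect_false(any(tor$residue == 1 & tor$torsion == "phi"))
  expect_false(any(tor$residue == n & tor$torsion == "psi"))
})

test_that("coarse chains give pseudo-torsions with correct terminal handling", {
  ap <- tinyApo()
  tor <- extractTorsions(ap, "A")
  expect_true(all(tor$torsion == "zeta"))
  expect_equal(length(tor$angles), 311 - 3)
  one <- toyEnsemble(list(matrix(0, 1, 3)), "A", 1L)
  expect_length(extractTorsions(one, "A")$angles, 0)
})

test_that("residue entropy is additive over torsions with RT conversion", {
  n <- 6
  set.seed(9)
  bb <- buildBackbone(runif(n, -pi, 0), runif(n, -pi, pi))
  frames <- lapply(1:30, function(i) bb$coords + rnorm(length(bb$coords), sd = 0.3))
  e <- toyEnsemble(frames, rep("A", 3 * n), bb$resid, atomName = bb$atomName,
                   states = rep("I", 30))
  tor <- extractTorsions(e, "A")
  prof <- residueEntropyProfile(tor)
  for (r in prof@profile$residue) {
    expect_equal(prof@profile$S[prof@profile$residue == r],
                 sum(prof@perTorsion$S[prof@perTorsion$residue == r]),
                 tolerance = 1e-12)
  }
  expect_equal(prof@profile$ST, prof@profile$S * 8.314 * 310, tolerance = 1e-12)
  # S = 1 nat corresponds to 2.577 kJ/mol at 310 K
  expect_equal(8.314 * 310 / 1000, 2.577, tolerance = 1e-3)
})

test_that("per-state profiles restrict and renormalize the weights", {
  cx <- tinyComplex()
  tor <- extractTorsions(cx, "A")
  w <- trueWeights(cx)
  byState <- entropyByState(tor, w, stateLabels(cx))
  expect_setequal(names(byState), c("I", "II", "III", "IV"))
  # state I profile equals the profile computed with manually restricted weights
  wI <- ifelse(stateLabels(cx) == "I", w, 0); wI <- wI / sum(wI)
  ref <- residueEntropyProfile(tor, weights = wI)
  expect_equal(byState$I@profile$S, ref@profile$S, tolerance = 1e-12)
})

test_that("contact-class comparison flags planted entropy shifts", {
  set.seed(31)
  prof <- data.frame(residue = 1:60, S = rnorm(60, 5, 0.2))
  prof$ST <- prof$S * 8.314 * 310
  cf <- structure(c(rep(0.05, 30), rep(0.9, 30)), names = 1:60)
  # identical groups: not significant
  same <- entropyContactComparison(prof, cf)
  expect_true(same$tested)
  expect_gt(same$p, 0.05)
  expect_equal(same$significance, "NS")
  # plant a 2 SD downward shift in the high-contact group
  prof2 <- prof
  prof2$S[31:60] <- prof2$S[31:60] - 0.4
  shift <- entropyContactComparison(prof2, cf)
  expect_lt(shift$p, 0.01)
  # threshold partition matches manual classification
  cls <- shift$groups$class
  expect_true(all(cls[1:30] == "low", na.rm = TRUE))
  expect_true(all(cls[31:60] == "high", na.rm = TRUE))
  # intermediate frequencies are unclassified
  mid <- entropyContactComparison(prof, structure(rep(0.4, 60), names = 1:60))
  expect_false(mid$tested)
})
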