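# hand-buildable two-chain toy: chain A 8 residues (2 segments),
# chain B 4 residues (1 segment)
toyContact <- function(shift = c(0, 0, 0)) {
  a <- cbind(seq(0, 35, by = 5), 0, 0)          # 8 beads along x
  b <- sweep(cbind(seq(0, 15, by = 5), 0, 0), 2, shift, "+")
  rbind(a, b)
}

toyContactEnsemble <- function(shifts) {
  toyEnsemble(lapply(shifts, toyContact),
              c(rep("A", 8), rep("B", 4)), c(1:8, 101:104),
              states = rep("I", length(shifts)))
}

test_that("frame contacts follow the distance cutoff", {
  near <- toyContactEnsemble(list(c(0, 3, 0)))     # chains 3 A apart
  fc <- frameContacts(near, 1, chainA = "A", chainB = "B", cutoff = 4.5)
  expect_true(fc[1, 1])        # facing segments in contact
  expect_false(fc[2, 1])       # distal segment out of range
  far <- toyContactEnsemble(list(c(0, 100, 0)))
  expect_true(!any(frameContacts(far, 1, chainA = "A", chainB = "B",
                                 cutoff = 4.5)))
})

test_that("intra-chain maps omit short-range segment pairs", {
  ap <- tinyApo()
  fc <- frameContacts(ap, 1, chainA = "A", cutoff = 8)
  sr <- abs(outer(seq_len(nrow(fc)), seq_len(ncol(fc)), "-")) <= 2
  expect_true(all(is.na(fc[sr])))
  expect_true(!anyNA(fc[!sr]))
})

test_that("contact indicators equal a brute-force oracle on random toys", {
  set.seed(6)
  frames <- lapply(1:10, function(i) matrix(rnorm(12 * 3, sd = 6), 12, 3))
  e <- toyEnsemble(frames, c(rep("A", 8), rep("B", 4)), c(1:8, 101:104),
                   states = rep("I", 10))
  cutoff <- 7
  cm <- contactFrequencyMap(e, scope = "inter", cutoff = cutoff)
  segA <- list(1:4, 5:8); segB <- list(9:12)
  for (f in 1:10) {
    x <- frames[[f]]
    for (i in 1:2) {
      D <- as.matrix(dist(rbind(x[segA[[i]], ], x[segB[[1]], ])))
      ref <- min(D[1:4, 5:8]) <= cutoff
      got <- frameContacts(e, f, chainA = "A", chainB = "B", cutoff = cutoff)[i, 1]
      expect_identical(unname(got), ref)
    }
  }
})

test_that("weighted contact frequencies average frame indicators", {
  # contact only in frame 2; weights (0.25, 0.75)
  e <- toyContactEnsemble(list(c(0, 100, 0), c(0, 3, 0)))
  pw <- c(0.25, 0.75)
  cm <- contactFrequencyMap(e, weights = pw, scope = "inter", cutoff = 4.5)
  expect_equal(cm$frequency[1, 1], 0.75)
  # delta weights reproduce a single frame
  cm1 <- contactFrequencyMap(e, weights = c(1, 0), scope = "inter", cutoff = 4.5)
  expect_true(all(cm1$frequency == 0))
  # contact in every frame -> frequency 1
  always <- toyContactEnsemble(list(c(0, 3, 0), c(0, 2, 0)))
  cma <- contactFrequencyMap(always, scope = "inter", cutoff = 4.5)
  expect_equal(cma$frequency[1, 1], 1)
})

test_that("uniform weights equal the unweighted frequency", {
  cx <- tinyComplex()
  n <- nFrames(cx)
  u <- contactFrequencyMap(cx, weights = rep(1 / n, n), scope = "inter")
  raw <- vapply(seq_len(n), function(f) {
    m <- frameContacts(cx, f, chainA = "A", chainB = "B")
    mean(m)
  }, numeric(1))
  expect_equal(mean(u$frequency), mean(raw), tolerance = 1e-9)
})

test_that("per-state maps renormalize within each state", {
  cx <- tinyComplex()
  w <- trueWeights(cx)
  cm <- contactFrequencyMap(cx, weights = w, scope = "inter", byState = TRUE)
  expect_setequal(names(cm$states), c("I", "II", "III", "IV"))
  # a state map equals the map of the state-restricted renormalized ensemble
  fI <- which(stateLabels(cx) == "I")
  sub <- subsetFrames(cx, fI)
  ref <- contactFrequencyMap(sub, weights = w[fI] / sum(w[fI]), scope = "inter")
  expect_equal(cm$states$I, ref$frequency, tolerance = 1e-12)
})

test_that("interaction profiles are any-partner contact probabilities", {
  e <- toyContactEnsemble(list(c(0, 3, 0), c(0, 100, 0)))
  pr <- interactionProfile(e, weights = c(0.5, 0.5), cutoff = 4.5)
  # segment 1 of A touches B only in frame 1; segment 2 never
  expect_equal(pr$chainA$probability, c(0.5, 0))
  expect_equal(pr$chainB$probability, 0.5)
  # permanently far segment
  prFar <- interactionProfile(toyContactEnsemble(list(c(0, 100, 0))),
                              cutoff = 4.5)
  expect_true(all(prFar$chainA$probability == 0))
  # per-residue expansion covers all residues
  expect_setequal(pr$perResidueA$residue, 1:8)
  # oracle equality on a 20-frame toy
  set.seed(9)
  frames <- lapply(1:20, function(i) matrix(rnorm(36, sd = 5), 12, 3))
  e20 <- toyEnsemble(frames, c(rep("A", 8), rep("B", 4)), c(1:8, 101:104),
                     states = rep("I", 20))
  p20 <- interactionProfile(e20, cutoff = 6)
  ref <- sapply(1:20, function(f) {
    sapply(list(1:4, 5:8), function(ia) {
      D <- as.matrix(dist(rbind(frames[[f]][ia, ], frames[[f]][9:12, ])))
      min(D[1:4, 5:8]) <= 6
    })
  })
  expect_equal(p20$chainA$probability, rowMeans(ref), tolerance = 1e-12)
})

test_that("state-specific contacts recover a planted design", {
  mk <- function(v) matrix(v, 2, 2)
  maps <- list(I = mk(c(1, 0, 0, 0)), II = mk(c(0, 1, 0, 0)),
               III = mk(c(0, 0, 0.5, 0)), IV = mk(c(0, 0, 0.5, 0)))
  sp <- stateSpecificContacts(maps, highThresh = 0.6, lowThresh = 0.2)
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$state, c("I", "II"))
  expect_equal(sp$frequency, c(1, 1))
  # a contact present everywhere at 0.5 is not specific
  flat <- lapply(1:4, function(i) mk(rep(0.5, 4)))
  names(flat) <- c("I", "II", "III", "IV")
  expect_equal(nrow(stateSpecificContacts(flat)), 0)
  expect_error(stateSpecificContacts(maps["I"]), "at least two")
})
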