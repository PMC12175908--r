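# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small 4-state complex with unequal ground-truth weights
tinyComplex <- function() {
  fixture("tinyComplex", function() {
    truth <- groundTruth(stateWeights = c(I = 0.4, II = 0.3, III = 0.2, IV = 0.1),
                         noiseSd = 0, seed = 101)
    sampleComplexEnsemble(truth = truth, nFramesPerState = 30L)
  })
}

tinyTruth <- function() {
  groundTruth(stateWeights = c(I = 0.4, II = 0.3, III = 0.2, IV = 0.1),
              noiseSd = 0, seed = 101)
}

tinyApo <- function() {
  fixture("tinyApo", function() sampleApoEnsemble(nFrames = 10L, seed = 7))
}

# toy two-chain ensemble with hand-placeable coordinates
toyEnsemble <- function(coordsList, chain, resid, atomName = NULL,
                        states = NULL) {
  co <- array(NA_real_, c(length(chain), 3, length(coordsList)))
  for (f in seq_along(coordsList)) co[, , f] <- coordsList[[f]]
  Ensemble(co, chain, resid, atomName, states)
}
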