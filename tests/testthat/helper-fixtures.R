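# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 8 M1/PMd units, 8/8/8 trials: fast structural checks.
tinySession <- function(direction = "CCW", seed = 11) {
  cachedFixture(paste0("tiny_", direction, "_", seed), function() {
    set.seed(seed)
    units <- makeUnits(nM1 = 4L, nPMd = 4L, nPRR = 0L, latentRank = 2L)
    generateSession(
      schedule = perturbationSchedule(direction = direction,
                                      nBaseline = 8L, nRotation = 8L,
                                      nWashout = 8L),
      units = units, learning = learningModel(learningRate = 0.1),
      seed = seed, nCalibTrials = 16L)
  })
}

# 48 units over 3 areas, 60/100/40 trials, fast-adapting learner:
# the workhorse for recon / manifold / stats checks.
midSession <- function(seed = 21, frameNon = "motor",
                       gainNon = 0.75, gainPRR = 0.25) {
  key <- paste("mid", seed, frameNon, gainNon, gainPRR, sep = "_")
  cachedFixture(key, function() {
    set.seed(seed)
    units <- makeUnits(nM1 = 12L, nPMd = 12L, nPRR = 24L,
                       gainM1PMdNon = gainNon, gainPRRNon = gainPRR,
                       frameNoncontrolling = frameNon)
    generateSession(
      schedule = perturbationSchedule(nBaseline = 60L, nRotation = 100L,
                                      nWashout = 40L),
      units = units,
      learning = learningModel(learningRate = 0.05, retention = 0.99),
      seed = seed)
  })
}

# Noiseless, non-learning session: deterministic geometry checks.
noiselessSession <- function(seed = 31) {
  cachedFixture(paste0("noiseless_", seed), function() {
    set.seed(seed)
    units <- makeUnits(noiseSd = 0, latentScale = 0, latentRank = 0L)
    generateSession(
      schedule = perturbationSchedule(nBaseline = 8L, nRotation = 8L,
                                      nWashout = 0L),
      units = units, learning = learningModel(learningRate = 0),
      seed = seed, nCalibTrials = 16L, noiseModel = "none")
  })
}

# A hand-made decoder with chosen matrices (for filter-level oracles).
manualDecoder <- function(H, Q, A = diag(4), W = NULL, binMs = 50) {
  n <- nrow(H)
  if (is.null(W)) W <- diag(c(1, 1, 1, 0))
  A[4L, 4L] <- 1
  W[4L, ] <- 0; W[, 4L] <- 0
  new("KalmanDecoder", unitIds = seq_len(n), H = H, Q = Q, A = A, W = W,
      binMs = binMs, meta = list())
}

# Random well-spread tuning matrix (units x 4, last column b0).
randomH <- function(nUnits, scale = 0.01, b0 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(matrix(rnorm(nUnits * 3L, 0, scale), nUnits, 3L), rep(b0, nUnits))
}
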