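test_that("an unadapted command under rotation shows the full visual error", {
  s <- noiselessSession()
  tt <- trialTable(s)
  rot <- tt$alphaDeg[tt$phase == "rotation"]
  expect_equal(rot, rep(30, length(rot)), tolerance = 1e-3)
  # truth aim never moves with a zero learning rate
  expect_equal(truthAim(s), rep(0, nTrials(s)))
})

test_that("exact compensation yields a straight on-target cursor path", {
  set.seed(41)
  units <- makeUnits(nM1 = 8L, nPMd = 8L, nPRR = 0L, noiseSd = 0,
                     latentScale = 0, latentRank = 0L)
  dec <- bcivmr:::.calibrateOnManual(units, taskConfig(), 16L, "none")
  tg <- makeTargets(taskConfig())[2L, ]
  tr <- simulateTrial(-30, tg, units, dec, rotationDegSigned = 30,
                      noiseModel = "none")
  al <- alignToTargetFrame(tr$cursorPath, tg, 1)
  expect_lt(abs(midpointAngle(al)), 0.01)
  expect_lt(abs(deflection(al, 1)), 0.05)
  # and the unadapted command in the same setting errs by the rotation
  tr0 <- simulateTrial(0, tg, units, dec, rotationDegSigned = 30,
                       noiseModel = "none")
  expect_equal(midpointAngle(alignToTargetFrame(tr0$cursorPath, tg, 1)),
               30, tolerance = 0.01)
})

test_that("the aim trajectory follows the scalar learning-rule iteration", {
  set.seed(42)
  units <- makeUnits(nM1 = 8L, nPMd = 8L, nPRR = 0L, noiseSd = 0,
                     latentScale = 0, latentRank = 0L)
  lr <- 0.05
  s <- generateSession(
    schedule = perturbationSchedule(nBaseline = 0L, nRotation = 80L,
                                    nWashout = 0L),
    units = units, learning = learningModel(learningRate = lr,
                                            retention = 1),
    seed = 42, nCalibTrials = 16L, noiseModel = "none")
  # oracle: iterate aim <- aim - lr * (aim + 30) from 0
  aim <- numeric(80); a <- 0
  for (t in 1:80) { aim[t] <- a; a <- a - lr * (a + 30) }
  expect_equal(truthAim(s), aim, tolerance = 0.05)
  # the per-trial error sequence is a clean decaying exponential whose
  # asymptote matches the analytic fixed point (0 for retention = 1)
  f <- fitExponential(trialTable(s)$alphaDeg, nBoot = 0L)
  expect_equal(f$interceptDeg, 30, tolerance = 0.5)
  expect_equal(f$decayPerTrial, log(1 - lr), tolerance = 0.1)
  # monotone approach to the fixed point when retention = 1 (up to the
  # decoder-regression tolerance of the measured error driving the rule)
  expect_true(all(diff(truthAim(s)) <= 0.02))
  expect_lt(abs(tail(truthAim(s), 1) + 30), 1)
})

test_that("washout shows a negative aftereffect and learning is seeded", {
  s <- midSession()
  tt <- trialTable(s)
  lateRot <- mean(tail(tt$alphaDeg[tt$phase == "rotation"], 20))
  earlyWash <- mean(head(tt$alphaDeg[tt$phase == "washout"], 10))
  expect_gt(lateRot, 0)
  expect_lt(earlyWash, 0)   # opposite sign: aftereffect
  # adaptation reduced the error relative to its onset
  earlyRot <- mean(head(tt$alphaDeg[tt$phase == "rotation"], 10))
  expect_lt(lateRot, earlyRot / 2)
})

test_that("sessions are reproducible and serialize byte-for-byte", {
  set.seed(43); u1 <- makeUnits(nM1 = 4L, nPMd = 4L, nPRR = 0L)
  set.seed(43); u2 <- makeUnits(nM1 = 4L, nPMd = 4L, nPRR = 0L)
  sch <- perturbationSchedule(nBaseline = 6L, nRotation = 6L,
                              nWashout = 4L)
  s1 <- generateSession(schedule = sch, units = u1, seed = 7,
                        nCalibTrials = 16L)
  s2 <- generateSession(schedule = sch, units = u2, seed = 7,
                        nCalibTrials = 16L)
  expect_identical(spikeCounts(s1), spikeCounts(s2))
  expect_identical(trialTable(s1), trialTable(s2))
  d1 <- file.path(tempdir(), "ses1"); d2 <- file.path(tempdir(), "ses2")
  writeSession(s1, d1); writeSession(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("counts, cursor and hand respect the session invariants", {
  s <- midSession()
  cts <- spikeCounts(s)
  v <- cts[!is.na(cts)]
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  tt <- trialTable(s)
  # cursor pinned to the fixation point during the planning hold
  for (tr in c(1L, 50L, nTrials(s))) {
    plan <- seq_len(tt$nPlanBins[tr])
    expect_true(all(s@cursor[tr, plan, ] == 0))
    hand <- s@hand[tr, seq_len(tt$endBin[tr]), ]
    expect_true(all(sqrt(rowSums(hand^2)) <=
                      s@task$handSecurityRadiusMm))
  }
  # phase labels partition trials in schedule order
  expect_equal(rle(tt$phase)$values, c("baseline", "rotation", "washout"))
})

test_that("noiseless decoding reproduces the command to < 1% per bin", {
  set.seed(44)
  units <- makeUnits(nM1 = 16L, nPMd = 16L, nPRR = 0L, noiseSd = 0,
                     latentScale = 0, latentRank = 0L)
  dec <- bcivmr:::.calibrateOnManual(units, taskConfig(), 16L, "none")
  tg <- makeTargets(taskConfig())[7L, ]
  tr <- simulateTrial(0, tg, units, dec, noiseModel = "none")
  nPlan <- length(tr$planBins)
  Vdec <- diff(tr$cursorPath) / 0.05
  Vtrue <- bcivmr:::.minimumJerkVelocity(tg, 14L, 0.05)
  relErr <- sqrt(rowSums((Vdec - Vtrue)^2)) / sqrt(rowSums(Vtrue^2))
  expect_true(all(relErr[-(1:2)] < 0.01))
})

test_that("expected counts are equivariant under workspace rotation", {
  set.seed(45)
  units <- makeUnits(nM1 = 6L, nPMd = 6L, nPRR = 0L, noiseSd = 0,
                     latentScale = 0, latentRank = 0L)
  dec <- bcivmr:::.calibrateOnManual(units, taskConfig(), 16L, "none")
  tg <- makeTargets(taskConfig())
  # rotating all tuning vectors by 90 deg about Z maps the cube onto
  # itself: target 2 = (+,-,-) goes to target 4-ish; use explicit pairs
  R <- bcivmr:::.rotZ(90)
  rotated <- units
  B <- as.matrix(units$table[, c("bx", "by", "bz")]) %*% t(R)
  rotated$table$bx <- B[, 1]; rotated$table$by <- B[, 2]
  rotated$table$bz <- B[, 3]
  decR <- bcivmr:::.calibrateOnManual(rotated, taskConfig(), 16L, "none")
  t1 <- tg[1L, ]                 # (-35, -35, -35)
  t1r <- drop(R %*% t1)          # its image under the workspace rotation
  a <- simulateTrial(0, t1, units, dec, noiseModel = "none")
  b <- simulateTrial(0, t1r, rotated, decR, noiseModel = "none")
  expect_equal(a$counts, b$counts, tolerance = 1e-8)
})

test_that("the decoder roster must match the controlling units", {
  s <- tinySession()
  units <- list(table = unitInfo(s), loadings = s@loadings)
  class(units) <- "UnitRoster"
  badUnits <- units
  badUnits$table$controlling <- !badUnits$table$controlling
  expect_error(simulateTrial(0, c(35, 35, 35), badUnits, onlineDecoder(s)),
               "roster")
})
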