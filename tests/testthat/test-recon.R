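test_that("unit selection filters by area and controlling status", {
  s <- midSession()
  tab <- unitInfo(s)
  idx <- selectUnits(s, "PRR", "noncontrolling")
  expect_true(all(tab$area[idx] == "PRR"))
  expect_true(all(!tab$controlling[idx]))
  expect_error(selectUnits(s, "PRR", "controlling"), "empty")
  expect_setequal(selectUnits(s),
                  seq_len(nUnits(s)))
})

test_that("offline movement reconstruction reads out the encoded frame", {
  # motor-frame noncontrolling units deflect negatively in late rotation,
  # visual-frame units positively, and gain-0 units stay near zero
  sM <- midSession()                               # motor, gain 0.75
  sV <- midSession(seed = 22, frameNon = "visual")
  sH1 <- midSession(seed = 23, gainNon = 0, gainPRR = 0)
  defl <- function(s) {
    late <- phaseTrials(s, "rotation", 0.5)
    non <- selectUnits(s, c("M1", "PMd"), "noncontrolling")
    mean(deflectionEnd(reconMovement(s, non, "rotation", trials = late)))
  }
  expect_lt(defl(sM), -3)
  expect_gt(defl(sV), 3)
  expect_lt(abs(defl(sH1)), 2)
})

test_that("baseline leave-one-out reconstructions head toward the target", {
  s <- midSession()
  non <- selectUnits(s, c("M1", "PMd"), "noncontrolling")
  some <- phaseTrials(s, "baseline")[seq(1, 57, by = 8)]
  rec <- reconMovement(s, non, "baseline", trials = some)
  targets <- makeTargets(taskConfig())
  tt <- trialTable(s)
  ang <- vapply(seq_along(some), function(i) {
    p <- rec@trajectories[[i]]
    e <- p[nrow(p), ]
    tg <- targets[tt$target[some[i]], ]
    acos(sum(e * tg) / sqrt(sum(e^2) * sum(tg^2))) * 180 / pi
  }, numeric(1))
  expect_lt(mean(ang), 45)
  # no trend across baseline (stationary reconstruction error)
  all <- phaseTrials(s, "baseline")
  recAll <- reconMovement(s, non, "baseline", trials = all)
  fit <- lm(abs(deflectionEnd(recAll)) ~ seq_along(all))
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("memory decoding classifies baseline targets above chance and
           agrees in sign with the movement readout", {
  s <- midSession()
  ctrl <- selectUnits(s, controlling = "controlling")
  some <- phaseTrials(s, "baseline")[1:24]
  rec <- reconMemory(s, ctrl, "baseline", trials = some)
  cls <- classifyTarget(rec, makeTargets(taskConfig()))
  truth <- trialTable(s)$target[some]
  expect_gt(mean(cls == truth), 0.5)   # chance is 0.125
  # planning-period re-aiming: negative deflection for motor-frame units
  late <- phaseTrials(s, "rotation", 0.5)
  non <- selectUnits(s, c("M1", "PMd"), "noncontrolling")
  memDefl <- mean(deflectionEnd(reconMemory(s, non, "rotation",
                                            trials = late)))
  movDefl <- mean(deflectionEnd(reconMovement(s, non, "rotation",
                                              trials = late)))
  expect_lt(memDefl, 0)
  expect_equal(sign(memDefl), sign(movDefl))
})

test_that("target classification equals an exhaustive distance scan", {
  set.seed(51)
  targets <- makeTargets(taskConfig())
  pts <- matrix(rnorm(3000, 0, 40), 1000, 3)
  got <- apply(pts, 1, classifyTarget, targets = targets)
  want <- apply(pts, 1, function(p) {
    best <- 1; bestD <- Inf
    for (k in 1:8) {
      d <- sum((p - targets[k, ])^2)
      if (d < bestD) { bestD <- d; best <- k }
    }
    best
  })
  expect_equal(unname(got), want)
  # exact endpoint and the tie rule at the equidistant center
  expect_equal(as.integer(classifyTarget(targets[3, ], targets)), 3L)
  ctr <- classifyTarget(c(0, 0, 0), targets)
  expect_equal(as.integer(ctr), 1L)
  expect_true(attr(ctr, "tie"))
})

test_that("aiming vectors sum unit-normalized decoded directions", {
  mkRecon <- function(V) {
    path <- rbind(c(0, 0, 0), apply(V, 2, cumsum))
    new("ReconResult", trajectories = list(path),
        aligned = list(new("AlignedTrajectory", alongTarget = 0,
                           alongPerturbation = 0, rotationSign = 1)),
        deflectionEnd = 0, trialIndex = 1L, phase = "baseline",
        unitIndex = 1:2, kind = "memory")
  }
  V <- matrix(rep(c(5, 0, 0), 8), 8, 3, byrow = TRUE)
  expect_equal(drop(aimingVector(mkRecon(V))), c(8, 0, 0))
  V2 <- rbind(matrix(rep(c(2, 0, 0), 4), 4, 3, byrow = TRUE),
              matrix(rep(c(-2, 0, 0), 4), 4, 3, byrow = TRUE))
  expect_equal(drop(aimingVector(mkRecon(V2))), c(0, 0, 0))
  set.seed(52)
  V3 <- matrix(rnorm(24), 8, 3)
  expect_equal(drop(aimingVector(mkRecon(V3))),
               colSums(V3 / sqrt(rowSums(V3^2))))
  expect_error(aimingVector(mkRecon(V3[1:4, ])), "fewer")
})

test_that("relative gain scales a population's final angle to controlling", {
  s <- midSession()
  late <- phaseTrials(s, "rotation", 0.5)
  ctrl <- selectUnits(s, controlling = "controlling")
  rc <- reconMovement(s, ctrl, "rotation", trials = late)
  # identical population: 100% by construction
  expect_equal(relativeGain(rc, rc)$gainPercent, 100)
  non <- selectUnits(s, c("M1", "PMd"), "noncontrolling")
  rn <- reconMovement(s, non, "rotation", trials = late)
  g <- relativeGain(rn, rc, "M1PMd-non")
  expect_gt(g$gainPercent, 30)
  expect_lt(g$gainPercent, 100)
  # a zero-deflection population has gain ~0: fabricate straight recons
  rs <- rc
  rs@aligned <- lapply(rs@aligned, function(a) {
    a@alongPerturbation <- a@alongPerturbation * 0
    a
  })
  expect_equal(relativeGain(rs, rc)$gainPercent, 0)
  # undefined when the controlling reference itself has a ~0 angle
  expect_error(relativeGain(rn, rs), "undefined")
})

test_that("recon results export as tidy tables", {
  s <- tinySession()
  late <- phaseTrials(s, "rotation", 0.5)
  idx <- selectUnits(s, controlling = "controlling")
  rec <- reconMovement(s, idx, "rotation", trials = late)
  df <- reconAsDataFrame(rec, makeTargets(taskConfig()))
  expect_equal(nrow(df), length(late))
  expect_named(df, c("trial", "phase", "deflectionEnd", "classifiedTarget"))
})
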