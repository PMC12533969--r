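test_that("calibration recovers a noiseless tuning model exactly", {
  set.seed(3)
  H <- randomH(12, scale = 0.01, b0 = 1.5)
  V <- matrix(rnorm(200 * 3, 0, 80), 200, 3)
  Y <- cbind(V, 1) %*% t(H)
  dec <- calibrateDecoder(Y, V)
  expect_equal(observationMatrix(dec), H, tolerance = 1e-8)
  expect_lt(max(abs(dec@Q)), 1e-16)
  expect_error(calibrateDecoder(Y[, 1, drop = FALSE], V), "2 units")
  expect_error(calibrateDecoder(Y[1:3, ], V[1:3, ]), "more bins")
})

test_that("calibration under noise is unbiased within Monte-Carlo bounds", {
  set.seed(4)
  H <- randomH(6, scale = 0.01, b0 = 1)
  sigma <- 0.5
  nBins <- 400
  est <- replicate(30, {
    V <- matrix(rnorm(nBins * 3, 0, 80), nBins, 3)
    Y <- cbind(V, 1) %*% t(H) + matrix(rnorm(nBins * 6, 0, sigma),
                                       nBins, 6)
    observationMatrix(calibrateDecoder(Y, V))
  })
  bias <- as.vector(apply(est, c(1, 2), mean) - H)
  # empirical standard error of the replicate mean per coefficient
  se <- as.vector(apply(est, c(1, 2), sd)) / sqrt(dim(est)[3])
  expect_true(all(abs(bias[1:18]) < 5 * pmax(se[1:18], 1e-8)))
  # Q estimates the injected observation noise
  set.seed(5)
  V <- matrix(rnorm(2000 * 3, 0, 80), 2000, 3)
  Y <- cbind(V, 1) %*% t(H) + matrix(rnorm(2000 * 6, 0, sigma), 2000, 6)
  dec <- calibrateDecoder(Y, V)
  expect_equal(mean(diag(dec@Q)), sigma^2, tolerance = 0.15)
})

test_that("the state transition recovers an AR(1) velocity process", {
  set.seed(6)
  n <- 3000
  V <- matrix(0, n, 3)
  for (t in 2:n) V[t, ] <- 0.9 * V[t - 1, ] + rnorm(3, 0, 10)
  H <- randomH(5, seed = 7)
  Y <- cbind(V, 1) %*% t(H) + matrix(rnorm(n * 5, 0, 0.2), n, 5)
  dec <- calibrateDecoder(Y, V)
  expect_equal(unname(diag(dec@A)[1:3]), rep(0.9, 3), tolerance = 0.03)
  expect_equal(dec@A[4, 4], 1)
  expect_equal(dec@W[4, ], rep(0, 4))
})

test_that("single filter steps obey the no-information and low-noise limits", {
  H <- randomH(20, scale = 0.01, b0 = 1, seed = 8)
  A <- diag(c(0.9, 0.9, 0.9, 1))
  # uninformative observations: posterior equals the prediction A %*% prior
  decBig <- manualDecoder(H, Q = diag(1e12, 20), A = A, W = diag(c(1, 1, 1, 0)))
  prior <- c(30, -20, 10, 1)
  st <- decodeStep(decBig, prior, diag(c(5, 5, 5, 0)), rnorm(20))
  expect_equal(st$state, drop(A %*% prior), tolerance = 1e-4)
  # near-noiseless observations with many units: posterior equals the
  # least-squares inversion of H on the observed bin
  decLo <- manualDecoder(H, Q = diag(1e-12, 20), A = diag(4),
                         W = diag(c(100, 100, 100, 0)))
  v <- c(55, -80, 120)
  y <- drop(H %*% c(v, 1))
  st2 <- decodeStep(decLo, c(0, 0, 0, 1), diag(c(100, 100, 100, 0)), y)
  pinv <- solve(crossprod(H[, 1:3]), crossprod(H[, 1:3], y - H[, 4]))
  expect_equal(st2$state[1:3], drop(pinv), tolerance = 1e-3)
  expect_equal(st2$state[1:3], v, tolerance = 1e-3)
  expect_equal(st2$state[4], 1)
})

test_that("repeated identical bins converge to the Riccati fixed point", {
  H <- randomH(8, scale = 0.02, b0 = 1, seed = 9)
  A <- diag(c(0.8, 0.8, 0.8, 1))
  W <- diag(c(4, 4, 4, 0))
  Q <- diag(0.3, 8)
  dec <- manualDecoder(H, Q = Q, A = A, W = W)
  # independent oracle: iterate the discrete Riccati recursion directly
  P <- diag(c(10, 10, 10, 0))
  for (i in 1:200) {
    Pp <- A %*% P %*% t(A) + W
    S <- H %*% Pp %*% t(H) + Q
    K <- Pp %*% t(H) %*% solve(S)
    P <- (diag(4) - K %*% H) %*% Pp
    P[4, ] <- 0; P[, 4] <- 0
  }
  st <- list(state = c(0, 0, 0, 1), cov = diag(c(10, 10, 10, 0)))
  y <- drop(H %*% c(40, -40, 10, 1))
  for (i in 1:200) st <- decodeStep(dec, st$state, st$cov, y)
  expect_equal(st$cov, P, tolerance = 1e-6)
  # the state has reached its fixed point too
  st2 <- decodeStep(dec, st$state, st$cov, y)
  expect_equal(st2$state, st$state, tolerance = 1e-8)
})

test_that("closed-loop decoding blends computer and neural velocities", {
  H <- randomH(10, scale = 0.01, b0 = 1, seed = 10)
  V <- matrix(rnorm(300 * 3, 0, 80), 300, 3)
  Y <- cbind(V, 1) %*% t(H)
  dec <- calibrateDecoder(Y, V)
  yTest <- cbind(matrix(rnorm(12 * 3, 0, 60), 12, 3), 1) %*% t(H)
  comp <- matrix(rep(c(0, 100, 0), each = 12), 12, 3)
  full <- decodeClosedLoop(dec, yTest, assistWeight = 1,
                           computerVelocity = comp)
  expect_equal(full$velocities, comp)
  expect_equal(full$positions[13, ], c(0, 100 * 12 * 0.05, 0))
  pure <- decodeClosedLoop(dec, yTest)
  mixed <- decodeClosedLoop(dec, yTest, assistWeight = 0.7,
                            computerVelocity = comp)
  expect_equal(mixed$velocities, 0.7 * comp + 0.3 * pure$velocities)
  expect_error(decodeClosedLoop(dec, yTest, assistWeight = 0.5),
               "computerVelocity")
})

test_that("assist schedules validate, expand, and reject overlong schedules", {
  sch <- assistSchedule()
  expect_equal(tail(sch$levels, 1), 0)
  w <- assistWeights(sch, 120)
  expect_equal(w[1:20], rep(0.7, 20))
  expect_equal(w[101:120], rep(0, 20))
  expect_error(assistWeights(sch, 50), "longer than session")
  expect_error(assistSchedule(levels = c(0.5, 0.7, 0)))
})

test_that("calibrate-decode round trip reproduces noiseless velocities", {
  set.seed(11)
  H <- randomH(30, scale = 0.01, b0 = 1)
  n <- 400
  V <- matrix(0, n, 3)
  for (t in 2:n) V[t, ] <- 0.85 * V[t - 1, ] + rnorm(3, 0, 30)
  Y <- cbind(V, 1) %*% t(H)
  dec <- calibrateDecoder(Y, V)
  out <- decodeClosedLoop(dec, Y)
  relErr <- sqrt(rowSums((out$velocities - V)^2)) /
    pmax(sqrt(rowSums(V^2)), 1e-9)
  expect_lt(stats::median(relErr[-(1:2)]), 0.01)
})

test_that("filter innovations are chi-square consistent on model data", {
  set.seed(12)
  nU <- 10
  H <- randomH(nU, scale = 0.01, b0 = 1)
  A <- diag(c(0.9, 0.9, 0.9, 1))
  W <- diag(c(25, 25, 25, 0))
  Q <- diag(0.25, nU)
  dec <- manualDecoder(H, Q = Q, A = A, W = W)
  n <- 3000
  x <- c(0, 0, 0)
  nis <- numeric(n)
  st <- list(state = c(0, 0, 0, 1), cov = diag(c(250, 250, 250, 0)))
  for (t in seq_len(n)) {
    x <- drop(A[1:3, 1:3] %*% x) + rnorm(3, 0, 5)
    y <- drop(H %*% c(x, 1)) + rnorm(nU, 0, 0.5)
    # normalized innovation squared w.r.t. the filter's own prediction
    xp <- drop(dec@A %*% st$state)
    Pp <- dec@A %*% st$cov %*% t(dec@A) + dec@W
    S <- H %*% Pp %*% t(H) + Q
    innov <- y - drop(H %*% xp)
    nis[t] <- drop(t(innov) %*% solve(S, innov))
    st <- decodeStep(dec, st$state, st$cov, y)
  }
  expect_equal(mean(nis[-(1:10)]), nU, tolerance = 0.05)
})

test_that("decoding is equivariant under a common workspace rotation", {
  set.seed(13)
  H <- randomH(15, scale = 0.01, b0 = 1)
  n <- 300
  V <- matrix(rnorm(n * 3, 0, 60), n, 3)
  Y <- cbind(V, 1) %*% t(H) + matrix(rnorm(n * 15, 0, 0.3), n, 15)
  errs <- function(Hm, Vm, Ym) {
    d <- calibrateDecoder(Ym, Vm)
    out <- decodeClosedLoop(d, Ym)
    sqrt(rowSums((out$velocities - Vm)^2))
  }
  R3 <- rbind(cbind(matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2),
                    0), c(0, 0, 1))
  e1 <- errs(H, V, Y)
  # rotate tuning vectors and velocities together: same counts, same errors
  H2 <- cbind(H[, 1:3] %*% t(R3), H[, 4])
  V2 <- V %*% t(R3)
  expect_equal(cbind(V2, 1) %*% t(H2), cbind(V, 1) %*% t(H))
  e2 <- errs(H2, V2, Y)
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("target-pointing retraining uses unit directions at nominal speed", {
  set.seed(14)
  H <- randomH(8, scale = 0.01, b0 = 1)
  cube <- makeTargets(taskConfig())
  tgt <- cube[sample.int(8, 64, replace = TRUE), ]
  pos <- matrix(rnorm(64 * 3, 0, 5), 64, 3)
  # the retraining outputs are unit center-to-target directions at the
  # nominal speed; cursor at center toward (35,35,35) gives (1,1,1)/sqrt(3)
  Vtrain <- (tgt - pos) / sqrt(rowSums((tgt - pos)^2)) * 200
  expect_equal(unname((c(35, 35, 35) - 0) / sqrt(3 * 35^2) * 200),
               rep(200 / sqrt(3), 3))
  Y <- cbind(Vtrain, 1) %*% t(H)
  dec0 <- calibrateDecoder(Y + matrix(rnorm(64 * 8, 0, 0.01), 64, 8),
                           matrix(rnorm(64 * 3, 0, 50), 64, 3))
  dec <- retrainToTarget(dec0, Y, tgt, pos)
  expect_equal(unname(observationMatrix(dec)), unname(H),
               tolerance = 1e-8)
  expect_true(dec@meta$retrained)
  # a degenerate bin (cursor exactly on target) is excluded by rule
  dec2 <- retrainToTarget(dec0, rbind(Y, Y[1, ]),
                          rbind(tgt, tgt[1, ]),
                          rbind(pos, tgt[1, ]))
  expect_equal(unname(observationMatrix(dec2)), unname(H),
               tolerance = 1e-8)
  expect_error(retrainToTarget(dec0, Y[1:2, ], tgt[1:2, ] * 0,
                               tgt[1:2, ] * 0), "degenerate")
})

test_that("decoder JSON serialization round-trips exactly", {
  set.seed(15)
  V <- matrix(rnorm(300, 0, 50), 100, 3)
  Y <- cbind(V, 1) %*% t(randomH(5)) + matrix(rnorm(500, 0, 0.2), 100, 5)
  dec <- calibrateDecoder(Y, V)
  path <- file.path(tempdir(), "dec.json")
  writeDecoder(dec, path)
  dec2 <- readDecoder(path)
  expect_equal(dec2@H, dec@H)
  expect_equal(dec2@Q, dec@Q)
  expect_equal(dec2@A, dec@A)
  expect_equal(dec2@W, dec@W)
  expect_identical(dec2@unitIds, dec@unitIds)
})
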