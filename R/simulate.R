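## Closed-loop session simulator: minimum-jerk commands through linearly
## tuned units, Kalman-filter decoding, visual rotation of the cursor, and
## a scalar re-association learning rule across trials.

## Minimum-jerk speed profile toward a target at distance d, sampled at bin
## midpoints over nBins bins of width dt seconds.
.minimumJerkVelocity <- function(target, nBins, dt,
                                 durationS = nBins * dt) {
  d <- sqrt(sum(target^2))
  u <- target / d
  tau <- (seq_len(nBins) - 0.5) / (durationS / dt)   # profile midpoint times
  tau <- pmin(tau, 1)
  sp <- d / durationS * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  outer(sp, u)
}

## Expected counts for a unit block: rates = b0 + V %*% t(B)
.expectedCounts <- function(tab, V) {
  B <- as.matrix(tab[, c("bx", "by", "bz")])
  sweep(V %*% t(B), 2L, tab$b0, "+")
}

## Add latent + private noise, round, clip at zero.
.noisyCounts <- function(lambda, loadings, noiseSd,
                         noiseModel = c("gaussian", "poisson", "none")) {
  noiseModel <- match.arg(noiseModel)
  if (noiseModel == "none") return(pmax(lambda, 0))
  nb <- nrow(lambda); n <- ncol(lambda)
  k <- ncol(loadings)
  shared <- if (k > 0)
    matrix(rnorm(nb * k), nb, k) %*% t(loadings) else 0
  if (noiseModel == "gaussian") {
    eps <- if (any(noiseSd > 0))
      matrix(rnorm(nb * n), nb, n) * rep(noiseSd, each = nb) else 0
    pmax(round(lambda + shared + eps), 0)
  } else {
    matrix(stats::rpois(nb * n, pmax(lambda + shared, 0)), nb, n)
  }
}

## Effective aim angle (CCW-positive, degrees) per unit given the shared
## aim and the trial's applied rotation.
.unitAims <- function(tab, aimDeg, rotationDegSigned) {
  ifelse(tab$frame == "visual",
         aimDeg + rotationDegSigned,
         tab$adaptationGain * aimDeg)
}

.planNominalSpeed <- 200  # mm/s, nominal speed of the planning-period drive

#' Simulate one closed-loop BCI trial
#'
#' The intended command follows a minimum-jerk speed profile toward the
#' target direction rotated by the current aim offset in the X-Y plane.
#' Every unit's expected count per bin is \code{b0 + b . v(t)} (planning
#' bins use \code{planningGain} times the directional term at a fixed
#' nominal speed); counts add shared latent-factor and private noise, are
#' rounded and clipped at 0. The cursor velocity is the decoder output on
#' the controlling units' counts, rotated by the applied visual rotation;
#' the hand stays near the rest position within the security radius.
#'
#' Noncontrolling units express the shared aim scaled by their adaptation
#' gain (motor frame) or encode the rotated visual feedback (visual frame).
#' Uses the current RNG state.
#'
#' @param aimDeg current shared aim offset (degrees, CCW-positive).
#' @param target length-3 target position (mm).
#' @param units a [makeUnits()] roster.
#' @param decoder the online \linkS4class{KalmanDecoder}, calibrated on the
#'   roster's controlling units.
#' @param rotationDegSigned signed visual rotation applied on this trial
#'   (0 outside the rotation phase; positive = CCW).
#' @param task a [taskConfig()].
#' @param nPlanBins number of planning-period bins preceding the go cue.
#' @param noiseModel "gaussian" (default), "poisson", or "none" (the
#'   deterministic limit: expected rates, not rounded, so the
#'   calibrate-decode identity is exact).
#' @param kfPlan optional precomputed filter plan (internal fast path).
#' @return a list with \code{counts} (bins x units), \code{cursor}
#'   (bins x 3 positions; at the fixation point during planning),
#'   \code{hand} (bins x 3), \code{planBins}, \code{moveBins}, and
#'   \code{cursorPath} ((moveBins + 1) x 3 movement path from the origin).
#' @export
simulateTrial <- function(aimDeg, target, units, decoder,
                          rotationDegSigned = 0, task = taskConfig(),
                          nPlanBins = (task$cueMs + task$planningMs) /
                            task$binMs,
                          noiseModel = c("gaussian", "poisson", "none"),
                          kfPlan = NULL) {
  noiseModel <- match.arg(noiseModel)
  tab <- units$table
  ctrlIdx <- which(tab$controlling)
  if (!identical(as.integer(ctrlIdx), decoder@unitIds))
    stop("decoder roster does not match the controlling units")
  dt <- task$binMs / 1000
  nMove <- task$movementMs / task$binMs
  nBins <- nPlanBins + nMove
  Vmj <- .minimumJerkVelocity(target, nMove, dt)
  that <- target / sqrt(sum(target^2))

  aims <- .unitAims(tab, aimDeg, rotationDegSigned)
  lambda <- matrix(0, nBins, nrow(tab))
  for (a in unique(aims)) {
    sel <- which(aims == a)
    R <- .rotZ(a)
    Vg <- Vmj %*% t(R)
    lamMove <- .expectedCounts(tab[sel, , drop = FALSE], Vg)
    uPlan <- drop(R %*% that) * .planNominalSpeed
    lamPlanRow <- tab$b0[sel] + tab$planningGain[sel] *
      drop(as.matrix(tab[sel, c("bx", "by", "bz")]) %*% uPlan)
    lambda[seq_len(nPlanBins), sel] <-
      matrix(lamPlanRow, nPlanBins, length(sel), byrow = TRUE)
    lambda[nPlanBins + seq_len(nMove), sel] <- lamMove
  }
  counts <- .noisyCounts(lambda, units$loadings, tab$noiseSd, noiseModel)

  ymove <- counts[nPlanBins + seq_len(nMove), ctrlIdx, drop = FALSE]
  Vdec <- if (is.null(kfPlan))
    decodeClosedLoop(decoder, ymove)$velocities
  else
    .kfApplyPlan(kfPlan, ymove)
  Vcur <- if (rotationDegSigned != 0)
    Vdec %*% t(.rotZ(rotationDegSigned)) else Vdec
  path <- rbind(c(0, 0, 0), apply(Vcur * dt, 2L, cumsum))

  cursor <- matrix(0, nBins, 3L)
  cursor[nPlanBins + seq_len(nMove), ] <- path[-1L, , drop = FALSE]
  hand <- matrix(rnorm(nBins * 3L, 0, 1), nBins, 3L)
  hand <- hand * pmin(1, (task$handSecurityRadiusMm - 1e-6) /
                        pmax(sqrt(rowSums(hand^2)), 1e-12))
  list(counts = counts, cursor = cursor, hand = hand,
       planBins = seq_len(nPlanBins),
       moveBins = nPlanBins + seq_len(nMove),
       cursorPath = path)
}

## Balanced pseudo-random target order: permuted blocks of the 8 targets.
.targetOrder <- function(nTrials) {
  nBlocks <- ceiling(nTrials / 8L)
  head(as.vector(vapply(seq_len(nBlocks), function(i) sample.int(8L),
                        integer(8L))), nTrials)
}

## Calibration block: manual-control trials with the hand tracking the
## minimum-jerk command exactly; returns a calibrated decoder for the
## controlling units.
.calibrateOnManual <- function(units, task, nCalibTrials,
                               noiseModel = "gaussian") {
  tab <- units$table
  ctrlIdx <- which(tab$controlling)
  if (length(ctrlIdx) < 2L) stop("need at least 2 controlling units")
  targets <- makeTargets(task)
  dt <- task$binMs / 1000
  nMove <- task$movementMs / task$binMs
  ord <- .targetOrder(nCalibTrials)
  Y <- vector("list", nCalibTrials)
  V <- vector("list", nCalibTrials)
  for (t in seq_len(nCalibTrials)) {
    Vmj <- .minimumJerkVelocity(targets[ord[t], ], nMove, dt)
    lam <- .expectedCounts(tab[ctrlIdx, , drop = FALSE], Vmj)
    Y[[t]] <- .noisyCounts(lam, units$loadings[ctrlIdx, , drop = FALSE],
                           tab$noiseSd[ctrlIdx], noiseModel)
    V[[t]] <- Vmj
  }
  calibrateDecoder(do.call(rbind, Y), do.call(rbind, V),
                   binMs = task$binMs,
                   trialId = rep(seq_len(nCalibTrials), each = nMove),
                   unitIds = ctrlIdx)
}

#' Generate a complete closed-loop BCI-VMR session
#'
#' Runs the full protocol: a manual-control calibration block (used only to
#' fit the online decoder), then baseline, rotation and washout BCI trials
#' in order. After every trial the shared aim offset is updated by the
#' re-association rule \code{aim <- retention * aim - learningRate * error},
#' where the error is the trial's signed (CCW-positive) midpoint angular
#' error; the ground-truth aim used on each trial is recorded. The whole
#' session is reproducible from \code{seed}.
#'
#' @param task a [taskConfig()].
#' @param schedule a [perturbationSchedule()].
#' @param units a [makeUnits()] roster, or NULL to draw a default roster.
#' @param learning a [learningModel()].
#' @param seed integer seed; set before any random draw.
#' @param nCalibTrials manual-control trials used for decoder calibration.
#' @param noiseModel "gaussian" (default), "poisson", or "none"
#'   (deterministic expected rates).
#' @return a \linkS4class{BCISession}.
#' @examples
#' s <- generateSession(schedule = perturbationSchedule(nBaseline = 16,
#'                      nRotation = 16, nWashout = 8),
#'                      units = NULL, seed = 1)
#' s
#' @export
generateSession <- function(task = taskConfig(),
                            schedule = perturbationSchedule(),
                            units = NULL,
                            learning = learningModel(),
                            seed = 1L, nCalibTrials = 40L,
                            noiseModel = c("gaussian", "poisson", "none")) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(inherits(task, "TaskConfig"),
            inherits(schedule, "PerturbationSchedule"),
            inherits(learning, "LearningModel"))
  set.seed(as.integer(seed))
  if (is.null(units)) units <- makeUnits()
  tab <- units$table
  n <- nrow(tab)
  rotSign <- if (schedule$direction == "CCW") 1 else -1
  rotSigned <- rotSign * schedule$rotationDeg
  targets <- makeTargets(task)
  decoder <- .calibrateOnManual(units, task, nCalibTrials, noiseModel)

  nTot <- schedule$nBaseline + schedule$nRotation + schedule$nWashout
  if (schedule$nBaseline + schedule$nRotation == 0L)
    stop("schedule must contain at least one baseline or rotation trial")
  phase <- rep(c("baseline", "rotation", "washout"),
               c(schedule$nBaseline, schedule$nRotation, schedule$nWashout))
  ord <- .targetOrder(nTot)
  maxDelay <- task$variableDelayMaxMs / task$binMs
  delays <- if (maxDelay > 0) sample.int(maxDelay + 1L, nTot,
                                         replace = TRUE) - 1L else
    rep(0L, nTot)
  basePlan <- (task$cueMs + task$planningMs) / task$binMs
  nMove <- task$movementMs / task$binMs
  maxBins <- basePlan + maxDelay + nMove
  kfPlan <- .kfPlan(decoder, nMove)

  counts <- array(NA_real_, c(nTot, maxBins, n))
  cursor <- array(NA_real_, c(nTot, maxBins, 3L))
  hand <- array(NA_real_, c(nTot, maxBins, 3L))
  alpha <- truth <- numeric(nTot)
  nPlanVec <- integer(nTot)
  aim <- learning$aimDeg0
  for (t in seq_len(nTot)) {
    rot <- if (phase[t] == "rotation") rotSigned else 0
    nPlan <- basePlan + delays[t]
    tr <- simulateTrial(aim, targets[ord[t], ], units, decoder,
                        rotationDegSigned = rot, task = task,
                        nPlanBins = nPlan, noiseModel = noiseModel,
                        kfPlan = kfPlan)
    nb <- nPlan + nMove
    counts[t, seq_len(nb), ] <- tr$counts
    cursor[t, seq_len(nb), ] <- tr$cursor
    hand[t, seq_len(nb), ] <- tr$hand
    al <- alignToTargetFrame(tr$cursorPath, targets[ord[t], ], rotSign)
    aFold <- midpointAngle(al)
    alpha[t] <- aFold
    truth[t] <- aim
    nPlanVec[t] <- nPlan
    aCcw <- rotSign * aFold
    aim <- learning$retention * aim - learning$learningRate * aCcw
  }
  trials <- data.frame(
    trial = seq_len(nTot), target = ord, phase = phase,
    rotationDeg = ifelse(phase == "rotation", rotSigned, 0),
    rotationSign = rotSign, nPlanBins = nPlanVec,
    goBin = nPlanVec + 1L, endBin = nPlanVec + nMove,
    success = TRUE, alphaDeg = alpha, truthAimDeg = truth,
    stringsAsFactors = FALSE)
  new("BCISession", counts = counts, trials = trials, cursor = cursor,
      hand = hand, units = tab, loadings = units$loadings,
      task = unclass(task), schedule = unclass(schedule),
      learning = c(unclass(learning), list(noiseModel = noiseModel)),
      decoder = decoder,
      seed = as.integer(seed))
}

#' Extract a trial's cursor movement path
#'
#' The movement-period cursor positions with the starting center position
#' prepended, as used by the alignment and angular-error analyses.
#'
#' @param session a \linkS4class{BCISession}.
#' @param trial trial number.
#' @return a (moveBins + 1) x 3 matrix of positions (mm).
#' @export
trialCursorPath <- function(session, trial) {
  tt <- session@trials[trial, ]
  bins <- seq.int(tt$goBin, tt$endBin)
  rbind(c(0, 0, 0), session@cursor[trial, bins, ])
}
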