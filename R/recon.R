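## Offline population re-decoding: train a decoder on baseline activity of
## a chosen population, apply it to rotation trials, and read out motor-like
## vs visual-like encoding from deflections along the perturbation axis.
## Includes the memory-period decoder and the 8-way target classifier.

#' Select units by area and controlling status
#'
#' @param session a \linkS4class{BCISession}.
#' @param area subset of c("M1", "PMd", "PRR").
#' @param controlling "all", "controlling" or "noncontrolling".
#' @return integer vector of roster indices (error if empty).
#' @export
selectUnits <- function(session, area = c("M1", "PMd", "PRR"),
                        controlling = c("all", "controlling",
                                        "noncontrolling")) {
  controlling <- match.arg(controlling)
  tab <- session@units
  keep <- tab$area %in% area
  if (controlling == "controlling") keep <- keep & tab$controlling
  if (controlling == "noncontrolling") keep <- keep & !tab$controlling
  idx <- which(keep)
  if (length(idx) == 0L) stop("unit selection is empty")
  idx
}

#' Trials of a phase, optionally restricted to the late part
#'
#' "Late" means the last given fraction of the phase's trials (late
#' rotation = last 50% by default in the deflection analyses).
#'
#' @param session a \linkS4class{BCISession}.
#' @param phase "baseline", "rotation" or "washout".
#' @param lateFraction if non-NULL, keep only the last such fraction.
#' @return integer vector of trial numbers (successful trials only).
#' @export
phaseTrials <- function(session, phase, lateFraction = NULL) {
  tt <- session@trials
  idx <- tt$trial[tt$phase == phase & tt$success]
  if (!is.null(lateFraction)) {
    stopifnot(lateFraction > 0, lateFraction <= 1)
    idx <- tail(idx, ceiling(length(idx) * lateFraction))
  }
  idx
}

## Movement-period counts and realized cursor velocities, stacked over
## trials.
.movementData <- function(session, trials, unitIdx) {
  dt <- session@task$binMs / 1000
  tt <- session@trials
  Y <- vector("list", length(trials))
  V <- vector("list", length(trials))
  id <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[i]
    bins <- seq.int(tt$goBin[tr], tt$endBin[tr])
    pos <- session@cursor[tr, bins, , drop = TRUE]
    Y[[i]] <- session@counts[tr, bins, unitIdx, drop = TRUE]
    V[[i]] <- rbind(pos[1L, ], diff(pos)) / dt
    id[[i]] <- rep(tr, length(bins))
  }
  list(Y = do.call(rbind, Y), V = do.call(rbind, V),
       trialId = unlist(id))
}

## Planning-period counts and unit target-pointing vectors.
.planningData <- function(session, trials, unitIdx, window = NULL) {
  tt <- session@trials
  targets <- .sessionTargets(session)
  Y <- vector("list", length(trials))
  V <- vector("list", length(trials))
  id <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[i]
    bins <- seq_len(tt$nPlanBins[tr])
    if (!is.null(window)) bins <- tail(bins, window)
    tg <- targets[tt$target[tr], ]
    u <- tg / sqrt(sum(tg^2))
    Y[[i]] <- session@counts[tr, bins, unitIdx, drop = TRUE]
    V[[i]] <- matrix(u, length(bins), 3L, byrow = TRUE)
    id[[i]] <- rep(tr, length(bins))
  }
  list(Y = do.call(rbind, Y), V = do.call(rbind, V),
       trialId = unlist(id))
}

## Per-bin maximum-likelihood inversion of the observation model:
## v-hat = argmin (y - H v)' Q^-1 (y - H v) with the constant channel
## pinned. Used by the memory decoder, where bins are conditionally
## independent given the static target.
.decodeBinsML <- function(decoder, Y) {
  Hv <- decoder@H[, 1:3, drop = FALSE]
  b0 <- decoder@H[, 4L]
  Qi <- solve(.qFloor(decoder@Q))
  G <- solve(t(Hv) %*% Qi %*% Hv, t(Hv) %*% Qi)
  sweep(Y, 2L, b0) %*% t(G)
}

.sessionTargets <- function(session) {
  h <- session@task$cubeSideMm / 2
  g <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}

.alignRecon <- function(session, trials, paths) {
  targets <- .sessionTargets(session)
  tt <- session@trials
  aligned <- vector("list", length(trials))
  defl <- numeric(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[i]
    al <- alignToTargetFrame(paths[[i]], targets[tt$target[tr], ],
                             tt$rotationSign[tr])
    aligned[[i]] <- al
    defl[i] <- deflection(al, 1)
  }
  list(aligned = aligned, deflectionEnd = defl)
}

#' Offline movement-period reconstruction
#'
#' Calibrates a velocity Kalman filter on the selected population's
#' baseline movement-period counts against the realized cursor velocities,
#' then applies it to the movement-period counts of the test trials and
#' integrates the decoded velocities into reconstructed 3D paths. Each path
#' is aligned to the shared target/perturbation frame and its
#' end-of-movement deflection computed. When \code{phaseTest = "baseline"},
#' a leave-one-out procedure is used so every baseline trial is
#' reconstructed by a decoder that never saw it.
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices (e.g. from [selectUnits()]).
#' @param phaseTest phase whose trials are reconstructed.
#' @param trials optional explicit trial numbers (e.g. late rotation via
#'   [phaseTrials()]); defaults to all successful trials of
#'   \code{phaseTest}.
#' @return a \linkS4class{ReconResult} of kind "movement".
#' @export
reconMovement <- function(session, unitIndex,
                          phaseTest = c("rotation", "washout", "baseline"),
                          trials = NULL) {
  phaseTest <- match.arg(phaseTest)
  stopifnot(length(unitIndex) >= 2L)
  trainTrials <- phaseTrials(session, "baseline")
  if (length(trainTrials) < 2L) stop("need baseline trials for training")
  if (is.null(trials)) trials <- phaseTrials(session, phaseTest)
  if (length(trials) == 0L) stop("no test trials in phase ", phaseTest)
  dt <- session@task$binMs / 1000
  tt <- session@trials
  paths <- vector("list", length(trials))
  if (phaseTest == "baseline") {
    full <- .movementData(session, trainTrials, unitIndex)
    for (i in seq_along(trials)) {
      keep <- full$trialId != trials[i]
      dec <- calibrateDecoder(full$Y[keep, , drop = FALSE],
                              full$V[keep, , drop = FALSE],
                              binMs = session@task$binMs,
                              trialId = full$trialId[keep],
                              unitIds = unitIndex)
      bins <- seq.int(tt$goBin[trials[i]], tt$endBin[trials[i]])
      Yt <- session@counts[trials[i], bins, unitIndex, drop = TRUE]
      paths[[i]] <- decodeClosedLoop(dec, Yt)$positions
    }
  } else {
    train <- .movementData(session, trainTrials, unitIndex)
    dec <- calibrateDecoder(train$Y, train$V, binMs = session@task$binMs,
                            trialId = train$trialId, unitIds = unitIndex)
    nMove <- session@task$movementMs / session@task$binMs
    plan <- .kfPlan(dec, nMove)
    for (i in seq_along(trials)) {
      bins <- seq.int(tt$goBin[trials[i]], tt$endBin[trials[i]])
      Yt <- session@counts[trials[i], bins, unitIndex, drop = TRUE]
      V <- .kfApplyPlan(plan, Yt)
      paths[[i]] <- rbind(c(0, 0, 0), apply(V * dt, 2L, cumsum))
    }
  }
  ar <- .alignRecon(session, trials, paths)
  new("ReconResult", trajectories = paths, aligned = ar$aligned,
      deflectionEnd = ar$deflectionEnd, trialIndex = as.integer(trials),
      phase = rep(phaseTest, length(trials)),
      unitIndex = as.integer(unitIndex), kind = "movement")
}

#' Offline memory-period reconstruction
#'
#' Calibrates the observation model on the selected population's baseline
#' planning-period counts against unit-norm vectors pointing at the cued
#' target, then decodes every 50 ms planning bin of the test trials
#' (bins are conditionally independent given the static target, so each bin
#' is inverted with the calibrated observation model). The hypothetical
#' planning trajectory is the cumulative sum of the decoded vectors and is
#' therefore in arbitrary units. Baseline evaluation is leave-one-out.
#'
#' @inheritParams reconMovement
#' @return a \linkS4class{ReconResult} of kind "memory".
#' @export
reconMemory <- function(session, unitIndex,
                        phaseTest = c("rotation", "washout", "baseline"),
                        trials = NULL) {
  phaseTest <- match.arg(phaseTest)
  stopifnot(length(unitIndex) >= 2L)
  trainTrials <- phaseTrials(session, "baseline")
  if (length(trainTrials) < 2L) stop("need baseline trials for training")
  if (is.null(trials)) trials <- phaseTrials(session, phaseTest)
  if (length(trials) == 0L) stop("no test trials in phase ", phaseTest)
  tt <- session@trials
  full <- .planningData(session, trainTrials, unitIndex)
  paths <- vector("list", length(trials))
  decodeOne <- function(dec, tr) {
    bins <- seq_len(tt$nPlanBins[tr])
    Yt <- session@counts[tr, bins, unitIndex, drop = TRUE]
    V <- .decodeBinsML(dec, Yt)
    rbind(c(0, 0, 0), apply(V, 2L, cumsum))
  }
  if (phaseTest == "baseline") {
    for (i in seq_along(trials)) {
      keep <- full$trialId != trials[i]
      dec <- calibrateDecoder(full$Y[keep, , drop = FALSE],
                              full$V[keep, , drop = FALSE],
                              binMs = session@task$binMs,
                              trialId = full$trialId[keep],
                              unitIds = unitIndex)
      paths[[i]] <- decodeOne(dec, trials[i])
    }
  } else {
    dec <- calibrateDecoder(full$Y, full$V, binMs = session@task$binMs,
                            trialId = full$trialId, unitIds = unitIndex)
    for (i in seq_along(trials)) paths[[i]] <- decodeOne(dec, trials[i])
  }
  ar <- .alignRecon(session, trials, paths)
  new("ReconResult", trajectories = paths, aligned = ar$aligned,
      deflectionEnd = ar$deflectionEnd, trialIndex = as.integer(trials),
      phase = rep(phaseTest, length(trials)),
      unitIndex = as.integer(unitIndex), kind = "memory")
}

#' 8-way target classification of a reconstructed trajectory
#'
#' Assigns the target whose position is closest (Euclidean) to the final
#' position of the reconstruction. Ties are broken by the lowest target
#' index and flagged in the \code{"tie"} attribute.
#'
#' @param traj an n x 3 path matrix, a length-3 endpoint, or a
#'   \linkS4class{ReconResult} (classifies every trial).
#' @param targets 8 x 3 target matrix (from [makeTargets()]).
#' @return integer target index (vector for a ReconResult), with attribute
#'   \code{tie}.
#' @export
classifyTarget <- function(traj, targets) {
  if (is(traj, "ReconResult")) {
    out <- vapply(traj@trajectories, function(p)
      classifyTarget(p, targets), integer(1))
    attr(out, "tie") <- vapply(traj@trajectories, function(p)
      attr(classifyTarget(p, targets), "tie"), logical(1))
    return(out)
  }
  endpoint <- if (is.matrix(traj)) traj[nrow(traj), ] else traj
  d2 <- rowSums(sweep(targets, 2L, endpoint)^2)
  best <- which(d2 <= min(d2) + 1e-12)
  structure(as.integer(best[1L]), tie = length(best) > 1L)
}

#' Planning aiming vector
#'
#' The vector sum of the unit-normalized decoded direction vectors over the
#' final window (default 400 ms, i.e. 8 bins at 50 ms) of the planning
#' period. Bins with a zero decoded vector are skipped.
#'
#' @param recon a memory-period \linkS4class{ReconResult}.
#' @param windowMs window length before the go cue.
#' @param binMs bin width in ms.
#' @return an n_trials x 3 matrix of aiming vectors.
#' @export
aimingVector <- function(recon, windowMs = 400, binMs = 50) {
  stopifnot(is(recon, "ReconResult"))
  nb <- windowMs / binMs
  t(vapply(recon@trajectories, function(p) {
    V <- diff(p)
    if (nrow(V) < nb)
      stop("fewer decoded planning bins than the aiming window")
    V <- tail(V, nb)
    nn <- sqrt(rowSums(V^2))
    keep <- nn > 1e-12
    if (!all(keep))
      message("aimingVector: skipping ", sum(!keep), " zero-norm bin(s)")
    colSums(V[keep, , drop = FALSE] / nn[keep])
  }, numeric(3)))
}

.finalAngle <- function(recon) {
  avg <- averageAligned(recon@aligned)
  n <- length(avg@alongTarget)
  atan2(avg@alongPerturbation[n], avg@alongTarget[n]) * 180 / pi
}

#' Relative adaptation gain of a population
#'
#' The signed angle between a population's mean reconstructed trajectory
#' endpoint and the direct-to-target axis, expressed as a percentage of the
#' controlling population's angle. The controlling population's own gain is
#' 100% by construction.
#'
#' @param resultPop \linkS4class{ReconResult} for the population of
#'   interest.
#' @param resultCtrl \linkS4class{ReconResult} for the controlling
#'   population, same session and trials.
#' @param population optional label stored in the result.
#' @return a list of class "RelativeGain" with \code{finalAngleDeg},
#'   \code{ctrlAngleDeg} and \code{gainPercent}.
#' @export
relativeGain <- function(resultPop, resultCtrl, population = "population") {
  stopifnot(is(resultPop, "ReconResult"), is(resultCtrl, "ReconResult"))
  if (!identical(resultPop@trialIndex, resultCtrl@trialIndex))
    warning("population and controlling reconstructions cover different ",
            "trials")
  aPop <- .finalAngle(resultPop)
  aCtrl <- .finalAngle(resultCtrl)
  if (abs(aCtrl) < 0.5)
    stop("controlling final angle is ~0; relative gain undefined")
  structure(list(population = population, finalAngleDeg = aPop,
                 ctrlAngleDeg = aCtrl,
                 gainPercent = 100 * aPop / aCtrl),
            class = "RelativeGain")
}

#' Tidy export of a ReconResult
#'
#' @param recon a \linkS4class{ReconResult}.
#' @param targets optional 8 x 3 target matrix to add a classified-target
#'   column.
#' @return a data.frame with one row per reconstructed trial.
#' @export
reconAsDataFrame <- function(recon, targets = NULL) {
  out <- data.frame(trial = recon@trialIndex, phase = recon@phase,
                    deflectionEnd = recon@deflectionEnd)
  if (!is.null(targets)) out$classifiedTarget <- classifyTarget(recon, targets)
  out
}
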