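#' Task geometry and timing configuration
#'
#' The memory-guided 3D center-out task: eight targets at the vertices of a
#' cube centered on the fixation point, a fixation / cue / planning sequence
#' with a variable delay, then a timed movement period. All durations that
#' are binned must be positive multiples of the bin width.
#'
#' @param cubeSideMm cube side length (mm); targets sit at the 8 vertices.
#' @param fixationMs fixation hold duration.
#' @param cueMs target cue duration.
#' @param planningMs fixed planning (memory) duration after the cue.
#' @param variableDelayMaxMs maximum additional random delay before go.
#' @param movementTimeoutMs movement timeout.
#' @param movementMs nominal movement duration used by the simulator's
#'   minimum-jerk command profile (must not exceed the timeout).
#' @param binMs task-loop bin width.
#' @param handSecurityRadiusMm maximum tolerated hand excursion during BCI
#'   trials.
#' @return a list of class \code{"TaskConfig"}.
#' @examples
#' cfg <- taskConfig()
#' makeTargets(cfg)
#' @export
taskConfig <- function(cubeSideMm = 70, fixationMs = 400, cueMs = 300,
                       planningMs = 400, variableDelayMaxMs = 600,
                       movementTimeoutMs = 1500, movementMs = 700,
                       binMs = 50, handSecurityRadiusMm = 15) {
  stopifnot(cubeSideMm > 0, binMs > 0, movementMs <= movementTimeoutMs)
  binned <- c(fixationMs = fixationMs, cueMs = cueMs, planningMs = planningMs,
              variableDelayMaxMs = variableDelayMaxMs,
              movementTimeoutMs = movementTimeoutMs, movementMs = movementMs)
  ok <- binned >= 0 & abs(binned / binMs - round(binned / binMs)) < 1e-9 &
    (binned > 0 | names(binned) == "variableDelayMaxMs")
  if (!all(ok))
    stop("durations must be positive multiples of binMs: ",
         paste(names(binned)[!ok], collapse = ", "))
  structure(list(cubeSideMm = cubeSideMm, nTargets = 8L,
                 fixationMs = fixationMs, cueMs = cueMs,
                 planningMs = planningMs,
                 variableDelayMaxMs = variableDelayMaxMs,
                 movementTimeoutMs = movementTimeoutMs,
                 movementMs = movementMs, binMs = binMs,
                 handSecurityRadiusMm = handSecurityRadiusMm),
            class = "TaskConfig")
}

#' Perturbation schedule
#'
#' Phase structure of a session: baseline, then a fixed visual rotation in
#' the fronto-parallel X-Y plane (Z unaffected), then washout with the
#' rotation removed. Within a session the rotation direction is fixed.
#'
#' @param rotationDeg magnitude of the visual rotation (degrees).
#' @param direction "CCW" (positive about +Z) or "CW".
#' @param nBaseline,nRotation,nWashout trial counts per phase.
#' @return a list of class \code{"PerturbationSchedule"}.
#' @export
perturbationSchedule <- function(rotationDeg = 30,
                                 direction = c("CCW", "CW"),
                                 nBaseline = 160L, nRotation = 300L,
                                 nWashout = 160L) {
  direction <- match.arg(direction)
  stopifnot(rotationDeg >= 0, nBaseline >= 0, nRotation >= 0, nWashout >= 0)
  structure(list(rotationDeg = rotationDeg, direction = direction,
                 nBaseline = as.integer(nBaseline),
                 nRotation = as.integer(nRotation),
                 nWashout = as.integer(nWashout)),
            class = "PerturbationSchedule")
}

#' Target positions of the center-out task
#'
#' The eight targets are the vertices of the task cube, i.e. the sign
#' patterns of (+/- side/2, +/- side/2, +/- side/2), centered on the
#' fixation point at the origin. Row order is fixed (x fastest), so target
#' indices are stable across the package.
#'
#' @param config a [taskConfig()].
#' @return an 8 x 3 numeric matrix of target positions (mm).
#' @examples
#' tg <- makeTargets(taskConfig())
#' stopifnot(nrow(tg) == 8, all(colMeans(tg) == 0))
#' @export
makeTargets <- function(config = taskConfig()) {
  h <- config$cubeSideMm / 2
  g <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}
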