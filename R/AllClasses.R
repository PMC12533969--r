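#' BCISession: one simulated closed-loop BCI-VMR session
#'
#' Container for a simulated memory-guided 3D center-out BCI session with a
#' baseline / rotation / washout schedule. Spike counts are binned at the
#' task loop period (50 ms by default) and stored as a ragged
#' trials x bins x units array padded with \code{NA} beyond each trial's last
#' movement bin. Each trial consists of a planning period (including a
#' variable delay) followed by a movement period; per-trial event indices
#' live in the trial table.
#'
#' @slot counts numeric array, trials x bins x units; non-negative integer
#'   spike counts, \code{NA} beyond the trial end.
#' @slot trials data.frame with one row per trial: \code{trial},
#'   \code{target} (1-8), \code{phase} (baseline/rotation/washout),
#'   \code{rotationDeg} (signed rotation applied on that trial, 0 outside
#'   the rotation phase), \code{rotationSign} (session direction, +1 CCW /
#'   -1 CW), \code{nPlanBins}, \code{goBin} (first movement bin),
#'   \code{endBin}, \code{success}, \code{alphaDeg} (measured midpoint
#'   angular error, sign-folded so positive = toward the applied rotation),
#'   \code{truthAimDeg} (ground-truth aim offset, CCW-positive).
#' @slot cursor numeric array, trials x bins x 3 cursor positions (mm);
#'   held at the central fixation point (origin) during planning.
#' @slot hand numeric array, trials x bins x 3 hand positions (mm).
#' @slot units data.frame describing each unit: \code{unit}, \code{area}
#'   (M1/PMd/PRR), \code{controlling}, \code{b0} (counts/bin), \code{bx},
#'   \code{by}, \code{bz} (counts/bin per mm/s), \code{planningGain},
#'   \code{noiseSd}, \code{adaptationGain}, \code{frame} (motor/visual).
#' @slot loadings numeric matrix, units x k latent-factor loadings.
#' @slot task list, the task geometry/timing configuration.
#' @slot schedule list, the perturbation schedule.
#' @slot learning list, the re-association learning model.
#' @slot decoder the online \linkS4class{KalmanDecoder}.
#' @slot seed integer RNG seed the session was generated from.
#'
#' @seealso [generateSession()]
#' @export
setClass("BCISession",
  representation(
    counts = "array",
    trials = "data.frame",
    cursor = "array",
    hand = "array",
    units = "data.frame",
    loadings = "matrix",
    task = "list",
    schedule = "list",
    learning = "list",
    decoder = "ANY",
    seed = "integer"
  )
)

setValidity("BCISession", function(object) {
  msg <- character(0)
  dc <- dim(object@counts)
  if (length(dc) != 3L) msg <- c(msg, "counts must be a 3D array")
  if (nrow(object@trials) != dc[1L])
    msg <- c(msg, "trial table rows must match counts dim 1")
  if (nrow(object@units) != dc[3L])
    msg <- c(msg, "unit table rows must match counts dim 3")
  if (!all(dim(object@cursor) == c(dc[1L], dc[2L], 3L)))
    msg <- c(msg, "cursor must be trials x bins x 3")
  cts <- object@counts[!is.na(object@counts)]
  if (length(cts) && any(cts < 0))
    msg <- c(msg, "counts must be non-negative")
  stochastic <- !identical(object@learning$noiseModel, "none")
  if (stochastic && length(cts) && any(cts != round(cts)))
    msg <- c(msg, "counts must be integers under a stochastic noise model")
  need <- c("trial", "target", "phase", "rotationDeg", "rotationSign",
            "nPlanBins", "goBin", "endBin", "success", "alphaDeg",
            "truthAimDeg")
  if (!all(need %in% names(object@trials)))
    msg <- c(msg, paste("trial table must contain:",
                        paste(setdiff(need, names(object@trials)),
                              collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' KalmanDecoder: a calibrated velocity Kalman filter
#'
#' Observation model \code{counts = H \%*\% c(vx, vy, vz, 1) + noise} with
#' noise covariance \code{Q}; state model on the augmented velocity state
#' with transition \code{A} and process noise \code{W}. The constant channel
#' (4th state) is pinned: \code{A[4,4] = 1} and its process-noise row/column
#' are zero, so the filter never updates it.
#'
#' @slot unitIds integer indices of the units in the roster.
#' @slot H numeric matrix, units x 4 (last column = baseline rate b0).
#' @slot Q numeric matrix, units x units observation-noise covariance.
#' @slot A numeric 4 x 4 state transition.
#' @slot W numeric 4 x 4 process-noise covariance.
#' @slot binMs numeric bin width in ms.
#' @slot meta list of calibration details (e.g. ridge used).
#'
#' @seealso [calibrateDecoder()], [decodeClosedLoop()]
#' @export
setClass("KalmanDecoder",
  representation(
    unitIds = "integer",
    H = "matrix",
    Q = "matrix",
    A = "matrix",
    W = "matrix",
    binMs = "numeric",
    meta = "list"
  )
)

setValidity("KalmanDecoder", function(object) {
  msg <- character(0)
  n <- length(object@unitIds)
  if (!all(dim(object@H) == c(n, 4L)))
    msg <- c(msg, "H must be n_units x 4")
  if (!all(dim(object@Q) == c(n, n)))
    msg <- c(msg, "Q must be n_units x n_units")
  if (!all(dim(object@A) == c(4L, 4L)) || !all(dim(object@W) == c(4L, 4L)))
    msg <- c(msg, "A and W must be 4 x 4")
  if (max(abs(object@Q - t(object@Q))) > 1e-8)
    msg <- c(msg, "Q must be symmetric")
  if (max(abs(object@W - t(object@W))) > 1e-8)
    msg <- c(msg, "W must be symmetric")
  if (length(msg) == 0) {
    if (abs(object@A[4L, 4L] - 1) > 1e-12 ||
        any(abs(object@W[4L, ]) > 1e-12) || any(abs(object@W[, 4L]) > 1e-12))
      msg <- c(msg, "constant channel must be pinned (A[4,4]=1, W zero)")
  }
  if (length(msg)) msg else TRUE
})

#' AlignedTrajectory: a path in the shared target/perturbation frame
#'
#' A trajectory re-expressed in the common 2D frame used to average
#' movements across the eight targets: one axis along the center-to-target
#' direction (in the perturbation plane), the orthogonal in-plane axis
#' oriented so that positive values point toward the applied visual
#' rotation. Sessions with opposite rotation directions therefore average
#' coherently.
#'
#' @slot alongTarget numeric, per-sample coordinate (mm) on the
#'   center-to-target axis.
#' @slot alongPerturbation numeric, per-sample coordinate (mm) on the
#'   perturbation axis (positive = visual side).
#' @slot rotationSign numeric, +1 for CCW sessions, -1 for CW.
#' @slot samples list; for averaged trajectories, the per-point sample
#'   matrices (\code{alongTarget}, \code{alongPerturbation}; trajectories in
#'   rows) supporting bootstrap bands.
#'
#' @seealso [alignToTargetFrame()], [averageAligned()]
#' @export
setClass("AlignedTrajectory",
  representation(
    alongTarget = "numeric",
    alongPerturbation = "numeric",
    rotationSign = "numeric",
    samples = "list"
  ),
  prototype(samples = list())
)

setValidity("AlignedTrajectory", function(object) {
  msg <- character(0)
  if (length(object@alongTarget) != length(object@alongPerturbation))
    msg <- c(msg, "axis coordinate vectors must have equal length")
  if (!object@rotationSign %in% c(-1, 1))
    msg <- c(msg, "rotationSign must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' ReconResult: offline reconstructions for a unit population
#'
#' Result of re-decoding a session offline from a selected unit population:
#' one reconstructed 3D path per analyzed trial, its aligned version, and
#' the end-of-path deflection along the perturbation axis.
#'
#' @slot trajectories list of bins x 3 matrices (one per trial). Movement
#'   reconstructions are in mm; memory reconstructions are cumulative sums
#'   of decoded direction vectors and therefore in arbitrary units.
#' @slot aligned list of \linkS4class{AlignedTrajectory}.
#' @slot deflectionEnd numeric, per-trial deflection at the end of the
#'   reconstruction (positive = visual side, negative = motor side).
#' @slot trialIndex integer, session trial numbers analyzed.
#' @slot phase character, phase label of the analyzed trials.
#' @slot unitIndex integer, roster indices of the population used.
#' @slot kind character, "movement" or "memory".
#'
#' @seealso [reconMovement()], [reconMemory()], [relativeGain()]
#' @export
setClass("ReconResult",
  representation(
    trajectories = "list",
    aligned = "list",
    deflectionEnd = "numeric",
    trialIndex = "integer",
    phase = "character",
    unitIndex = "integer",
    kind = "character"
  )
)

setValidity("ReconResult", function(object) {
  n <- length(object@trajectories)
  if (length(object@aligned) != n || length(object@deflectionEnd) != n ||
      length(object@trialIndex) != n)
    "trajectories, aligned, deflectionEnd and trialIndex must be parallel"
  else TRUE
})
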