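## Velocity Kalman filter: calibration by regression of binned counts on
## velocity, target-pointing retraining, single-step inference, and
## closed-loop decoding with optional computer assistance.

.symmetrize <- function(M) (M + t(M)) / 2

## Least squares of counts on (vx, vy, vz, 1) with a loud ridge fallback
## when the regressors are near-singular.
.obsRegression <- function(Y, X) {
  XtX <- crossprod(X)
  ridge <- 0
  if (rcond(XtX) < 1e-12) {
    ridge <- 1e-8 * mean(diag(XtX))
    warning("near-singular regressors in decoder calibration; ",
            "applying ridge loading ", signif(ridge, 3), call. = FALSE)
    XtX <- XtX + ridge * diag(ncol(X))
  }
  B <- solve(XtX, crossprod(X, Y))
  resid <- Y - X %*% B
  Q <- .symmetrize(crossprod(resid) / max(nrow(Y) - ncol(X), 1L))
  list(H = unname(t(B)), Q = unname(Q), ridge = ridge)
}

## AR(1) fit of v_t on v_{t-1}; pairs never cross trial boundaries.
.velTransition <- function(V, trialId) {
  n <- nrow(V)
  keep <- which(trialId[-1L] == trialId[-n])
  V0 <- V[keep, , drop = FALSE]
  V1 <- V[keep + 1L, , drop = FALSE]
  G <- crossprod(V0)
  if (rcond(G) < 1e-12) G <- G + 1e-8 * mean(diag(G)) * diag(3L)
  M <- solve(G, crossprod(V0, V1))     # V1 ~ V0 %*% M
  Av <- t(M)
  Wv <- .symmetrize(crossprod(V1 - V0 %*% M) / max(nrow(V0) - 3L, 1L))
  list(Av = Av, Wv = Wv)
}

#' Calibrate a velocity Kalman filter decoder
#'
#' Per-unit least squares of binned spike counts on (vx, vy, vz, 1) fills
#' the observation matrix H (last column = baseline rate); Q is the
#' residual covariance. The state transition A is the least-squares fit of
#' v_t on v_(t-1) (pairs never straddle trial boundaries) and W its
#' residual covariance; the constant state channel is pinned (A[4,4] = 1,
#' zero process noise). Calibration is deterministic.
#'
#' @param counts bins x units matrix of spike counts.
#' @param velocities bins x 3 matrix of velocities (mm/s), aligned per bin.
#' @param binMs bin width in ms.
#' @param trialId optional per-bin trial labels; transition pairs are only
#'   formed within a trial.
#' @param unitIds roster indices stored in the decoder (default 1..n).
#' @return a \linkS4class{KalmanDecoder}.
#' @export
calibrateDecoder <- function(counts, velocities, binMs = 50,
                             trialId = NULL, unitIds = NULL) {
  counts <- as.matrix(counts)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(counts) == nrow(velocities), ncol(velocities) == 3L)
  if (ncol(counts) < 2L) stop("need at least 2 units")
  if (nrow(counts) <= 4L) stop("need more bins than the state dimension")
  if (is.null(trialId)) trialId <- rep(1L, nrow(counts))
  if (is.null(unitIds)) unitIds <- seq_len(ncol(counts))
  obs <- .obsRegression(counts, cbind(velocities, 1))
  tr <- .velTransition(velocities, trialId)
  A <- diag(4); A[1:3, 1:3] <- tr$Av
  W <- matrix(0, 4, 4); W[1:3, 1:3] <- tr$Wv
  new("KalmanDecoder", unitIds = as.integer(unitIds), H = obs$H, Q = obs$Q,
      A = A, W = W, binMs = binMs,
      meta = list(ridge = obs$ridge, retrained = FALSE))
}

#' Retrain a decoder with target-pointing velocities
#'
#' Recalibrates the filter using idealized training outputs: unit-norm
#' vectors from the current cursor position toward the cued target, scaled
#' by a nominal speed. Bins where the cursor already sits on the target
#' (zero training vector) are excluded.
#'
#' @param decoder the previously calibrated \linkS4class{KalmanDecoder}
#'   (supplies roster and bin width).
#' @param counts bins x units matrix over the same roster.
#' @param targets bins x 3 matrix, cued target position per bin.
#' @param positions bins x 3 matrix, cursor position per bin.
#' @param nominalSpeed training speed in mm/s.
#' @param trialId optional per-bin trial labels.
#' @return a retrained \linkS4class{KalmanDecoder}.
#' @export
retrainToTarget <- function(decoder, counts, targets, positions,
                            nominalSpeed = 200, trialId = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nUnits(decoder))
  d <- as.matrix(targets) - as.matrix(positions)
  nn <- sqrt(rowSums(d^2))
  keep <- nn > 1e-9
  if (!any(keep)) stop("all training bins are degenerate (cursor on target)")
  V <- d[keep, , drop = FALSE] / nn[keep] * nominalSpeed
  if (is.null(trialId)) trialId <- rep(1L, nrow(counts))
  out <- calibrateDecoder(counts[keep, , drop = FALSE], V,
                          binMs = decoder@binMs, trialId = trialId[keep],
                          unitIds = decoder@unitIds)
  out@meta$retrained <- TRUE
  out
}

.qFloor <- function(Q) {
  ## tiny diagonal floor so the innovation covariance stays invertible in
  ## the noiseless limit (H P H' has rank <= 4)
  d <- mean(diag(Q))
  Q + max(1e-8, 1e-10 * d) * diag(nrow(Q))
}

.initCov <- function(decoder) {
  ## isotropic broad prior (10x the mean process-noise variance) so that
  ## decoding is exactly equivariant under workspace rotations
  P0 <- matrix(0, 4, 4)
  p0 <- 10 * max(mean(diag(decoder@W)[1:3]), 1e-6)
  P0[1:3, 1:3] <- diag(p0, 3L)
  P0
}

#' One Kalman filter predict + update cycle
#'
#' Standard linear-Gaussian step on the augmented state (vx, vy, vz, 1).
#' The constant channel is pinned to 1 and is never updated (its process
#' noise and prior variance are zero).
#'
#' @param decoder a \linkS4class{KalmanDecoder}.
#' @param priorState length-4 posterior state from the previous bin.
#' @param priorCov 4 x 4 posterior covariance from the previous bin.
#' @param countsBin length-units vector of spike counts for this bin.
#' @return a list with elements \code{state} and \code{cov}.
#' @export
decodeStep <- function(decoder, priorState, priorCov, countsBin) {
  A <- decoder@A; W <- decoder@W; H <- decoder@H
  xp <- drop(A %*% priorState)
  Pp <- .symmetrize(A %*% priorCov %*% t(A) + W)
  S <- .symmetrize(H %*% Pp %*% t(H) + .qFloor(decoder@Q))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("non-invertible innovation covariance: degenerate observation noise")
  PHt <- Pp %*% t(H)
  K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
  innov <- countsBin - drop(H %*% xp)
  x <- xp + drop(K %*% innov)
  P <- .symmetrize((diag(4) - K %*% H) %*% Pp)
  x[4L] <- 1
  P[4L, ] <- 0; P[, 4L] <- 0
  list(state = x, cov = P)
}

## Precompute the (data-independent) gain sequence for nBins steps so that
## decoding a whole session reduces to matrix-vector products.
.kfPlan <- function(decoder, nBins) {
  A <- decoder@A; W <- decoder@W; H <- decoder@H
  Qf <- .qFloor(decoder@Q)
  P <- .initCov(decoder)
  Ks <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    Pp <- .symmetrize(A %*% P %*% t(A) + W)
    S <- .symmetrize(H %*% Pp %*% t(H) + Qf)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("non-invertible innovation covariance in filter plan")
    PHt <- Pp %*% t(H)
    K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
    P <- .symmetrize((diag(4) - K %*% H) %*% Pp)
    P[4L, ] <- 0; P[, 4L] <- 0
    Ks[[b]] <- K
  }
  list(A = A, H = H, Ks = Ks, nBins = nBins)
}

.kfApplyPlan <- function(plan, Y) {
  nb <- nrow(Y)
  V <- matrix(0, nb, 3L)
  x <- c(0, 0, 0, 1)
  for (b in seq_len(nb)) {
    xp <- drop(plan$A %*% x)
    x <- xp + drop(plan$Ks[[min(b, plan$nBins)]] %*% (Y[b, ] - plan$H %*% xp))
    x[4L] <- 1
    V[b, ] <- x[1:3]
  }
  V
}

#' Decode a trial closed-loop, with optional computer assistance
#'
#' Runs the filter over ordered bins of spike counts and integrates the
#' output velocity into a cursor path starting at the center. With an
#' assist weight w, the output velocity of each bin is the weighted
#' vectorial sum \code{w * computer + (1 - w) * decoded}.
#'
#' @param decoder a \linkS4class{KalmanDecoder}.
#' @param countsByBin bins x units matrix, in temporal order.
#' @param assistWeight scalar or per-bin vector of computer weights in
#'   [0, 1]; 0 (default) is pure neural control.
#' @param computerVelocity bins x 3 matrix of computer-generated
#'   velocities; required when any assist weight is positive.
#' @return a list with \code{velocities} (bins x 3, mm/s) and
#'   \code{positions} ((bins + 1) x 3 mm, first row at the origin).
#' @export
decodeClosedLoop <- function(decoder, countsByBin, assistWeight = 0,
                             computerVelocity = NULL) {
  countsByBin <- as.matrix(countsByBin)
  nb <- nrow(countsByBin)
  w <- rep_len(assistWeight, nb)
  stopifnot(all(w >= 0 & w <= 1))
  if (any(w > 0) && is.null(computerVelocity))
    stop("computerVelocity is required when assistWeight > 0")
  plan <- .kfPlan(decoder, nb)
  V <- .kfApplyPlan(plan, countsByBin)
  if (any(w > 0))
    V <- w * computerVelocity + (1 - w) * V
  dt <- decoder@binMs / 1000
  pos <- rbind(c(0, 0, 0), apply(V * dt, 2L, cumsum))
  list(velocities = V, positions = pos)
}

#' Assist schedule for gradual transfer to brain control
#'
#' An ordered sequence of computer-weight levels and the number of trials
#' spent at each; weights must decrease monotonically and end at 0.
#'
#' @param levels computer-weight fractions (e.g. from 0.7 down to 0).
#' @param blockSizes trials per level.
#' @return a list of class "AssistSchedule".
#' @export
assistSchedule <- function(levels = c(0.7, 0.5, 0.3, 0.1, 0),
                           blockSizes = rep(20L, length(levels))) {
  stopifnot(length(levels) == length(blockSizes),
            all(diff(levels) < 0), levels[length(levels)] == 0,
            all(blockSizes > 0))
  structure(list(levels = levels, blockSizes = as.integer(blockSizes)),
            class = "AssistSchedule")
}

#' Per-trial computer weights from an assist schedule
#'
#' @param schedule an [assistSchedule()].
#' @param nTrials number of trials in the session.
#' @return numeric vector of length nTrials (0 after the schedule ends).
#' @export
assistWeights <- function(schedule, nTrials) {
  w <- rep(schedule$levels, schedule$blockSizes)
  if (length(w) > nTrials)
    stop("assist schedule longer than session (", length(w), " > ",
         nTrials, " trials)")
  c(w, rep(0, nTrials - length(w)))
}

#' Write / read a decoder as JSON
#'
#' Matrices are stored row-major with explicit shape fields for exact
#' reload.
#'
#' @param decoder a \linkS4class{KalmanDecoder}.
#' @param path file path.
#' @return \code{writeDecoder} returns the path invisibly;
#'   \code{readDecoder} returns the decoder.
#' @export
writeDecoder <- function(decoder, path) {
  mat <- function(M) list(shape = dim(M), data = as.vector(t(M)))
  obj <- list(schema_version = 1L, unitIds = decoder@unitIds,
              binMs = decoder@binMs, H = mat(decoder@H), Q = mat(decoder@Q),
              A = mat(decoder@A), W = mat(decoder@W),
              meta = decoder@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDecoder
#' @export
readDecoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(m) matrix(m$data, m$shape[1L], m$shape[2L], byrow = TRUE)
  new("KalmanDecoder", unitIds = as.integer(obj$unitIds), H = mat(obj$H),
      Q = mat(obj$Q), A = mat(obj$A), W = mat(obj$W), binMs = obj$binMs,
      meta = as.list(obj$meta))
}
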