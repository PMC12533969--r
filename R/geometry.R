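## Trajectory geometry: the visuomotor rotation, the shared
## target/perturbation frame, midpoint angular error, and deflection.

.rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3L, 3L)
}

#' Apply the visuomotor rotation to a point or path
#'
#' Rotates the X-Y (fronto-parallel) components about the Z axis by the
#' given angle; Z is unaffected and the norm is preserved. "CCW" is a
#' positive rotation about +Z (right-handed frame, X rightward, Y upward,
#' Z toward the subject).
#'
#' @param point a length-3 vector or an n x 3 matrix (rows = samples).
#' @param rotationDeg rotation magnitude in degrees.
#' @param direction "CCW" or "CW".
#' @return the rotated point(s), same shape as the input.
#' @examples
#' applyVmr(c(1, 0, 0), 30, "CCW")  # (cos30, sin30, 0)
#' applyVmr(c(0, 0, 5), 30, "CCW")  # depth axis unperturbed
#' @export
applyVmr <- function(point, rotationDeg, direction = c("CCW", "CW")) {
  direction <- match.arg(direction)
  signed <- if (direction == "CCW") rotationDeg else -rotationDeg
  R <- .rotZ(signed)
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L, all(is.finite(point)))
    point %*% t(R)
  } else {
    stopifnot(length(point) == 3L, all(is.finite(point)))
    drop(R %*% point)
  }
}

#' Express a 3D trajectory in the shared target/perturbation frame
#'
#' The trajectory is first projected onto the X-Y plane of the applied
#' perturbation, then expressed in the basis (center-to-target in-plane
#' direction, orthogonal in-plane direction). The orthogonal axis is
#' oriented by \code{rotationSign} so that positive values point toward the
#' applied visual rotation; clockwise and counterclockwise sessions
#' therefore average coherently in this frame.
#'
#' @param traj an n x 3 matrix of positions (mm), starting at the center.
#' @param target the length-3 target position (mm).
#' @param rotationSign +1 for CCW sessions, -1 for CW.
#' @return an \linkS4class{AlignedTrajectory}.
#' @export
alignToTargetFrame <- function(traj, target, rotationSign = 1) {
  stopifnot(is.matrix(traj), ncol(traj) == 3L,
            rotationSign %in% c(-1, 1))
  t2 <- target[1:2]
  nt <- sqrt(sum(t2^2))
  if (nt < 1e-9)
    stop("degenerate target: no in-plane component")
  that <- t2 / nt
  # CCW-orthogonal of the target direction, flipped for CW sessions
  phat <- rotationSign * c(-that[2L], that[1L])
  xy <- traj[, 1:2, drop = FALSE]
  new("AlignedTrajectory",
      alongTarget = drop(xy %*% that),
      alongPerturbation = drop(xy %*% phat),
      rotationSign = as.numeric(rotationSign))
}

#' Midpoint angular error of an aligned trajectory
#'
#' The trial-by-trial angular movement error: the signed angle, in the
#' perturbation plane, of the position halfway along the trajectory
#' relative to the straight center-to-target line. Positive angles point
#' toward the applied visual rotation (the frame's sign convention). By
#' default "halfway" means 50% of cumulative path length; a
#' normalized-time variant is available.
#'
#' @param traj an \linkS4class{AlignedTrajectory} with at least 3 samples
#'   and nonzero path length.
#' @param method "pathlength" (default) or "time".
#' @return the signed angle in degrees, in (-180, 180].
#' @export
midpointAngle <- function(traj, method = c("pathlength", "time")) {
  method <- match.arg(method)
  x <- traj@alongTarget
  y <- traj@alongPerturbation
  n <- length(x)
  if (n < 3L) stop("trajectory must have at least 3 samples")
  if (method == "pathlength") {
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    s <- c(0, cumsum(seg))
    if (s[n] <= 0) stop("zero-length trajectory")
    half <- s[n] / 2
    i <- findInterval(half, s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    w <- if (seg[i] > 0) (half - s[i]) / seg[i] else 0
    px <- x[i] + w * (x[i + 1L] - x[i])
    py <- y[i] + w * (y[i + 1L] - y[i])
  } else {
    tt <- seq(0, 1, length.out = n)
    px <- stats::approx(tt, x, xout = 0.5)$y
    py <- stats::approx(tt, y, xout = 0.5)$y
  }
  if (abs(px) < 1e-12 && abs(py) < 1e-12) stop("zero-length trajectory")
  atan2(py, px) * 180 / pi
}

#' Deflection of an aligned trajectory at a movement fraction
#'
#' The coordinate along the perturbation axis at the sample closest to the
#' given fraction of the movement (fraction = 1 is the end of movement).
#' Positive deflections lie on the visual-feedback side of the direct path,
#' negative deflections on the compensatory motor side. The fraction is
#' measured on normalized movement time by default; a path-length variant
#' is available.
#'
#' @param traj an \linkS4class{AlignedTrajectory}.
#' @param fraction movement fraction in (0, 1].
#' @param basis "time" (default) or "pathlength".
#' @return deflection in mm (arbitrary units for memory reconstructions).
#' @export
deflection <- function(traj, fraction = 1, basis = c("time", "pathlength")) {
  basis <- match.arg(basis)
  y <- traj@alongPerturbation
  n <- length(y)
  if (n == 0L) stop("empty trajectory")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (basis == "time") {
    frac <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  } else {
    x <- traj@alongTarget
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    frac <- if (s[n] > 0) s / s[n] else rep(0, n)
  }
  y[which.min(abs(frac - fraction))]
}

#' Average aligned trajectories on a common time base
#'
#' Each trajectory is resampled to \code{nPoints} by linear interpolation
#' over normalized time, then averaged pointwise. The per-point samples are
#' kept in the result's \code{samples} slot so bootstrap confidence bands
#' can be drawn from them.
#'
#' @param trajs a list of \linkS4class{AlignedTrajectory} (each with at
#'   least 2 samples, same rotation sign).
#' @param nPoints number of resampling points.
#' @return an \linkS4class{AlignedTrajectory} with sample matrices attached.
#' @export
averageAligned <- function(trajs, nPoints = 100L) {
  if (length(trajs) == 0L) stop("empty trajectory list")
  stopifnot(all(vapply(trajs, function(tr) length(tr@alongTarget) >= 2L,
                       logical(1))))
  tt <- seq(0, 1, length.out = nPoints)
  res <- function(v) {
    n <- length(v)
    stats::approx(seq(0, 1, length.out = n), v, xout = tt)$y
  }
  at <- t(vapply(trajs, function(tr) res(tr@alongTarget), numeric(nPoints)))
  ap <- t(vapply(trajs, function(tr) res(tr@alongPerturbation),
                 numeric(nPoints)))
  new("AlignedTrajectory",
      alongTarget = colMeans(at),
      alongPerturbation = colMeans(ap),
      rotationSign = trajs[[1L]]@rotationSign,
      samples = list(alongTarget = at, alongPerturbation = ap))
}

#' Export aligned trajectories as a tidy data frame
#'
#' @param trajs a list of \linkS4class{AlignedTrajectory}.
#' @param trial optional trial labels (defaults to list position).
#' @return a data.frame with columns trial, bin, alongTarget,
#'   alongPerturbation.
#' @export
alignedAsDataFrame <- function(trajs, trial = seq_along(trajs)) {
  do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(trial = trial[i], bin = seq_along(tr@alongTarget),
               alongTarget = tr@alongTarget,
               alongPerturbation = tr@alongPerturbation)
  }))
}
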