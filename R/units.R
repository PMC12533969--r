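#' Build a unit roster for the simulator
#'
#' Generates linearly velocity-tuned units (firing rate = b0 + b . v per
#' bin) in areas M1, PMd and PRR, with preferred directions approximately
#' uniform on the sphere, plus rank-k loadings onto shared latent factors.
#' A configurable subset of M1/PMd units is connected to the online decoder
#' (controlling units); PRR units are connected only under the
#' frontoparietal decoder configuration (\code{prrControlling = TRUE}).
#'
#' Noncontrolling populations carry an \code{adaptationGain} in [0, 1] (the
#' fraction of the controlling population's compensatory aim rotation they
#' express) and a \code{frame}: \code{"motor"} units encode the (gain-scaled)
#' produced command, \code{"visual"} units encode the rotated cursor
#' feedback. Controlling units are always motor-frame with gain 1 -- their
#' activity *is* the command. The three generator hypotheses about
#' noncontrolling coding are obtained as: stationary non-adaptive
#' (\code{frame = "motor"}, gain 0), visual-feedback tuned
#' (\code{frame = "visual"}), and motor re-association
#' (\code{frame = "motor"}, gain > 0).
#'
#' Uses the current RNG state; call \code{set.seed()} first for
#' reproducibility (or let [generateSession()] do it).
#'
#' @param nM1,nPMd,nPRR unit counts per area.
#' @param controllingFraction fraction of M1/PMd units wired to the decoder.
#' @param prrControlling if TRUE, PRR units are also wired (FP decoder);
#'   otherwise PRR is fully disconnected (FO decoder).
#' @param b0Range range of baseline rates (counts/bin); each unit's
#'   baseline is floored at 1.05 x its tuning norm x \code{speedRange} so
#'   expected rates never rectify at zero within the task's speed range.
#' @param tuningRange range of tuning-vector norms (counts/bin per mm/s).
#' @param planningGain scaling of the directional term during planning.
#' @param noiseSd private rate noise sd (counts/bin).
#' @param latentRank number of shared latent factors.
#' @param latentScale sd of latent loadings (counts/bin per factor sd).
#' @param gainM1PMdNon adaptation gain of noncontrolling M1/PMd units.
#' @param gainPRRNon adaptation gain of noncontrolling PRR units.
#' @param frameNoncontrolling spatial frame of noncontrolling units,
#'   "motor" or "visual".
#' @param speedRange speed range (mm/s) over which rates must remain
#'   non-negative (the task's minimum-jerk peak speed by default).
#' @return a list of class "UnitRoster" with elements \code{table} (one row
#'   per unit) and \code{loadings} (units x latentRank matrix).
#' @export
makeUnits <- function(nM1 = 32L, nPMd = 32L, nPRR = 32L,
                      controllingFraction = 0.5, prrControlling = FALSE,
                      b0Range = c(0.5, 2), tuningRange = c(0.004, 0.012),
                      planningGain = 0.7, noiseSd = 0.3,
                      latentRank = 4L, latentScale = 0.15,
                      gainM1PMdNon = 0.75, gainPRRNon = 0.25,
                      frameNoncontrolling = c("motor", "visual"),
                      speedRange = 165) {
  frameNoncontrolling <- match.arg(frameNoncontrolling)
  area <- rep(c("M1", "PMd", "PRR"), c(nM1, nPMd, nPRR))
  n <- length(area)
  stopifnot(n >= 2L)
  ctrl <- logical(n)
  for (a in c("M1", "PMd")) {
    idx <- which(area == a)
    k <- round(controllingFraction * length(idx))
    ctrl[head(idx, k)] <- TRUE
  }
  ctrl[area == "PRR"] <- prrControlling
  dirs <- matrix(rnorm(3L * n), n, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  mag <- runif(n, tuningRange[1L], tuningRange[2L])
  ## baseline floored so expected rates stay non-negative over the task's
  ## speed range (tuned cells modulate around an elevated baseline);
  ## keeps the rate model linear where the Kalman filter assumes it
  b0 <- pmax(runif(n, b0Range[1L], b0Range[2L]), 1.05 * mag * speedRange)
  gain <- ifelse(ctrl, 1,
                 ifelse(area == "PRR", gainPRRNon, gainM1PMdNon))
  frame <- ifelse(ctrl, "motor", frameNoncontrolling)
  tab <- data.frame(
    unit = seq_len(n), area = area, controlling = ctrl, b0 = b0,
    bx = dirs[, 1L] * mag, by = dirs[, 2L] * mag, bz = dirs[, 3L] * mag,
    planningGain = planningGain, noiseSd = noiseSd,
    adaptationGain = gain, frame = frame,
    stringsAsFactors = FALSE)
  loadings <- matrix(rnorm(n * latentRank, 0, latentScale), n, latentRank)
  structure(list(table = tab, loadings = loadings), class = "UnitRoster")
}

#' Trial-by-trial re-association learning model
#'
#' A single scalar aim angle in the perturbation plane, shared across the
#' population, updated after every trial by
#' \code{aim <- retention * aim - learningRate * error}, where the error is
#' the signed (CCW-positive) midpoint angular error of that trial's cursor
#' path. Noncontrolling populations express this aim scaled by their
#' adaptation gain. With \code{learningRate = 0} the aim never moves; the
#' fixed point under a rotation R is
#' \code{-learningRate * R / (1 - retention + learningRate)}, whose
#' magnitude never exceeds R.
#'
#' @param learningRate per-trial learning rate in [0, 1).
#' @param retention retention factor in (0, 1].
#' @param aimDeg0 initial aim offset (degrees, CCW-positive).
#' @return a list of class "LearningModel".
#' @export
learningModel <- function(learningRate = 0.02, retention = 0.995,
                          aimDeg0 = 0) {
  stopifnot(learningRate >= 0, learningRate < 1,
            retention > 0, retention <= 1)
  structure(list(learningRate = learningRate, retention = retention,
                 aimDeg0 = aimDeg0),
            class = "LearningModel")
}
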