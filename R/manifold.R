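## Principal-component variance structure, the alignment index between
## epochs, and planning-to-movement cross-projection.

## Common planning bins across trials: the cue + fixed planning period
## (variable delay bins are dropped so trials align).
.epochBins <- function(session, trial, period) {
  tt <- session@trials
  if (period == "movement")
    seq.int(tt$goBin[trial], tt$endBin[trial])
  else
    seq_len((session@task$cueMs + session@task$planningMs) /
              session@task$binMs)
}

#' Unit covariance of an epoch
#'
#' Builds the covariance substrate for the manifold analyses: per-target
#' trial-averaged counts over the epoch's bins, concatenated across targets,
#' optionally soft-normalized per unit (divide by the firing-rate range
#' plus 5 spikes/s), then mean-centered; returns the unit-by-unit
#' covariance. A single-trial (non-averaged) variant is available.
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices.
#' @param phase trial phase ("baseline", "rotation", "washout").
#' @param period "movement" or "planning".
#' @param trials optional explicit trial subset (e.g. late rotation).
#' @param softNorm apply soft normalization (default TRUE).
#' @param trialAverage average trials within target (default TRUE).
#' @return a units x units covariance matrix.
#' @export
epochCovariance <- function(session, unitIndex, phase = "baseline",
                            period = c("movement", "planning"),
                            trials = NULL, softNorm = TRUE,
                            trialAverage = TRUE) {
  period <- match.arg(period)
  if (is.null(trials)) trials <- phaseTrials(session, phase)
  if (length(trials) < 2L) stop("need at least 2 trials in the epoch")
  tt <- session@trials
  nb <- length(.epochBins(session, trials[1L], period))
  rows <- list()
  if (trialAverage) {
    for (tg in sort(unique(tt$target[trials]))) {
      trs <- trials[tt$target[trials] == tg]
      acc <- matrix(0, nb, length(unitIndex))
      for (tr in trs)
        acc <- acc + session@counts[tr, .epochBins(session, tr, period),
                                    unitIndex, drop = TRUE]
      rows[[length(rows) + 1L]] <- acc / length(trs)
    }
  } else {
    for (tr in trials)
      rows[[length(rows) + 1L]] <-
        session@counts[tr, .epochBins(session, tr, period), unitIndex,
                       drop = TRUE]
  }
  M <- do.call(rbind, rows)
  if (softNorm) {
    ## 5 spikes/s expressed in counts per bin
    soft <- 5 * session@task$binMs / 1000
    rng <- apply(M, 2L, function(v) diff(range(v)))
    M <- sweep(M, 2L, rng + soft, "/")
  }
  M <- scale(M, center = TRUE, scale = FALSE)
  crossprod(M) / (nrow(M) - 1L)
}

#' Alignment index between two epochs
#'
#' The fraction of the projected epoch's top-subspace variance that is
#' captured by the reference epoch's top principal components:
#' \code{ai = tr(P' C_proj P) / sum(top-nPcs eigenvalues of C_proj)}, where
#' P holds the top nPcs eigenvectors of the reference covariance. An epoch
#' aligned with itself (no cross-validation) gives exactly 1; orthogonal
#' top subspaces give ~0. Values slightly above 1 can occur under
#' cross-validation noise and are flagged beyond 1.05.
#'
#' @param covReference reference covariance (defines the PCs).
#' @param covProjected covariance of the projected epoch.
#' @param nPcs number of principal components (default 4).
#' @param epochPair optional labels c(reference, projected).
#' @param crossValidated flag stored in the result.
#' @return a list of class "AlignmentResult" with the \code{ai} ratio.
#' @export
alignmentIndex <- function(covReference, covProjected, nPcs = 4L,
                           epochPair = c("reference", "projected"),
                           crossValidated = FALSE) {
  stopifnot(all(dim(covReference) == dim(covProjected)),
            nPcs >= 1L, nPcs <= ncol(covReference))
  er <- eigen(.symmetrize(covReference), symmetric = TRUE)
  if (er$values[nPcs] <= max(er$values[1L], 0) * 1e-12)
    stop("nPcs exceeds the rank of the reference covariance")
  P <- er$vectors[, seq_len(nPcs), drop = FALSE]
  ep <- eigen(.symmetrize(covProjected), symmetric = TRUE,
              only.values = TRUE)$values
  ai <- sum(diag(t(P) %*% covProjected %*% P)) / sum(ep[seq_len(nPcs)])
  if (ai > 1.05)
    warning("alignment index > 1.05; check covariance estimates")
  structure(list(epochPair = epochPair, nPcs = as.integer(nPcs), ai = ai,
                 crossValidated = crossValidated),
            class = "AlignmentResult")
}

#' Cross-validated baseline alignment index
#'
#' Baseline trials are split in random halves; the principal components are
#' taken from one half and the variance ratio from the other, then averaged
#' over splits. This is the reference value against which the rotation-phase
#' alignment index is compared, so that estimation noise does not masquerade
#' as manifold change. Uses the current RNG state.
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices.
#' @param nPcs number of principal components.
#' @param nSplits number of random half-splits.
#' @param period "movement" or "planning".
#' @return a list of class "AlignmentResult" (ai averaged over splits).
#' @export
crossValidatedBaselineAI <- function(session, unitIndex, nPcs = 4L,
                                     nSplits = 10L,
                                     period = c("movement", "planning")) {
  period <- match.arg(period)
  trials <- phaseTrials(session, "baseline")
  if (length(trials) < 2L * nSplits && length(trials) < 4L)
    stop("too few baseline trials for cross-validation")
  ais <- numeric(nSplits)
  for (s in seq_len(nSplits)) {
    half <- sample(trials, floor(length(trials) / 2))
    other <- setdiff(trials, half)
    cA <- epochCovariance(session, unitIndex, period = period, trials = half)
    cB <- epochCovariance(session, unitIndex, period = period, trials = other)
    ais[s] <- alignmentIndex(cA, cB, nPcs = nPcs)$ai
  }
  structure(list(epochPair = c("baseline", "baseline"),
                 nPcs = as.integer(nPcs), ai = mean(ais),
                 crossValidated = TRUE),
            class = "AlignmentResult")
}

#' Planning-to-movement cross-projection
#'
#' Takes the principal components of the movement-epoch covariance and
#' reports the fraction of planning-epoch variance they capture, alongside
#' the movement epoch's self-projection. The component count is either a
#' fixed number (top 4 by default) or the number needed to explain 90% of
#' the movement (reference) variance.
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices.
#' @param nPcs fixed component count (used when \code{pcCriterion="fixed"}).
#' @param pcCriterion "fixed" or "var90".
#' @param phase trial phase used for both epochs (default "baseline").
#' @return a list with \code{planningFraction}, \code{movementFraction} and
#'   the \code{nPcs} actually used.
#' @export
crossProjectPlanning <- function(session, unitIndex, nPcs = 4L,
                                 pcCriterion = c("fixed", "var90"),
                                 phase = "baseline") {
  pcCriterion <- match.arg(pcCriterion)
  cMov <- epochCovariance(session, unitIndex, phase, period = "movement")
  cPlan <- epochCovariance(session, unitIndex, phase, period = "planning")
  em <- eigen(.symmetrize(cMov), symmetric = TRUE)
  if (pcCriterion == "var90") {
    cum <- cumsum(pmax(em$values, 0)) / sum(pmax(em$values, 0))
    nPcs <- which(cum >= 0.9)[1L]
  }
  P <- em$vectors[, seq_len(nPcs), drop = FALSE]
  list(planningFraction =
         sum(diag(t(P) %*% cPlan %*% P)) / sum(diag(cPlan)),
       movementFraction =
         sum(em$values[seq_len(nPcs)]) / sum(diag(cMov)),
       nPcs = as.integer(nPcs))
}
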