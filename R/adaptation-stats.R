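## Adaptation-curve fits, deflection tests, tuning-shift estimation,
## decoder contribution, firing-rate comparisons, and the hierarchical
## planning-to-movement model.

#' Exponential fit of the trial-by-trial angular error
#'
#' Nonlinear least squares of \code{alpha(t) = a * exp(b * t)} on the
#' pooled per-trial angular errors of one or more sessions, with
#' session-clustered bootstrap inference: sessions are resampled with
#' replacement, the model refit, and two-sided p-values for the intercept a
#' and decay b taken from the sign distribution of the bootstrap
#' estimates. With a single session, trials are resampled instead.
#' Multi-start initialization guards against non-convergence.
#'
#' @param alphaDeg per-trial angular errors (degrees), pooled.
#' @param trial within-phase trial index, 0-based (prediction at trial 0
#'   equals the intercept). Defaults to order within session.
#' @param session session labels for clustered resampling.
#' @param phase label stored in the result.
#' @param nBoot bootstrap resamples (2000 for publication-grade inference;
#'   reduce for quick checks).
#' @return a list of class "AdaptationFit" with \code{interceptDeg},
#'   \code{decayPerTrial}, \code{pIntercept}, \code{pDecay}, bootstrap
#'   percentile CIs and \code{n} (number of sessions).
#' @export
fitExponential <- function(alphaDeg, trial = NULL, session = NULL,
                           phase = "rotation", nBoot = 2000L) {
  if (length(alphaDeg) < 10L) stop("need at least 10 trials")
  if (is.null(session)) session <- rep(1L, length(alphaDeg))
  session <- as.character(session)
  if (is.null(trial)) {
    trial <- stats::ave(seq_along(alphaDeg), session,
                        FUN = function(i) seq_along(i) - 1)
  }
  fit1 <- function(a, t) {
    best <- NULL
    a0 <- mean(head(a[order(t)], max(5L, length(a) %/% 10L)))
    if (!is.finite(a0) || a0 == 0) a0 <- mean(a)
    for (b0 in c(-0.01, -0.003, -0.001, 0, 0.003)) {
      f <- tryCatch(
        minpack.lm::nlsLM(a ~ A * exp(B * t),
                          start = list(A = a0, B = b0),
                          data = data.frame(a = a, t = t),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rss <- sum(stats::resid(f)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(coef = coef(f), rss = rss)
      }
    }
    if (is.null(best)) stop("exponential fit did not converge")
    best$coef
  }
  cf <- fit1(alphaDeg, trial)
  sessions <- unique(session)
  if (nBoot == 0L) {
    return(structure(list(
      interceptDeg = unname(cf[1L]), decayPerTrial = unname(cf[2L]),
      pIntercept = NA_real_, pDecay = NA_real_,
      ciIntercept = c(NA_real_, NA_real_), ciDecay = c(NA_real_, NA_real_),
      n = length(sessions), nBoot = 0L, phase = phase),
      class = "AdaptationFit"))
  }
  boot <- matrix(NA_real_, nBoot, 2L)
  for (r in seq_len(nBoot)) {
    if (length(sessions) > 1L) {
      pick <- sample(sessions, replace = TRUE)
      idx <- unlist(lapply(pick, function(s) which(session == s)))
    } else {
      idx <- sample(seq_along(alphaDeg), replace = TRUE)
    }
    boot[r, ] <- tryCatch(fit1(alphaDeg[idx], trial[idx]),
                          error = function(e) c(NA_real_, NA_real_))
  }
  boot <- boot[complete.cases(boot), , drop = FALSE]
  pval <- function(v) {
    if (nrow(boot) == 0L) return(NA_real_)
    max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / nrow(boot))
  }
  structure(list(
    interceptDeg = unname(cf[1L]), decayPerTrial = unname(cf[2L]),
    pIntercept = pval(boot[, 1L]), pDecay = pval(boot[, 2L]),
    ciIntercept = unname(quantile(boot[, 1L], c(0.025, 0.975),
                                  na.rm = TRUE)),
    ciDecay = unname(quantile(boot[, 2L], c(0.025, 0.975), na.rm = TRUE)),
    n = length(sessions), nBoot = nrow(boot), phase = phase),
    class = "AdaptationFit")
}

#' @export
print.AdaptationFit <- function(x, ...) {
  cat(sprintf(
    "Exponential adaptation fit (%s, n = %d sessions):\n", x$phase, x$n))
  cat(sprintf("  intercept = %.3f deg (p = %.4g)\n", x$interceptDeg,
              x$pIntercept))
  cat(sprintf("  decay     = %.5f per trial (p = %.4g)\n", x$decayPerTrial,
              x$pDecay))
  invisible(x)
}

#' One-sample test of end-of-movement deflections
#'
#' Two-sided one-sample t test of per-session mean deflections against
#' zero.
#'
#' @param deflectionsBySession numeric vector, one mean deflection per
#'   session (at least 3).
#' @return a list with t, df, p, mean, sd and n.
#' @export
testDeflections <- function(deflectionsBySession) {
  x <- deflectionsBySession
  if (length(x) < 3L) stop("need at least 3 sessions")
  if (sd(x) == 0) {
    return(list(t = NA_real_, df = length(x) - 1L,
                p = if (mean(x) == 0) 1 else 0,
                mean = mean(x), sd = 0, n = length(x),
                degenerate = TRUE))
  }
  ht <- t.test(x, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(x), sd = sd(x), n = length(x),
       degenerate = FALSE)
}

## Signed circular difference in (-180, 180]
.circDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Regression of a unit's counts on the intended (straight-to-target)
## command velocity over given trials; returns the fitted tuning vector.
.tuningFit <- function(session, unitIndex, trials, epoch) {
  tt <- session@trials
  targets <- .sessionTargets(session)
  dt <- session@task$binMs / 1000
  nMove <- session@task$movementMs / session@task$binMs
  Y <- list(); X <- list()
  for (tr in trials) {
    tg <- targets[tt$target[tr], ]
    if (epoch == "movement") {
      bins <- seq.int(tt$goBin[tr], tt$endBin[tr])
      V <- .minimumJerkVelocity(tg, nMove, dt)
    } else {
      bins <- .epochBins(session, tr, "planning")
      V <- matrix(tg / sqrt(sum(tg^2)), length(bins), 3L, byrow = TRUE)
    }
    Y[[length(Y) + 1L]] <- session@counts[tr, bins, unitIndex, drop = FALSE]
    X[[length(X) + 1L]] <- V
  }
  Y <- do.call(rbind, lapply(Y, function(a) matrix(a, ncol =
                                                     length(unitIndex))))
  X <- cbind(do.call(rbind, X), 1)
  B <- solve(crossprod(X) + 1e-10 * diag(4L), crossprod(X, Y))
  t(B)[, 1:3, drop = FALSE]   # units x (bx, by, bz)
}

#' Preferred-direction shift between baseline and rotation
#'
#' Fits each unit's tuning vector per phase by linear regression of counts
#' on the intended straight-to-target command (minimum-jerk velocity during
#' movement; unit target direction during planning), takes the in-plane
#' preferred direction (PD) as the X-Y angle of the fitted vector, and
#' reports the signed circular shift rotation minus baseline
#' (CCW-positive). Under re-association a population with adaptation gain g
#' shifts by minus g times the aim, i.e. in the direction of the applied
#' rotation, which is exactly the shift that implements the behavioral
#' compensation. Units whose in-plane tuning norm falls below
#' \code{minNorm} in either phase are excluded (reported in the result).
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices (default: all units).
#' @param epoch "movement" or "planning".
#' @param lateFraction use only the last fraction of rotation trials
#'   (default 0.5, the adapted part of the phase).
#' @param minNorm exclusion threshold on the in-plane tuning norm
#'   (counts/bin per mm/s for movement; counts/bin for planning).
#' @return a data.frame with unit, pdBaselineDeg, pdRotationDeg, shiftDeg,
#'   epoch; excluded units carry NA shifts.
#' @export
pdShift <- function(session, unitIndex = seq_len(nUnits(session)),
                    epoch = c("movement", "planning"), lateFraction = 0.5,
                    minNorm = 1e-4) {
  epoch <- match.arg(epoch)
  bTrials <- phaseTrials(session, "baseline")
  rTrials <- phaseTrials(session, "rotation", lateFraction)
  if (length(bTrials) < 8L || length(rTrials) < 8L)
    stop("not enough trials per phase for tuning regression")
  Bb <- .tuningFit(session, unitIndex, bTrials, epoch)
  Br <- .tuningFit(session, unitIndex, rTrials, epoch)
  nb <- sqrt(rowSums(Bb[, 1:2, drop = FALSE]^2))
  nr <- sqrt(rowSums(Br[, 1:2, drop = FALSE]^2))
  ok <- nb >= minNorm & nr >= minNorm
  if (any(!ok))
    message("pdShift: excluding ", sum(!ok), " weakly tuned unit(s)")
  pdb <- atan2(Bb[, 2L], Bb[, 1L]) * 180 / pi
  pdr <- atan2(Br[, 2L], Br[, 1L]) * 180 / pi
  out <- data.frame(unit = unitIndex, pdBaselineDeg = pdb,
                    pdRotationDeg = pdr,
                    shiftDeg = .circDiff(pdr, pdb), epoch = epoch)
  out$shiftDeg[!ok] <- NA_real_
  out
}

#' Decoder contribution of each unit
#'
#' The amplitude of the regression vector translating velocity into the
#' unit's firing rate, summed with its baseline rate:
#' \code{||(b1, b2, b3)|| + b0}. A single scalar reflecting how much
#' leverage the unit has on the decoded cursor state.
#'
#' @param decoder a \linkS4class{KalmanDecoder}.
#' @param unit optional roster indices to report (default: all).
#' @return a data.frame with unit and score.
#' @export
decoderContribution <- function(decoder, unit = NULL) {
  H <- decoder@H
  score <- sqrt(rowSums(H[, 1:3, drop = FALSE]^2)) + H[, 4L]
  out <- data.frame(unit = decoder@unitIds, score = score)
  if (!is.null(unit)) out <- out[match(unit, out$unit), ]
  rownames(out) <- NULL
  out
}

#' Per-trial planning and movement re-aiming deflections
#'
#' For the rotation-phase trials of a session, pairs the deflection of the
#' memory-period reconstruction at the end of planning (arbitrary units)
#' with the deflection of the movement-period reconstruction 200 ms after
#' the go cue (mm; early window to limit feedback-driven corrections).
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices of the population.
#' @param population population label.
#' @param sessionId,animalId identifiers for the hierarchical model.
#' @param movementMs deflection time for the movement reconstruction
#'   (snapped to the bin grid).
#' @return a data.frame with planningDeflection, movementDeflection,
#'   trialNumber, population, session, animal.
#' @export
planningMovementTable <- function(session, unitIndex,
                                  population = "population",
                                  sessionId = "s1", animalId = "a1",
                                  movementMs = 200) {
  trials <- phaseTrials(session, "rotation")
  recM <- reconMemory(session, unitIndex, "rotation", trials = trials)
  recV <- reconMovement(session, unitIndex, "rotation", trials = trials)
  frac <- movementMs / session@task$movementMs
  mdefl <- vapply(recV@aligned, deflection, numeric(1), fraction = frac)
  data.frame(planningDeflection = recM@deflectionEnd,
             movementDeflection = mdefl,
             trialNumber = seq_along(trials),
             population = population, session = sessionId,
             animal = animalId, stringsAsFactors = FALSE)
}

#' Hierarchical model linking planning to movement re-aiming
#'
#' Mixed-effects model of the movement deflection on the planning
#' deflection and its interaction with trial number, with random intercepts
#' for recording session nested in animal:
#' \code{movement ~ 1 + planning + planning:trial + (1 | animal/session)}.
#' A positive interaction means the same degree of planning re-aiming
#' translates into larger movement corrections as learning progresses.
#' When several populations are present, a second model with
#' planning-by-population interactions performs all pairwise slope
#' comparisons, Bonferroni-corrected. If the nested random-effects fit is
#' singular or the grouping is degenerate, the model falls back to fixed
#' session effects (flagged in the result).
#'
#' @param table a [planningMovementTable()] (rotation-phase trials only),
#'   possibly row-bound across sessions/populations.
#' @param level confidence level for Wald CIs.
#' @return a list of class "PlanningMovementFit": \code{slope},
#'   \code{interaction}, \code{pSlope}, \code{pInteraction}, Wald CIs,
#'   \code{pairwise} (data.frame or NULL) and \code{fallback}.
#' @export
planningMovementModel <- function(table, level = 0.95) {
  need <- c("planningDeflection", "movementDeflection", "trialNumber",
            "session", "animal")
  stopifnot(all(need %in% names(table)))
  if (length(unique(table$session)) < 2L)
    stop("need at least 2 sessions")
  table$session <- factor(table$session)
  table$animal <- factor(table$animal)
  multiAnimal <- nlevels(table$animal) > 1L
  form <- if (multiAnimal)
    movementDeflection ~ planningDeflection +
      planningDeflection:trialNumber + (1 | animal / session)
  else
    movementDeflection ~ planningDeflection +
      planningDeflection:trialNumber + (1 | session)
  fallback <- FALSE
  fit <- tryCatch(
    lmerTest::lmer(form, data = table,
                   control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- lm(movementDeflection ~ planningDeflection +
                planningDeflection:trialNumber + session, data = table)
    ct <- summary(fit)$coefficients
    rows <- c("planningDeflection", "planningDeflection:trialNumber")
    ci <- confint(fit, rows, level = level)
  } else {
    ct <- coef(summary(fit))
    rows <- c("planningDeflection", "planningDeflection:trialNumber")
    ci <- confint(fit, rows, method = "Wald", level = level)
  }
  pcol <- grep("^Pr", colnames(ct))
  pairwise <- NULL
  if ("population" %in% names(table) &&
      length(unique(table$population)) > 1L) {
    pops <- sort(unique(as.character(table$population)))
    pairs <- utils::combn(pops, 2L)
    nPair <- ncol(pairs)
    pw <- data.frame(pop1 = pairs[1L, ], pop2 = pairs[2L, ],
                     slopeDiff = NA_real_, p = NA_real_,
                     pBonferroni = NA_real_)
    for (k in seq_len(nPair)) {
      sub <- table[table$population %in% pairs[, k], ]
      sub$population <- factor(sub$population, levels = pairs[, k])
      pform <- if (nlevels(droplevels(sub$animal)) > 1L)
        movementDeflection ~ planningDeflection +
          planningDeflection:population + (1 | animal / session)
      else
        movementDeflection ~ planningDeflection +
          planningDeflection:population + (1 | session)
      pf <- tryCatch(
        lmerTest::lmer(pform, data = sub,
                       control = lme4::lmerControl(check.conv.singular =
                           lme4::.makeCC(action = "ignore", tol = 1e-4))),
        error = function(e) NULL)
      if (is.null(pf)) {
        pf <- lm(movementDeflection ~ planningDeflection +
                   planningDeflection:population + session, data = sub)
        pct <- summary(pf)$coefficients
      } else pct <- coef(summary(pf))
      irow <- grep("planningDeflection:population", rownames(pct))[1L]
      pw$slopeDiff[k] <- pct[irow, 1L]
      pw$p[k] <- pct[irow, grep("^Pr", colnames(pct))]
    }
    pw$pBonferroni <- pmin(pw$p * nPair, 1)
    pairwise <- pw
  }
  structure(list(
    slope = ct["planningDeflection", 1L],
    interaction = ct["planningDeflection:trialNumber", 1L],
    pSlope = ct["planningDeflection", pcol],
    pInteraction = ct["planningDeflection:trialNumber", pcol],
    ciSlope = unname(ci["planningDeflection", ]),
    ciInteraction = unname(ci["planningDeflection:trialNumber", ]),
    pairwise = pairwise, fallback = fallback, model = fit),
    class = "PlanningMovementFit")
}

#' @export
print.PlanningMovementFit <- function(x, ...) {
  cat("Planning-to-movement hierarchical model",
      if (x$fallback) "(fixed-session fallback)" else "", "\n")
  cat(sprintf("  slope       = %.5f (p = %.4g)\n", x$slope, x$pSlope))
  cat(sprintf("  interaction = %.6f (p = %.4g)\n", x$interaction,
              x$pInteraction))
  if (!is.null(x$pairwise))
    cat("  pairwise slope comparisons: ", nrow(x$pairwise),
        " (Bonferroni-corrected)\n", sep = "")
  invisible(x)
}

#' Mean firing rate of a population in a phase
#'
#' @param session a \linkS4class{BCISession}.
#' @param unitIndex roster indices.
#' @param phase trial phase; "rotation" with \code{lateFraction} gives the
#'   adaptation epoch.
#' @param lateFraction optional late-trial restriction.
#' @return mean rate in spikes/s across the population.
#' @export
meanFiringRate <- function(session, unitIndex, phase,
                           lateFraction = NULL) {
  trials <- phaseTrials(session, phase, lateFraction)
  cts <- session@counts[trials, , unitIndex, drop = FALSE]
  mean(cts, na.rm = TRUE) / (session@task$binMs / 1000)
}

#' Compare population firing rates between phases across sessions
#'
#' Rank-sum (Mann-Whitney) test on per-session mean rates between two
#' phases.
#'
#' @param sessions a list of \linkS4class{BCISession}.
#' @param area,controlling unit selection (see [selectUnits()]).
#' @param phaseA,phaseB phases compared (late rotation used for
#'   "rotation").
#' @return a list with p, statistic, and the per-session rate vectors.
#' @export
compareRates <- function(sessions, area = c("M1", "PMd", "PRR"),
                         controlling = "all",
                         phaseA = "baseline", phaseB = "rotation") {
  if (!is.list(sessions) || length(sessions) < 2L)
    stop("need at least 2 sessions (insufficient replicates)")
  rate <- function(s, ph) {
    idx <- selectUnits(s, area, controlling)
    meanFiringRate(s, idx, ph,
                   lateFraction = if (ph == "rotation") 0.5 else NULL)
  }
  ra <- vapply(sessions, rate, numeric(1), ph = phaseA)
  rb <- vapply(sessions, rate, numeric(1), ph = phaseB)
  ht <- wilcox.test(ra, rb, exact = FALSE)
  list(p = ht$p.value, statistic = unname(ht$statistic),
       ratesA = ra, ratesB = rb)
}
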