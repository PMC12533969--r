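## Orchestration: reproducible generate -> decode -> analyze -> report runs
## and standard fixture sets.

#' Run configuration
#'
#' Bundles everything a reproducible run needs; serializing the config and
#' re-running reproduces the run exactly (all randomness derives from
#' \code{seed}).
#'
#' @param task a [taskConfig()].
#' @param schedule a [perturbationSchedule()].
#' @param unitArgs list of arguments to [makeUnits()] (per-population
#'   generator gains live here).
#' @param learning a [learningModel()].
#' @param nSessions number of sessions to simulate; rotation direction
#'   alternates CCW/CW across sessions.
#' @param seed master seed; session i uses seed + i.
#' @param analyses character subset of
#'   c("behavior", "recon", "manifold", "stats").
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(task = taskConfig(),
                      schedule = perturbationSchedule(),
                      unitArgs = list(), learning = learningModel(),
                      nSessions = 1L, seed = 1L,
                      analyses = c("behavior", "recon", "manifold",
                                   "stats")) {
  structure(list(task = task, schedule = schedule, unitArgs = unitArgs,
                 learning = learning, nSessions = as.integer(nSessions),
                 seed = as.integer(seed), analyses = analyses),
            class = "RunConfig")
}

.logLine <- function(logPath, stage, status, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage, status = status), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = logPath, append = TRUE)
}

#' Run a full experiment
#'
#' Generates the configured sessions, writes them to disk, and runs the
#' enabled analysis stages, each consuming only serialized artifacts of
#' earlier stages. Outputs: per-session directories, tidy CSV/JSON reports
#' per stage, a line-delimited JSON log, and a manifest with the package
#' version and a hash of the serialized config. Stages whose outputs
#' already exist are skipped (partial-run resume); analyses that need a
#' rotation phase are skipped with a log entry when the schedule has none.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param overwrite if TRUE, rerun stages whose outputs exist.
#' @return the output directory, invisibly.
#' @export
runExperiment <- function(config, outDir, overwrite = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.ndjson")
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(
    list(task = unclass(config$task), schedule = unclass(config$schedule),
         unitArgs = config$unitArgs, learning = unclass(config$learning),
         nSessions = config$nSessions, seed = config$seed,
         analyses = config$analyses),
    cfgPath, auto_unbox = TRUE, digits = NA)
  done <- function(f) !overwrite && file.exists(file.path(outDir, f))

  ## stage: generate
  sessions <- vector("list", config$nSessions)
  for (i in seq_len(config$nSessions)) {
    sdir <- file.path(outDir, sprintf("session_%02d", i))
    sched <- config$schedule
    sched$direction <- if (i %% 2L == 1L) "CCW" else "CW"
    if (!overwrite && file.exists(file.path(sdir, "config.json"))) {
      sessions[[i]] <- readSession(sdir)
      .logLine(logPath, "generate", "resumed", session = i)
    } else {
      set.seed(config$seed + i)
      units <- do.call(makeUnits, config$unitArgs)
      sessions[[i]] <- generateSession(config$task, sched, units,
                                       config$learning,
                                       seed = config$seed + i)
      writeSession(sessions[[i]], sdir)
      .logLine(logPath, "generate", "ok", session = i)
    }
  }
  hasRotation <- config$schedule$nRotation > 0L

  ## stage: behavior (adaptation curves)
  if ("behavior" %in% config$analyses && !done("behavior.csv")) {
    beh <- do.call(rbind, lapply(seq_along(sessions), function(i)
      cbind(session = i, trialTable(sessions[[i]])[
        c("trial", "phase", "target", "alphaDeg", "truthAimDeg")])))
    write.csv(beh, file.path(outDir, "behavior.csv"), row.names = FALSE)
    fits <- list()
    for (ph in intersect(c("baseline", "rotation", "washout"),
                         unique(beh$phase))) {
      sub <- beh[beh$phase == ph, ]
      if (nrow(sub) >= 10L) {
        f <- fitExponential(sub$alphaDeg, session = sub$session,
                            phase = ph, nBoot = 200L)
        fits[[ph]] <- f[c("interceptDeg", "decayPerTrial", "pIntercept",
                          "pDecay", "n")]
      }
    }
    jsonlite::write_json(fits, file.path(outDir, "adaptation_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    .logLine(logPath, "behavior", "ok")
  }

  ## stage: recon (offline deflections + relative gain)
  if ("recon" %in% config$analyses && !done("recon.csv")) {
    if (!hasRotation) {
      .logLine(logPath, "recon", "skipped", reason = "no rotation phase")
    } else {
      rows <- list()
      for (i in seq_along(sessions)) {
        s <- sessions[[i]]
        late <- phaseTrials(s, "rotation", 0.5)
        ctrl <- selectUnits(s, controlling = "controlling")
        rc <- reconMovement(s, ctrl, "rotation", trials = late)
        pops <- list(ctrl = rc)
        non <- tryCatch(selectUnits(s, c("M1", "PMd"), "noncontrolling"),
                        error = function(e) NULL)
        if (!is.null(non))
          pops$M1PMdNon <- reconMovement(s, non, "rotation", trials = late)
        prr <- tryCatch(selectUnits(s, "PRR", "noncontrolling"),
                        error = function(e) NULL)
        if (!is.null(prr))
          pops$PRRNon <- reconMovement(s, prr, "rotation", trials = late)
        for (nm in names(pops)) {
          gain <- if (nm == "ctrl") 100 else
            tryCatch(relativeGain(pops[[nm]], rc, nm)$gainPercent,
                     error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            session = i, population = nm,
            meanDeflectionEnd = mean(deflectionEnd(pops[[nm]])),
            relativeGainPercent = gain)
        }
      }
      write.csv(do.call(rbind, rows), file.path(outDir, "recon.csv"),
                row.names = FALSE)
      .logLine(logPath, "recon", "ok")
    }
  }

  ## stage: manifold (alignment indices)
  if ("manifold" %in% config$analyses && !done("manifold.csv")) {
    if (!hasRotation) {
      .logLine(logPath, "manifold", "skipped", reason = "no rotation phase")
    } else {
      rows <- list()
      for (i in seq_along(sessions)) {
        s <- sessions[[i]]
        idx <- selectUnits(s)
        cvb <- crossValidatedBaselineAI(s, idx)
        cb <- epochCovariance(s, idx, "baseline")
        cl <- epochCovariance(s, idx, "rotation",
                              trials = phaseTrials(s, "rotation", 0.5))
        ail <- alignmentIndex(cb, cl, epochPair = c("baseline",
                                                    "lateRotation"))
        rows[[length(rows) + 1L]] <- data.frame(
          session = i, aiBaselineCV = cvb$ai, aiLateRotation = ail$ai,
          nPcs = ail$nPcs)
      }
      write.csv(do.call(rbind, rows), file.path(outDir, "manifold.csv"),
                row.names = FALSE)
      .logLine(logPath, "manifold", "ok")
    }
  }

  ## stage: stats (cross-session tests)
  if ("stats" %in% config$analyses && !done("stats.json")) {
    out <- list()
    if (hasRotation && length(sessions) >= 3L &&
        file.exists(file.path(outDir, "recon.csv"))) {
      rec <- read.csv(file.path(outDir, "recon.csv"))
      for (pop in unique(rec$population)) {
        d <- rec$meanDeflectionEnd[rec$population == pop]
        if (length(d) >= 3L)
          out[[paste0("deflectionTest_", pop)]] <-
            testDeflections(d)[c("t", "df", "p", "mean", "sd", "n")]
      }
    }
    if (length(sessions) >= 2L)
      out$rateComparison <- tryCatch(
        compareRates(sessions)[c("p", "statistic")],
        error = function(e) NULL)
    jsonlite::write_json(out, file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    .logLine(logPath, "stats", "ok")
  }

  manifest <- list(package = "bcivmr",
                   version = as.character(utils::packageVersion("bcivmr")),
                   configHash = unname(tools::md5sum(cfgPath)),
                   nSessions = config$nSessions, seed = config$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .logLine(logPath, "manifest", "ok")
  invisible(outDir)
}

#' Standard fixture sessions
#'
#' \code{tiny}: 8 M1/PMd units, 24 trials (8 per phase), generated in
#' seconds -- the unit-test workhorse. \code{paper_like}: 96 units across
#' the three areas and the full 160 / 300 / 160 trial schedule used by the
#' acceptance analyses.
#'
#' @param scale "tiny" or "paper_like".
#' @param dir optional directory; if given, sessions are serialized there.
#' @param nSessions number of sessions.
#' @param seed master seed (session i uses seed + i).
#' @return a list of \linkS4class{BCISession}.
#' @export
makeFixtures <- function(scale = c("tiny", "paper_like"), dir = NULL,
                         nSessions = 1L, seed = 1L) {
  scale <- match.arg(scale)
  out <- vector("list", nSessions)
  for (i in seq_len(nSessions)) {
    set.seed(seed + i)
    if (scale == "tiny") {
      units <- makeUnits(nM1 = 4L, nPMd = 4L, nPRR = 0L,
                         latentRank = 2L)
      sched <- perturbationSchedule(nBaseline = 8L, nRotation = 8L,
                                    nWashout = 8L,
                                    direction = if (i %% 2L) "CCW" else "CW")
      out[[i]] <- generateSession(schedule = sched, units = units,
                                  learning = learningModel(
                                    learningRate = 0.1),
                                  seed = seed + i, nCalibTrials = 16L)
    } else {
      units <- makeUnits()
      sched <- perturbationSchedule(
        direction = if (i %% 2L) "CCW" else "CW")
      out[[i]] <- generateSession(schedule = sched, units = units,
                                  seed = seed + i)
    }
    if (!is.null(dir))
      writeSession(out[[i]], file.path(dir, sprintf("%s_%02d", scale, i)))
  }
  out
}
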