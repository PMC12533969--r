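## Session serialization: one directory per session, counts and kinematics
## as long-format CSV (lossless for integer counts), tables as CSV, config
## as JSON with a mandatory schema version.

.SESSION_SCHEMA <- 1L

#' Write / read a session directory
#'
#' A session serializes to a directory containing \code{config.json}
#' (schema version, task, schedule, learning model, seed),
#' \code{trials.csv}, \code{units.csv}, \code{loadings.csv},
#' \code{counts.csv} (long format: trial, bin, unit, count),
#' \code{cursor.csv} / \code{hand.csv} (long format: trial, bin, x, y, z)
#' and \code{decoder.json}. The round trip is lossless.
#'
#' @param session a \linkS4class{BCISession}.
#' @param dir target directory (created if needed).
#' @return \code{writeSession} returns the directory invisibly;
#'   \code{readSession} returns the \linkS4class{BCISession}.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(schema_version = .SESSION_SCHEMA, task = session@task,
              schedule = session@schedule, learning = session@learning,
              seed = session@seed,
              dims = dim(session@counts))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(session@trials, file.path(dir, "trials.csv"),
            row.names = FALSE)
  write.csv(session@units, file.path(dir, "units.csv"), row.names = FALSE)
  write.csv(as.data.frame(session@loadings),
            file.path(dir, "loadings.csv"), row.names = FALSE)
  dc <- dim(session@counts)
  idx <- which(!is.na(session@counts), arr.ind = TRUE)
  cts <- data.frame(trial = idx[, 1L], bin = idx[, 2L], unit = idx[, 3L],
                    count = session@counts[idx])
  cts <- cts[order(cts$trial, cts$bin, cts$unit), ]
  write.csv(cts, file.path(dir, "counts.csv"), row.names = FALSE)
  wideKin <- function(arr, name) {
    idx <- which(!is.na(arr[, , 1L]), arr.ind = TRUE)
    d <- data.frame(trial = idx[, 1L], bin = idx[, 2L],
                    x = arr[cbind(idx, 1L)], y = arr[cbind(idx, 2L)],
                    z = arr[cbind(idx, 3L)])
    d <- d[order(d$trial, d$bin), ]
    write.csv(d, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wideKin(session@cursor, "cursor")
  wideKin(session@hand, "hand")
  writeDecoder(session@decoder, file.path(dir, "decoder.json"))
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  if (is.null(cfg$schema_version) ||
      cfg$schema_version != .SESSION_SCHEMA)
    stop("unsupported session schema version")
  trials <- read.csv(file.path(dir, "trials.csv"),
                     stringsAsFactors = FALSE)
  units <- read.csv(file.path(dir, "units.csv"), stringsAsFactors = FALSE)
  loadings <- as.matrix(read.csv(file.path(dir, "loadings.csv")))
  dimnames(loadings) <- NULL
  dims <- as.integer(cfg$dims)
  counts <- array(NA_real_, dims)
  cts <- read.csv(file.path(dir, "counts.csv"))
  counts[cbind(cts$trial, cts$bin, cts$unit)] <- cts$count
  readKin <- function(name) {
    d <- read.csv(file.path(dir, paste0(name, ".csv")))
    arr <- array(NA_real_, c(dims[1:2], 3L))
    for (j in 1:3)
      arr[cbind(d$trial, d$bin, j)] <- d[[c("x", "y", "z")[j]]]
    arr
  }
  new("BCISession", counts = counts, trials = trials,
      cursor = readKin("cursor"), hand = readKin("hand"), units = units,
      loadings = loadings, task = as.list(cfg$task),
      schedule = as.list(cfg$schedule), learning = as.list(cfg$learning),
      decoder = readDecoder(file.path(dir, "decoder.json")),
      seed = as.integer(cfg$seed))
}
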