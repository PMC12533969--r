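#' @name bcivmr-accessors
#' @title Accessors for bcivmr containers
#'
#' @description Slot accessors for \linkS4class{BCISession},
#' \linkS4class{KalmanDecoder}, \linkS4class{AlignedTrajectory} and
#' \linkS4class{ReconResult}.
#'
#' @param object a bcivmr S4 object.
#' @return The corresponding component (array, data.frame, matrix or
#'   vector); see each generic's name.
NULL

#' @rdname bcivmr-accessors
#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("unitInfo", function(object) standardGeneric("unitInfo"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("cursorArray", function(object) standardGeneric("cursorArray"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("handArray", function(object) standardGeneric("handArray"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("truthAim", function(object) standardGeneric("truthAim"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("onlineDecoder", function(object) standardGeneric("onlineDecoder"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("observationMatrix",
           function(object) standardGeneric("observationMatrix"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("alongTarget", function(object) standardGeneric("alongTarget"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("alongPerturbation",
           function(object) standardGeneric("alongPerturbation"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("rotationSign", function(object) standardGeneric("rotationSign"))

#' @rdname bcivmr-accessors
#' @export
setGeneric("deflectionEnd", function(object) standardGeneric("deflectionEnd"))

#' @rdname bcivmr-accessors
setMethod("spikeCounts", "BCISession", function(object) object@counts)

#' @rdname bcivmr-accessors
setMethod("trialTable", "BCISession", function(object) object@trials)

#' @rdname bcivmr-accessors
setMethod("unitInfo", "BCISession", function(object) object@units)

#' @rdname bcivmr-accessors
setMethod("cursorArray", "BCISession", function(object) object@cursor)

#' @rdname bcivmr-accessors
setMethod("handArray", "BCISession", function(object) object@hand)

#' @rdname bcivmr-accessors
setMethod("truthAim", "BCISession", function(object) object@trials$truthAimDeg)

#' @rdname bcivmr-accessors
setMethod("onlineDecoder", "BCISession", function(object) object@decoder)

#' @rdname bcivmr-accessors
setMethod("nTrials", "BCISession", function(object) dim(object@counts)[1L])

#' @rdname bcivmr-accessors
setMethod("nUnits", "BCISession", function(object) dim(object@counts)[3L])

#' @rdname bcivmr-accessors
setMethod("nUnits", "KalmanDecoder", function(object) length(object@unitIds))

#' @rdname bcivmr-accessors
setMethod("observationMatrix", "KalmanDecoder", function(object) object@H)

#' @rdname bcivmr-accessors
setMethod("alongTarget", "AlignedTrajectory",
          function(object) object@alongTarget)

#' @rdname bcivmr-accessors
setMethod("alongPerturbation", "AlignedTrajectory",
          function(object) object@alongPerturbation)

#' @rdname bcivmr-accessors
setMethod("rotationSign", "AlignedTrajectory",
          function(object) object@rotationSign)

#' @rdname bcivmr-accessors
setMethod("deflectionEnd", "ReconResult", function(object) object@deflectionEnd)

setMethod("show", "BCISession", function(object) {
  tab <- table(object@trials$phase)
  cat("BCISession:", nTrials(object), "trials,", nUnits(object), "units\n")
  cat("  phases:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  rotation:", object@schedule$rotationDeg, "deg",
      object@schedule$direction, "\n")
  ar <- table(object@units$area, object@units$controlling)
  cat("  units by area (noncontrolling/controlling):\n")
  for (a in rownames(ar))
    cat(sprintf("    %-4s %d / %d\n", a,
                ar[a, "FALSE"], ar[a, "TRUE"]))
  invisible(NULL)
})

setMethod("show", "KalmanDecoder", function(object) {
  cat("KalmanDecoder:", nUnits(object), "units, bin", object@binMs, "ms\n")
  cat("  mean |tuning|:",
      signif(mean(sqrt(rowSums(object@H[, 1:3, drop = FALSE]^2))), 3),
      "counts/bin per mm/s\n")
  invisible(NULL)
})

setMethod("show", "ReconResult", function(object) {
  cat("ReconResult (", object@kind, "): ", length(object@trajectories),
      " trials, phase ", paste(unique(object@phase), collapse = "/"),
      ", ", length(object@unitIndex), " units\n", sep = "")
  cat("  mean end deflection:", signif(mean(object@deflectionEnd), 4), "\n")
  invisible(NULL)
})
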