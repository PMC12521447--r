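#' Construct an EpochSet
#'
#' Usually produced by \code{\link{epochRecording}}; the constructor is
#' exported for building small fixtures directly.
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param fs sampling rate (Hz).
#' @param times epoch time axis (s), length = dim(data)[3].
#' @param intensityDb per-trial intensity labels (dB SPL).
#' @param keep per-trial keep flags (default all TRUE).
#' @param dropReason per-trial reason strings ("" when kept).
#' @param channelLabels,channelTypes channel metadata.
#' @param subjectId subject identifier.
#' @param log list of bookkeeping entries.
#' @return An \linkS4class{EpochSet}.
#' @export
epochSet <- function(data, fs, times, intensityDb,
                     keep = rep(TRUE, dim(data)[1]),
                     dropReason = rep("", dim(data)[1]),
                     channelLabels, channelTypes,
                     subjectId = "subject", log = list()) {
  new("EpochSet", data = data, fs = fs, times = times,
      intensityDb = as.numeric(intensityDb), keep = keep,
      dropReason = dropReason,
      channelLabels = as.character(channelLabels),
      channelTypes = as.character(channelTypes),
      subjectId = subjectId, log = log)
}

#' @rdname recData
#' @export
setMethod("recData", "EpochSet", function(x) x@data)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @rdname channelTypes
#' @export
setMethod("channelTypes", "EpochSet", function(x) x@channelTypes)

#' @rdname nChannels
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])

#' @rdname nSamples
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3])

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)

#' @rdname intensityLabels
#' @export
setMethod("intensityLabels", "EpochSet", function(x) x@intensityDb)

#' @rdname keptEpochs
#' @export
setMethod("keptEpochs", "EpochSet", function(x) x@keep)

#' @rdname subjectId
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' Number of trials in an EpochSet
#' @param es An \linkS4class{EpochSet}.
#' @param keptOnly If TRUE count only kept trials.
#' @return Integer.
#' @export
nTrials <- function(es, keptOnly = FALSE) {
  if (keptOnly) sum(es@keep) else dim(es@data)[1]
}

setMethod("show", "EpochSet", function(object) {
  tab <- table(factor(object@intensityDb), object@keep)
  cat("EpochSet [", object@subjectId, "]: ", nTrials(object), " trials x ",
      nChannels(object), " channels x ", nSamples(object), " samples @ ",
      object@fs, " Hz\n", sep = "")
  cat("  window: [", sprintf("%.3f", min(object@times)), ", ",
      sprintf("%.3f", max(object@times)), "] s; kept ",
      sum(object@keep), "/", nTrials(object), "\n", sep = "")
  kept <- vapply(split(object@keep, factor(object@intensityDb)), sum, 0L)
  cat("  kept per intensity:",
      paste(names(kept), "dB:", kept, collapse = "  "), "\n")
  invisible(tab)
})
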