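#' Construct a RawRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelLabels character vector of channel names.
#' @param channelTypes character vector, "EEG" or "EOG" per channel.
#' @param events data.frame with columns \code{onset_s}, \code{intensity_db}.
#' @param reference "raw" (default) or "average".
#' @return A \linkS4class{RawRecording}.
#' @examples
#' rec <- rawRecording(matrix(rnorm(2 * 100), 2), fs = 100,
#'                     channelLabels = c("Cz", "Pz"),
#'                     channelTypes = c("EEG", "EEG"))
#' nSamples(rec)
#' @export
rawRecording <- function(data, fs, channelLabels, channelTypes,
                         events = data.frame(onset_s = numeric(0),
                                             intensity_db = numeric(0)),
                         reference = "raw") {
  rownames(data) <- channelLabels
  new("RawRecording", data = data, fs = fs,
      channelLabels = as.character(channelLabels),
      channelTypes = as.character(channelTypes),
      events = events, reference = reference)
}

#' @rdname recData
#' @export
setMethod("recData", "RawRecording", function(x) x@data)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RawRecording", function(x) x@fs)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "RawRecording", function(x) x@channelLabels)

#' @rdname channelTypes
#' @export
setMethod("channelTypes", "RawRecording", function(x) x@channelTypes)

#' @rdname recEvents
#' @export
setMethod("recEvents", "RawRecording", function(x) x@events)

#' @rdname nChannels
#' @export
setMethod("nChannels", "RawRecording", function(x) nrow(x@data))

#' @rdname nSamples
#' @export
setMethod("nSamples", "RawRecording", function(x) ncol(x@data))

#' Recording duration in seconds
#' @param rec A \linkS4class{RawRecording}.
#' @return Numeric scalar, seconds.
#' @export
recordingDuration <- function(rec) nSamples(rec) / samplingRate(rec)

#' Indices of EEG (non-EOG) channels
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Integer indices of channels typed "EEG".
#' @export
eegChannels <- function(x) which(channelTypes(x) == "EEG")

#' Indices of EOG channels
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Integer indices of channels typed "EOG".
#' @export
eogChannels <- function(x) which(channelTypes(x) == "EOG")

setMethod("show", "RawRecording", function(object) {
  cat("RawRecording:", nChannels(object), "channels x",
      nSamples(object), "samples @", object@fs, "Hz (",
      sprintf("%.1f", recordingDuration(object)), "s )\n")
  cat("  EEG:", sum(object@channelTypes == "EEG"),
      " EOG:", sum(object@channelTypes == "EOG"),
      " reference:", object@reference, "\n")
  cat("  events:", nrow(object@events))
  if (nrow(object@events))
    cat(" (intensities:",
        paste(sort(unique(object@events$intensity_db)), collapse = ", "),
        "dB )")
  cat("\n")
})

# internal: replace data keeping metadata consistent
replaceData <- function(rec, data, reference = rec@reference,
                        fs = rec@fs, keepChannels = NULL) {
  labels <- rec@channelLabels
  types <- rec@channelTypes
  if (!is.null(keepChannels)) {
    labels <- labels[keepChannels]
    types <- types[keepChannels]
  }
  rawRecording(data, fs = fs, channelLabels = labels, channelTypes = types,
               events = rec@events, reference = reference)
}

#' Subset a recording to named channels
#' @param rec A \linkS4class{RawRecording}.
#' @param channels Character labels or integer indices to keep.
#' @return A \linkS4class{RawRecording} with only those channels.
#' @export
selectChannels <- function(rec, channels) {
  idx <- if (is.character(channels)) match(channels, rec@channelLabels)
         else as.integer(channels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  replaceData(rec, rec@data[idx, , drop = FALSE], keepChannels = idx)
}
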