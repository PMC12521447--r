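#' Raw multichannel EEG recording
#'
#' Container for a continuous EEG recording: a channels x samples signal
#' matrix in microvolts, its sampling rate, channel metadata, and the
#' stimulus event list. The \code{reference} slot tracks whether the data
#' are still in acquisition reference ("raw") or have been re-referenced to
#' the common average ("average").
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs numeric scalar, sampling rate in Hz.
#' @slot channelLabels character, one label per row of \code{data}.
#' @slot channelTypes character, "EEG" or "EOG" per channel.
#' @slot events data.frame with columns \code{onset_s} (seconds, increasing)
#'   and \code{intensity_db} (dB SPL).
#' @slot reference character, "raw" or "average".
#'
#' @seealso \code{\link{rawRecording}}, \code{\link{simulateRecording}}
#' @export
setClass("RawRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    channelTypes = "character",
    events = "data.frame",
    reference = "character"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "channelLabels length must equal nrow(data)")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channelLabels must be unique")
  if (length(object@channelTypes) != nrow(object@data))
    msg <- c(msg, "channelTypes length must equal nrow(data)")
  if (!all(object@channelTypes %in% c("EEG", "EOG")))
    msg <- c(msg, "channelTypes must be 'EEG' or 'EOG'")
  if (!all(c("onset_s", "intensity_db") %in% names(object@events)))
    msg <- c(msg, "events must have columns onset_s and intensity_db")
  if (nrow(object@events) > 1 && is.unsorted(object@events$onset_s))
    msg <- c(msg, "event onsets must be non-decreasing")
  if (!(object@reference %in% c("raw", "average")))
    msg <- c(msg, "reference must be 'raw' or 'average'")
  if (length(msg)) msg else TRUE
})

#' Stimulus-locked epochs
#'
#' Trials x channels x samples array of epoched EEG aligned to stimulus
#' onset, with per-trial intensity labels and keep flags. Trials that were
#' screened out (near a recording edge, inside a bad segment, or rejected by
#' the statistical epoch screen) keep their data for audit; only the
#' \code{keep} flag changes, with the reason recorded in \code{dropReason}.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot fs numeric, sampling rate (Hz).
#' @slot times numeric, epoch time axis in seconds (0 = stimulus onset).
#' @slot intensityDb numeric, per-trial stimulus intensity (dB SPL).
#' @slot keep logical, per-trial keep flag.
#' @slot dropReason character, per-trial reason ("" when kept).
#' @slot channelLabels,channelTypes character, channel metadata.
#' @slot subjectId character scalar.
#' @slot log list, bookkeeping from the preprocessing chain.
#'
#' @seealso \code{\link{epochRecording}}, \code{\link{rejectEpochs}}
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    times = "numeric",
    intensityDb = "numeric",
    keep = "logical",
    dropReason = "character",
    channelLabels = "character",
    channelTypes = "character",
    subjectId = "character",
    log = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
  else {
    if (length(object@times) != d[3])
      msg <- c(msg, "times length must equal dim(data)[3]")
    if (length(object@intensityDb) != d[1])
      msg <- c(msg, "intensityDb length must equal number of trials")
    if (length(object@keep) != d[1])
      msg <- c(msg, "keep length must equal number of trials")
    if (length(object@dropReason) != d[1])
      msg <- c(msg, "dropReason length must equal number of trials")
    if (length(object@channelLabels) != d[2])
      msg <- c(msg, "channelLabels length must equal number of channels")
    if (length(object@channelTypes) != d[2])
      msg <- c(msg, "channelTypes length must equal number of channels")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (any(object@keep) &&
      !all(is.finite(object@data[object@keep, , , drop = FALSE])))
    msg <- c(msg, "kept trials must contain finite data")
  if (length(msg)) msg else TRUE
})

#' Per-subject LDAEP result
#'
#' N1, P2 and N1P2 peak amplitudes per stimulus intensity at the analysis
#' electrode, together with the fitted intensity slopes (the LDAEP), their
#' intercepts and the R-squared of each line. The N1P2 amplitude at each
#' intensity is the peak-to-peak difference P2 - N1, so by construction the
#' fitted N1P2 slope equals the P2 slope minus the N1 slope.
#'
#' @slot subjectId character scalar.
#' @slot channel character, electrode used (default "Cz").
#' @slot intensities numeric, stimulus intensities (dB SPL).
#' @slot amplitudes numeric matrix, rows \code{n1}, \code{p2}, \code{n1p2};
#'   columns = intensities; microvolts.
#' @slot latencies numeric matrix, rows \code{n1}, \code{p2}; peak latencies
#'   in seconds.
#' @slot slopes,intercepts named numeric, per component (microvolts/dB and
#'   microvolts).
#' @slot r2 named numeric, R-squared of each fitted line.
#' @slot nEpochs numeric, epochs averaged per intensity.
#' @slot flagged logical, TRUE when the subject could not be fully measured.
#' @slot note character, reason when flagged.
#'
#' @seealso \code{\link{ldaepFromEpochs}}, \code{\link{computeLdaep}}
#' @export
setClass("LdaepResult",
  representation(
    subjectId = "character",
    channel = "character",
    intensities = "numeric",
    amplitudes = "matrix",
    latencies = "matrix",
    slopes = "numeric",
    intercepts = "numeric",
    r2 = "numeric",
    nEpochs = "numeric",
    flagged = "logical",
    note = "character"
  )
)

setValidity("LdaepResult", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@amplitudes), c("n1", "p2", "n1p2")))
    msg <- c(msg, "amplitudes must have rows n1, p2, n1p2")
  if (ncol(object@amplitudes) != length(object@intensities))
    msg <- c(msg, "amplitudes must have one column per intensity")
  if (!object@flagged &&
      !all(c("n1", "p2", "n1p2") %in% names(object@slopes)))
    msg <- c(msg, "slopes must be named n1, p2, n1p2")
  if (length(msg)) msg else TRUE
})
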