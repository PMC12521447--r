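#' @import methods
NULL

#' Signal matrix of a recording or epoch container
#'
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return For a recording, a channels x samples numeric matrix (microvolts);
#'   for an epoch set, a trials x channels x samples array.
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))

#' Sampling rate in Hz
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel labels
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Character vector of channel names.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Channel types ("EEG" or "EOG")
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Character vector, one of "EEG"/"EOG" per channel.
#' @export
setGeneric("channelTypes", function(x) standardGeneric("channelTypes"))

#' Stimulus events of a recording
#' @param x A \linkS4class{RawRecording}.
#' @return data.frame with columns \code{onset_s} and \code{intensity_db}.
#' @export
setGeneric("recEvents", function(x) standardGeneric("recEvents"))

#' Number of channels
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Integer.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples (per channel, or per epoch)
#' @param x A \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @return Integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Epoch time axis
#' @param x An \linkS4class{EpochSet}.
#' @return Numeric vector of times in seconds, 0 = stimulus onset.
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Per-trial intensity labels (dB SPL)
#' @param x An \linkS4class{EpochSet}.
#' @return Numeric vector, one intensity per trial.
#' @export
setGeneric("intensityLabels", function(x) standardGeneric("intensityLabels"))

#' Epoch keep flags
#' @param x An \linkS4class{EpochSet}.
#' @return Logical vector, TRUE for epochs that survived screening.
#' @export
setGeneric("keptEpochs", function(x) standardGeneric("keptEpochs"))

#' Subject identifier
#' @param x An \linkS4class{EpochSet} or \linkS4class{LdaepResult}.
#' @return Character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Fitted LDAEP slopes
#' @param x An \linkS4class{LdaepResult}.
#' @return Named numeric vector (\code{n1}, \code{p2}, \code{n1p2}), in
#'   microvolts per dB.
#' @export
setGeneric("slopes", function(x) standardGeneric("slopes"))

#' Per-intensity peak amplitudes
#' @param x An \linkS4class{LdaepResult}.
#' @return Matrix with rows \code{n1}, \code{p2}, \code{n1p2} and one column
#'   per stimulus intensity (microvolts).
#' @export
setGeneric("peakAmplitudes", function(x) standardGeneric("peakAmplitudes"))
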