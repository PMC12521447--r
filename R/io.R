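# Plain-text persistence: signal matrices as TSV with a JSON sidecar, plus
# BIDS-style *_events.tsv / *_channels.tsv. Deliberately simple, portable
# formats; every writer has a matching reader and validateDataset() checks
# their mutual consistency.

#' Write a recording to a BIDS-style directory
#'
#' Creates \code{<sub>_eeg.tsv} (samples x channels, header = labels),
#' \code{<sub>_eeg.json} (sampling rate, channel types, reference state,
#' sample count), \code{<sub>_events.tsv} (onset, duration, trial_type =
#' intensity in dB) and \code{<sub>_channels.tsv} (name, type).
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param dir output directory (created if needed).
#' @param sub subject label (e.g. "sub-01").
#' @param toneDurationS stimulus duration written to the events file.
#' @return Invisibly, the four file paths.
#' @export
writeRecording <- function(rec, dir, sub, toneDurationS = 0.03) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sub)
  sig <- t(recData(rec))
  colnames(sig) <- channelLabels(rec)
  utils::write.table(sig, paste0(base, "_eeg.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(SamplingFrequency = samplingRate(rec),
               ChannelTypes = as.list(stats::setNames(
                 channelTypes(rec), channelLabels(rec))),
               Reference = rec@reference,
               SampleCount = nSamples(rec))
  jsonlite::write_json(side, paste0(base, "_eeg.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  ev <- recEvents(rec)
  utils::write.table(
    data.frame(onset = ev$onset_s, duration = toneDurationS,
               trial_type = ev$intensity_db),
    paste0(base, "_events.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(name = channelLabels(rec), type = channelTypes(rec)),
    paste0(base, "_channels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(paste0(base, c("_eeg.tsv", "_eeg.json", "_events.tsv",
                           "_channels.tsv")))
}

#' Read a recording written by \code{\link{writeRecording}}
#'
#' @param dir dataset directory.
#' @param sub subject label.
#' @return A \linkS4class{RawRecording}.
#' @export
readRecording <- function(dir, sub) {
  base <- file.path(dir, sub)
  sig <- utils::read.delim(paste0(base, "_eeg.tsv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(base, "_eeg.json"))
  ev <- utils::read.delim(paste0(base, "_events.tsv"))
  ch <- utils::read.delim(paste0(base, "_channels.tsv"))
  rawRecording(t(as.matrix(sig)), fs = side$SamplingFrequency,
               channelLabels = ch$name, channelTypes = ch$type,
               events = data.frame(onset_s = ev$onset,
                                   intensity_db = ev$trial_type),
               reference = side$Reference)
}

#' Validate a simulated dataset directory
#'
#' Machine-readable consistency findings for every subject found in the
#' directory: unreadable or truncated files, channel lists that disagree
#' between the signal header and the channels sidecar, events outside the
#' recording, and intensity labels outside the expected stimulus set.
#' A freshly written dataset yields zero findings.
#'
#' @param dir dataset directory.
#' @param intensities allowed stimulus intensities (dB).
#' @return data.frame with columns \code{subject}, \code{file},
#'   \code{check}, \code{message}; zero rows when the dataset is clean.
#' @export
validateDataset <- function(dir, intensities = c(55, 65, 75, 85, 95)) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  findings <- list()
  addF <- function(subject, file, check, message)
    findings[[length(findings) + 1]] <<-
      data.frame(subject = subject, file = file, check = check,
                 message = message, stringsAsFactors = FALSE)
  subs <- unique(sub("_eeg\\.json$", "",
                     basename(list.files(dir, "_eeg\\.json$"))))
  if (!length(subs))
    addF("", dir, "dataset", "no subjects found")
  for (s in subs) {
    base <- file.path(dir, s)
    side <- tryCatch(jsonlite::read_json(paste0(base, "_eeg.json")),
                     error = function(e) NULL)
    if (is.null(side)) {
      addF(s, paste0(s, "_eeg.json"), "unreadable", "cannot parse sidecar")
      next
    }
    sig <- tryCatch(utils::read.delim(paste0(base, "_eeg.tsv"),
                                      check.names = FALSE),
                    error = function(e) NULL)
    if (is.null(sig)) {
      addF(s, paste0(s, "_eeg.tsv"), "unreadable", "cannot read signal")
      next
    }
    if (!is.null(side$SampleCount) && nrow(sig) < side$SampleCount)
      addF(s, paste0(s, "_eeg.tsv"), "truncated",
           sprintf("expected %d samples, found %d", side$SampleCount,
                   nrow(sig)))
    ch <- tryCatch(utils::read.delim(paste0(base, "_channels.tsv")),
                   error = function(e) NULL)
    if (is.null(ch)) {
      addF(s, paste0(s, "_channels.tsv"), "unreadable",
           "cannot read channel table")
    } else if (!identical(sort(colnames(sig)), sort(as.character(ch$name)))) {
      addF(s, paste0(s, "_channels.tsv"), "channel_mismatch",
           "channel lists differ between signal and sidecar")
    }
    ev <- tryCatch(utils::read.delim(paste0(base, "_events.tsv")),
                   error = function(e) NULL)
    if (is.null(ev)) {
      addF(s, paste0(s, "_events.tsv"), "unreadable",
           "cannot read event table")
    } else {
      bad <- setdiff(unique(ev$trial_type), intensities)
      if (length(bad))
        addF(s, paste0(s, "_events.tsv"), "unknown_intensity",
             paste("labels outside stimulus set:",
                   paste(bad, collapse = ", ")))
      fs <- side$SamplingFrequency
      if (!is.null(fs) && nrow(sig) > 0 &&
          any(ev$onset + 0.5 > nrow(sig) / fs))
        addF(s, paste0(s, "_events.tsv"), "event_out_of_range",
             "event epoch extends past the recording end")
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(subject = character(0), file = character(0),
                  check = character(0), message = character(0),
                  stringsAsFactors = FALSE)
}

#' Write a cohort covariate table (without ground truth)
#'
#' The covariate CSV consumed by the statistics stage; the generative
#' ground-truth parameters are written to a separate file that the
#' pipeline never reads, preventing accidental leakage.
#'
#' @param cohort cohort table from \code{\link{generateCohort}}.
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
writeCohortCsv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truthCols <- grep("^true_", names(cohort), value = TRUE)
  pCov <- file.path(dir, "cohort.csv")
  pTruth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort[, setdiff(names(cohort), truthCols)], pCov,
                   row.names = FALSE)
  utils::write.csv(cohort[, c("subject_id", truthCols)], pTruth,
                   row.names = FALSE)
  invisible(c(pCov, pTruth))
}

# content hash of an R object (version-pinned serialization -> md5)
hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
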