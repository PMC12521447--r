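#' Preprocessing configuration
#'
#' Defaults implement the four-stage cleaning chain: average re-reference,
#' resampling to 512 Hz, automated bad-channel detection on a 1 Hz
#' high-passed + line-suppressed detection copy, re-referencing to the
#' remaining channels, 1-100 Hz band-pass + 50 Hz spectral interpolation,
#' bad-segment screening (5-s blocks, >25\% of channels with SD > 25
#' microvolts), EOG-regression ocular cleaning, a 30 Hz low-pass, 600 ms
#' epoching (-100 to +500 ms) with pre-stimulus baseline correction, and
#' statistical epoch rejection at |z| > 3.
#'
#' @param resampleFs analysis sampling rate (Hz).
#' @param lineFreq mains frequency (Hz).
#' @param hpDetect high-pass cutoff for the detection copy (Hz).
#' @param bandpass c(low, high) band-pass for artifact screening (Hz).
#' @param finalLowpass low-pass before epoching (Hz).
#' @param segmentBlockS bad-segment block length (s).
#' @param segmentChannelFraction fraction of channels that must exceed the
#'   SD limit for a block to be dropped (strict inequality).
#' @param segmentSdUv per-channel SD limit within a block (microvolts,
#'   strict inequality).
#' @param epochWindowS c(start, end) epoch window relative to onset (s).
#' @param epochRejectZ |z| threshold of the epoch screen.
#' @param badVarianceZ robust-z threshold on log channel variance.
#' @param badCorrelationFloor minimum max-|correlation| with other channels.
#' @param badSpectralZ robust-z threshold on relative >40 Hz power.
#' @param baselineCorrect subtract the pre-stimulus mean per epoch/channel.
#' @return Object of class \code{preprocConfig}.
#' @export
preprocConfig <- function(resampleFs = 512, lineFreq = 50, hpDetect = 1,
                          bandpass = c(1, 100), finalLowpass = 30,
                          segmentBlockS = 5, segmentChannelFraction = 0.25,
                          segmentSdUv = 25, epochWindowS = c(-0.1, 0.5),
                          epochRejectZ = 3, badVarianceZ = 5,
                          badCorrelationFloor = 0.4, badSpectralZ = 5,
                          baselineCorrect = TRUE) {
  freqs <- c(lineFreq, hpDetect, bandpass, finalLowpass)
  if (any(freqs >= resampleFs / 2))
    stop("all filter frequencies must be below resampleFs/2")
  structure(as.list(environment()), class = "preprocConfig")
}

#' Re-reference EEG channels to their common average
#'
#' Subtracts, at every sample, the mean over the referenced EEG channels
#' from those channels. EOG channels and channels excluded from
#' \code{channelSubset} are left untouched, so a recording re-referenced to
#' its good channels keeps its (excluded) bad channels as recorded.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param channelSubset labels (or indices) of EEG channels forming the
#'   reference; default all EEG channels.
#' @return A \linkS4class{RawRecording} with reference state "average".
#' @export
rereferenceAverage <- function(rec, channelSubset = NULL) {
  idx <- if (is.null(channelSubset)) eegChannels(rec)
         else if (is.character(channelSubset))
           match(channelSubset, channelLabels(rec))
         else as.integer(channelSubset)
  if (anyNA(idx) || length(idx) == 0) stop("empty or unknown channel subset")
  idx <- idx[channelTypes(rec)[idx] == "EEG"]
  if (length(idx) < 2) stop("need at least 2 EEG channels to re-reference")
  data <- recData(rec)
  data[idx, ] <- sweep(data[idx, , drop = FALSE], 2,
                       colMeans(data[idx, , drop = FALSE]))
  replaceData(rec, data, reference = "average")
}

#' Resample a recording (downsampling only)
#'
#' Fourier-method resampling with implicit brick-wall anti-aliasing; the
#' new length is \code{round(n * targetFs / fs)} and event onsets are
#' carried in seconds, hence preserved exactly.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param targetFs target sampling rate (Hz), must not exceed the current.
#' @return A \linkS4class{RawRecording} at \code{targetFs}.
#' @export
resampleRecording <- function(rec, targetFs) {
  fs <- samplingRate(rec)
  if (targetFs > fs) stop("upsampling is not supported")
  if (targetFs == fs) return(rec)
  data <- recData(rec)
  out <- t(apply(data, 1, fftResampleVec, fs = fs, targetFs = targetFs))
  replaceData(rec, out, fs = targetFs)
}

#' Suppress mains noise by spectral interpolation
#'
#' Per channel, the amplitude spectrum within \code{lineFreq +/-
#' halfBandwidthHz} is replaced by log-magnitude linear interpolation
#' between the flanking bands of the same width on either side; phases are
#' preserved, so the out-of-band signal is untouched.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param lineFreq mains frequency (Hz).
#' @param halfBandwidthHz half-width of the replaced band (Hz).
#' @return A \linkS4class{RawRecording}.
#' @export
suppressLineNoise <- function(rec, lineFreq = 50, halfBandwidthHz = 1) {
  fs <- samplingRate(rec)
  if (lineFreq + 2 * halfBandwidthHz >= fs / 2)
    stop("interpolation band exceeds the Nyquist frequency")
  data <- recData(rec)
  n <- ncol(data)
  f <- (seq_len(n) - 1) * fs / n
  fpos <- pmin(f, fs - f)  # frequency of each bin, folded
  inBand <- which(abs(fpos - lineFreq) <= halfBandwidthHz &
                    seq_len(n) <= floor(n / 2) + 1)
  leftFlank <- which(fpos >= lineFreq - 2 * halfBandwidthHz &
                       fpos < lineFreq - halfBandwidthHz &
                       seq_len(n) <= floor(n / 2) + 1)
  rightFlank <- which(fpos > lineFreq + halfBandwidthHz &
                        fpos <= lineFreq + 2 * halfBandwidthHz &
                        seq_len(n) <= floor(n / 2) + 1)
  if (!length(inBand)) return(rec)
  for (ch in seq_len(nrow(data))) {
    xf <- stats::fft(data[ch, ])
    lm <- mean(log(Mod(xf[leftFlank]) + 1e-30))
    rm_ <- mean(log(Mod(xf[rightFlank]) + 1e-30))
    fl <- mean(fpos[leftFlank]); fr <- mean(fpos[rightFlank])
    newMag <- exp(lm + (rm_ - lm) * (fpos[inBand] - fl) / (fr - fl))
    scale <- newMag / (Mod(xf[inBand]) + 1e-30)
    xf[inBand] <- xf[inBand] * scale
    xf[n - inBand + 2] <- Conj(xf[inBand])  # conjugate-symmetric mirror
    data[ch, ] <- Re(stats::fft(xf, inverse = TRUE)) / n
  }
  replaceData(rec, data)
}

robustZ <- function(x) {
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv == 0) return(rep(0, length(x)))
  (x - med) / madv
}

#' Automated bad-channel detection
#'
#' Flags an EEG channel as bad when (a) the absolute robust z-score of its
#' log-variance exceeds \code{badVarianceZ} (catching both dead and wildly
#' noisy channels), (b) its maximum absolute
#' correlation with every other EEG channel falls below
#' \code{badCorrelationFloor}, or (c) the robust z-score of its relative
#' high-frequency (>40 Hz) power exceeds \code{badSpectralZ}. The caller is
#' expected to pass a detection copy that has been high-pass filtered at
#' \code{hpDetect} and line-suppressed. With fewer than 4 EEG channels the
#' correlation criterion is skipped with a warning.
#'
#' @param rec A \linkS4class{RawRecording} (detection copy).
#' @param config A \code{\link{preprocConfig}}.
#' @return data.frame with one row per EEG channel: \code{channel},
#'   \code{flag} ("good", "bad_variance", "bad_correlation",
#'   "bad_spectrum"), and the metrics used.
#' @export
detectBadChannels <- function(rec, config = preprocConfig()) {
  eeg <- eegChannels(rec)
  data <- recData(rec)[eeg, , drop = FALSE]
  labs <- channelLabels(rec)[eeg]
  v <- apply(data, 1, stats::var)
  logv <- log(v + 1e-30)
  zVar <- robustZ(logv)

  maxCor <- rep(NA_real_, length(eeg))
  if (length(eeg) >= 4) {
    cc <- abs(suppressWarnings(stats::cor(t(data))))
    diag(cc) <- 0
    cc[!is.finite(cc)] <- 0  # zero-variance channels correlate with nothing
    maxCor <- apply(cc, 1, max)
  } else {
    warning("fewer than 4 EEG channels; correlation criterion skipped")
  }

  fs <- samplingRate(rec)
  hfRel <- apply(data, 1, function(x) {
    n <- length(x)
    p <- Mod(stats::fft(x))^2
    f <- (seq_len(n) - 1) * fs / n
    half <- f <= fs / 2
    tot <- sum(p[half])
    if (tot == 0) return(0)
    sum(p[half & f > 40]) / tot
  })
  zSpec <- robustZ(hfRel)

  flag <- rep("good", length(eeg))
  # the z criterion alone misfires when every channel is essentially free
  # of high-frequency power; require a non-trivial absolute fraction too
  flag[zSpec > config$badSpectralZ & hfRel > 0.1] <- "bad_spectrum"
  if (length(eeg) >= 4)
    flag[maxCor < config$badCorrelationFloor] <- "bad_correlation"
  flag[abs(zVar) > config$badVarianceZ] <- "bad_variance"  # dead or wild
  data.frame(channel = labs, flag = flag, varianceZ = zVar,
             maxAbsCorrelation = maxCor, hfPowerZ = zSpec,
             stringsAsFactors = FALSE)
}

#' Bad-segment detection (5-s block rule)
#'
#' Tiles the recording into consecutive blocks of \code{segmentBlockS}
#' seconds (the trailing partial block, if >= 1 sample, is evaluated the
#' same way), computes the per-channel sample SD within each block, and
#' drops a block iff the fraction of EEG channels whose SD exceeds
#' \code{segmentSdUv} (strictly) is strictly greater than
#' \code{segmentChannelFraction}. The caller passes data already band-pass
#' filtered and line-suppressed.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param config A \code{\link{preprocConfig}}.
#' @return A list of class \code{segmentMask}: \code{keep} (logical per
#'   block), \code{startSample}/\code{endSample} (1-based, inclusive),
#'   \code{exceedFraction} per block.
#' @export
detectBadSegments <- function(rec, config = preprocConfig()) {
  fs <- samplingRate(rec)
  n <- nSamples(rec)
  blockLen <- round(config$segmentBlockS * fs)
  starts <- seq(1, n, by = blockLen)
  ends <- pmin(starts + blockLen - 1, n)
  eeg <- eegChannels(rec)
  data <- recData(rec)
  frac <- vapply(seq_along(starts), function(b) {
    sds <- apply(data[eeg, starts[b]:ends[b], drop = FALSE], 1, stats::sd)
    mean(sds > config$segmentSdUv)
  }, numeric(1))
  structure(list(keep = !(frac > config$segmentChannelFraction),
                 startSample = starts, endSample = ends,
                 exceedFraction = frac),
            class = "segmentMask")
}

#' Remove ocular artifacts by EOG regression
#'
#' Replaces every EEG channel by the residual of its least-squares
#' regression (with intercept) on all EOG channels, computed over the whole
#' recording. EOG channels are preserved. Signal uncorrelated with the EOG
#' - in particular the stimulus-locked ERP - is preserved in expectation.
#' With no EOG channels, or EOG channels carrying no signal, the recording
#' is returned unchanged with a warning/no-op respectively.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @return A \linkS4class{RawRecording}.
#' @export
removeOcularArtifacts <- function(rec) {
  eog <- eogChannels(rec)
  if (length(eog) == 0) {
    warning("no EOG channels; ocular correction skipped")
    return(rec)
  }
  data <- recData(rec)
  X <- t(data[eog, , drop = FALSE])
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  if (!any(keep)) return(rec)  # silent EOG: nothing to regress out
  X <- cbind(1, X[, keep, drop = FALSE])
  eeg <- eegChannels(rec)
  Y <- t(data[eeg, , drop = FALSE])
  # rank-tolerant least squares: perfectly collinear EOG channels are fine
  fit <- stats::lm.fit(X, Y)
  data[eeg, ] <- t(fit$residuals)
  replaceData(rec, data)
}

#' Cut a recording into stimulus-locked epochs
#'
#' One epoch per event, with samples indexed \code{round(window[1]*fs)} to
#' \code{round(window[2]*fs) - 1} relative to the onset sample (half-open
#' window), i.e. 307 samples at 512 Hz for the default -100..500 ms window,
#' onset at (1-based) index 52. Each epoch/channel is baseline-corrected by
#' subtracting its pre-stimulus mean (configurable). Events too close to a
#' recording edge are dropped and logged; events inside dropped segments
#' (if \code{segments} is given) are excluded as "bad_segment".
#'
#' @param rec A \linkS4class{RawRecording} (expected low-pass filtered).
#' @param events event table; defaults to \code{recEvents(rec)}.
#' @param window c(start, end) in seconds relative to onset.
#' @param baselineCorrect subtract the pre-stimulus mean.
#' @param segments optional \code{segmentMask} from
#'   \code{\link{detectBadSegments}}.
#' @param subjectIdLabel subject id stored in the result.
#' @return An \linkS4class{EpochSet}.
#' @export
epochRecording <- function(rec, events = recEvents(rec),
                           window = c(-0.1, 0.5), baselineCorrect = TRUE,
                           segments = NULL, subjectIdLabel = "subject") {
  fs <- samplingRate(rec)
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  nS <- length(rel)
  times <- rel / fs
  onsetSmp <- round(events$onset_s * fs) + 1  # 1-based onset sample
  nEv <- nrow(events)
  nCh <- nChannels(rec)
  data <- array(0, dim = c(nEv, nCh, nS))
  keep <- rep(TRUE, nEv)
  reason <- rep("", nEv)
  raw <- recData(rec)
  for (i in seq_len(nEv)) {
    idx <- onsetSmp[i] + rel
    if (idx[1] < 1 || idx[nS] > ncol(raw)) {
      keep[i] <- FALSE
      reason[i] <- "edge"
      next
    }
    if (!is.null(segments)) {
      bad <- which(!segments$keep)
      hit <- any(idx[1] <= segments$endSample[bad] &
                   idx[nS] >= segments$startSample[bad])
      if (hit) {
        keep[i] <- FALSE
        reason[i] <- "bad_segment"
      }
    }
    ep <- raw[, idx, drop = FALSE]
    if (baselineCorrect) {
      pre <- which(times < 0)
      if (length(pre))
        ep <- ep - rowMeans(ep[, pre, drop = FALSE])
    }
    data[i, , ] <- ep
  }
  nDropped <- sum(!keep)
  epochSet(data, fs = fs, times = times,
           intensityDb = events$intensity_db, keep = keep,
           dropReason = reason, channelLabels = channelLabels(rec),
           channelTypes = channelTypes(rec), subjectId = subjectIdLabel,
           log = list(edgeDropped = sum(reason == "edge"),
                      segmentDropped = sum(reason == "bad_segment")))
}

#' Statistical epoch rejection
#'
#' For every (currently kept) epoch, three per-epoch metrics are computed,
#' each averaged over EEG channels: amplitude range, variance, and
#' deviation of the epoch's channel mean from the average channel mean
#' across epochs. An epoch is rejected iff the absolute z-score of any
#' metric across epochs exceeds \code{zThreshold} (default 3). Constant
#' metrics (zero spread) yield z = 0 and no rejection. With fewer than 3
#' kept epochs no rejection is attempted.
#'
#' @param es An \linkS4class{EpochSet} (baseline-corrected).
#' @param zThreshold rejection threshold on |z|.
#' @return The \linkS4class{EpochSet} with updated keep flags; rejected
#'   epochs keep their data and get dropReason "rejected".
#' @export
rejectEpochs <- function(es, zThreshold = 3) {
  kept <- which(es@keep)
  if (length(kept) < 3) {
    warning("fewer than 3 epochs; rejection skipped")
    return(es)
  }
  eeg <- which(es@channelTypes == "EEG")
  d <- es@data[kept, eeg, , drop = FALSE]
  rng <- apply(d, 1, function(ep) mean(apply(ep, 1, function(x)
    max(x) - min(x))))
  vr <- apply(d, 1, function(ep) mean(apply(ep, 1, stats::var)))
  chMean <- apply(d, c(1, 2), mean)            # epoch x channel means
  dev <- rowMeans(abs(sweep(chMean, 2, colMeans(chMean))))
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  bad <- abs(zscore(rng)) > zThreshold | abs(zscore(vr)) > zThreshold |
    abs(zscore(dev)) > zThreshold
  es@keep[kept[bad]] <- FALSE
  es@dropReason[kept[bad]] <- "rejected"
  es@log$epochsRejected <- sum(bad)
  validObject(es)
  es
}

#' Run the full preprocessing chain
#'
#' Executes, in order: (1) average re-reference + resampling; (2)
#' bad-channel detection on a high-passed, line-suppressed detection copy;
#' (3) exclusion of bad channels, re-reference to the remaining channels,
#' band-pass + line suppression, bad-segment detection, EOG-regression
#' ocular cleaning; (4) final low-pass, epoching with baseline correction,
#' and statistical epoch rejection. The returned manifest records the
#' executed stage order and all exclusion counts.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param config A \code{\link{preprocConfig}}.
#' @param subjectIdLabel subject id propagated to the epochs.
#' @return A list: \code{epochs} (\linkS4class{EpochSet}),
#'   \code{channelReport}, \code{segmentMask}, \code{manifest} (stage
#'   order + exclusion counts).
#' @examples
#' prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0)
#' ev <- generateParadigm(paradigmSpec(trialsPerIntensity = 2, seed = 1))
#' rec <- simulateRecording(prof, ev, fs = 512, seed = 1)
#' out <- preprocess(rec)
#' out$manifest$counts
#' @export
preprocess <- function(rec, config = preprocConfig(),
                       subjectIdLabel = "subject") {
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  rec <- rereferenceAverage(rec); note("rereference_average")
  rec <- resampleRecording(rec, config$resampleFs); note("resample")

  det <- suppressLineNoise(rec, config$lineFreq)
  det <- replaceData(det, applyFir(recData(det),
    designFir(samplingRate(det), "high", config$hpDetect)))
  note("bad_channel_detection")
  chRep <- detectBadChannels(det, config)
  badCh <- chRep$channel[chRep$flag != "good"]
  if ("Cz" %in% badCh)
    stop("analysis channel Cz was flagged bad; subject not processable")
  goodIdx <- which(!(channelLabels(rec) %in% badCh))
  if (length(badCh)) {
    rec <- selectChannels(rec, goodIdx)
    note("drop_bad_channels")
  }
  rec <- rereferenceAverage(rec); note("rereference_remaining")

  bp <- designFir(samplingRate(rec), "pass", config$bandpass)
  rec <- replaceData(rec, applyFir(recData(rec), bp)); note("bandpass")
  rec <- suppressLineNoise(rec, config$lineFreq); note("line_suppression")
  segs <- detectBadSegments(rec, config); note("bad_segment_detection")
  rec <- removeOcularArtifacts(rec); note("ocular_regression")

  lp <- designFir(samplingRate(rec), "low", config$finalLowpass)
  rec <- replaceData(rec, applyFir(recData(rec), lp)); note("final_lowpass")
  es <- epochRecording(rec, window = config$epochWindowS,
                       baselineCorrect = config$baselineCorrect,
                       segments = segs, subjectIdLabel = subjectIdLabel)
  note("epoching")
  es <- rejectEpochs(es, config$epochRejectZ); note("epoch_rejection")

  counts <- list(
    badChannels = length(badCh),
    badSegments = sum(!segs$keep),
    edgeDroppedEpochs = es@log$edgeDropped,
    segmentDroppedEpochs = es@log$segmentDropped,
    rejectedEpochs = es@log$epochsRejected %||% 0L,
    keptEpochs = sum(es@keep)
  )
  list(epochs = es, channelReport = chRep, segmentMask = segs,
       manifest = list(stageOrder = stages, counts = counts,
                       badChannels = badCh))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
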