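#' EEG montage description for the simulator
#'
#' A montage couples channel labels/types with two fixed spatial profiles:
#' the auditory-ERP topography (where the N1/P2 source projects) and the
#' blink topography. The ERP topography is dipolar and is normalized to
#' (a) weight exactly 1 at Cz and (b) zero mean across EEG channels, so that
#' average re-referencing leaves the Cz response amplitude unchanged - the
#' polarity inversion at inferior-temporal sites mimics the tangential
#' orientation of the auditory cortex source. EOG channels carry no ERP.
#'
#' @param labels channel labels (must contain "Cz").
#' @param types "EEG"/"EOG" per channel.
#' @param erpTopo raw ERP topography (any scale); normalized internally.
#' @param blinkTopo blink topography (1 at EOG, decaying from the front).
#' @return Object of class \code{eegMontage}.
#' @export
eegMontage <- function(labels, types, erpTopo, blinkTopo) {
  if (!"Cz" %in% labels[types == "EEG"])
    stop("montage must contain an EEG channel named 'Cz'")
  eeg <- types == "EEG"
  w <- erpTopo
  w[eeg] <- w[eeg] - mean(w[eeg])
  w[!eeg] <- 0
  w <- w / w[labels == "Cz"]
  structure(list(labels = labels, types = types,
                 erpWeights = w, blinkWeights = blinkTopo),
            class = "eegMontage")
}

#' Reduced 8 EEG + 2 EOG montage (default)
#'
#' A compact montage used by default for speed: central/frontal/parietal
#' sites plus inferior-temporal sites where the auditory ERP inverts
#' polarity, and two periocular EOG channels.
#'
#' @return An \code{\link{eegMontage}}.
#' @export
defaultMontage <- function() {
  labels <- c("Cz", "Fz", "C3", "C4", "Pz", "TP9", "TP10", "Oz",
              "EOG1", "EOG2")
  types <- c(rep("EEG", 8), "EOG", "EOG")
  erp <- c(1.0, 0.6, 0.7, 0.7, 0.4, -1.2, -1.2, -1.0, 0, 0)
  blink <- c(0.15, 0.35, 0.10, 0.10, 0.05, 0.05, 0.05, 0.02, 1, 1)
  eegMontage(labels, types, erp, blink)
}

#' Full 64 EEG + 4 EOG montage
#'
#' Mirrors a 64-channel 10-10 acquisition setup with four periocular EOG
#' electrodes. ERP and blink topographies follow the same normalization
#' rules as \code{\link{defaultMontage}}.
#'
#' @return An \code{\link{eegMontage}}.
#' @export
fullMontage <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2",
    "EOG1", "EOG2", "EOG3", "EOG4")
  types <- c(rep("EEG", 64), rep("EOG", 4))
  # crude central-maximal topography with inferior polarity inversion
  central <- c("Cz", "FCz", "CPz", "C1", "C2", "FC1", "FC2", "CP1", "CP2")
  mid <- c("Fz", "Pz", "C3", "C4", "FC3", "FC4", "CP3", "CP4", "AFz", "POz",
           "F1", "F2", "P1", "P2")
  inferior <- c("T7", "T8", "TP7", "TP8", "P9", "P10", "FT7", "FT8", "Iz",
                "PO7", "PO8", "O1", "O2", "Oz")
  erp <- rep(0.2, 68)
  erp[labels %in% central] <- 1.0
  erp[labels == "Cz"] <- 1.1  # pre-normalization; rescaled to exactly 1
  erp[labels %in% mid] <- 0.6
  erp[labels %in% inferior] <- -1.0
  frontal <- grepl("^(Fp|AF|F[z0-9])", labels)
  blink <- ifelse(types == "EOG", 1, ifelse(frontal, 0.3, 0.05))
  eegMontage(labels, types, erp, blink)
}

#' One-row subject profile for direct simulation
#'
#' Convenience constructor for a single \code{SubjectProfile} with explicit
#' generative parameters (used in examples, tests and small studies);
#' \code{\link{generateCohort}} draws whole cohorts of these.
#'
#' @param subjectId subject identifier.
#' @param group group label.
#' @param n1Intercept,n1Slope N1 amplitude at 75 dB (microvolts, negative)
#'   and slope (microvolts/dB, <= 0).
#' @param p2Intercept,p2Slope P2 amplitude at 75 dB (positive) and slope
#'   (>= 0).
#' @param noiseSigmaUv,blinkRateHz,lineAmpUv noise parameters.
#' @param age,bdiCognitive,bdiSomatic,menstrualPhase,hcType,adverseMood
#'   covariates (defaults are neutral placeholders).
#' @return One-row data.frame compatible with \code{generateCohort} output.
#' @export
subjectProfile <- function(subjectId = "sub-01", group = "current_user",
                           n1Intercept = -5, n1Slope = -0.08,
                           p2Intercept = 5, p2Slope = 0.12,
                           noiseSigmaUv = 10, blinkRateHz = 0.25,
                           lineAmpUv = 5, age = 25, bdiCognitive = 3,
                           bdiSomatic = 5, menstrualPhase = "unknown",
                           hcType = "none", adverseMood = FALSE) {
  data.frame(subject_id = subjectId, group = group, hc_type = hcType,
             age = age, bdi_cognitive = bdiCognitive,
             bdi_somatic_affective = bdiSomatic,
             menstrual_phase = menstrualPhase, adverse_mood = adverseMood,
             true_n1_intercept_uv = n1Intercept,
             true_n1_slope_uv_per_db = n1Slope,
             true_p2_intercept_uv = p2Intercept,
             true_p2_slope_uv_per_db = p2Slope,
             noise_sigma_uv = noiseSigmaUv, blink_rate_hz = blinkRateHz,
             line_amp_uv = lineAmpUv, stringsAsFactors = FALSE)
}

# unit-peak Gaussian kernel sampled at fs over [0, supportS]
gaussKernel <- function(fs, centerS, sigmaS, supportS) {
  t <- seq(0, supportS, by = 1 / fs)
  exp(-(t - centerS)^2 / (2 * sigmaS^2))
}

# 1/f-shaped Gaussian noise with target RMS (sd across samples)
pinkNoise <- function(n, fs, rms) {
  if (rms <= 0 || n < 2) return(numeric(n))
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  mag <- 1 / sqrt(f)
  re <- stats::rnorm(nf) * mag
  im <- stats::rnorm(nf) * mag
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = re[nf], imaginary = 0)
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (rms / stats::sd(x))
}

# biphasic blink transient (~400 ms), unit positive peak
blinkKernel <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  b <- exp(-(t - 0.10)^2 / (2 * 0.030^2)) -
    0.35 * exp(-(t - 0.25)^2 / (2 * 0.060^2))
  b / max(b)
}

#' Simulate a raw auditory-evoked EEG recording
#'
#' For every stimulus event, adds to all EEG channels (scaled by the
#' montage's ERP topography, which is maximal at Cz) the component kernel
#' \deqn{s(t) = A_{N1} g(t; 100ms, 15ms) + A_{P2} g(t; 180ms, 25ms)}
#' with unit-peak Gaussians g, where the component amplitudes follow the
#' subject's linear loudness model centered at 75 dB:
#' \eqn{A_{N1} = intercept_{N1} + slope_{N1} (dB - 75)} (negative) and
#' analogously for P2 (positive). On top of the evoked signal the simulator
#' adds per-channel pink background noise (1/f, RMS \code{noise_sigma_uv}),
#' a 50 Hz line-noise sinusoid with per-channel amplitude jitter,
#' Poisson-scheduled biphasic blink transients (>= 100 microvolts on EOG,
#' frontally weighted on EEG), and - optionally - injected bad channels
#' (flat or high-variance) and broadband bad segments.
#'
#' Event onsets are quantized to the sample grid; the stored event table
#' contains the quantized onsets so downstream epoching aligns exactly.
#'
#' @param profile one-row data.frame from \code{\link{generateCohort}} or
#'   \code{\link{subjectProfile}}.
#' @param events data.frame from \code{\link{generateParadigm}}.
#' @param fs sampling rate (Hz), default 2048.
#' @param montage an \code{\link{eegMontage}} (default reduced 8+2).
#' @param seed integer seed for the noise processes.
#' @param padEndS silence appended after the last epoch window (s).
#' @param badChannels optional list with elements \code{flat} and/or
#'   \code{noisy}: channel labels to corrupt.
#' @param badSegments optional data.frame with \code{start_s}, \code{end_s}:
#'   windows overwritten with broadband bursts on all channels.
#' @return A \linkS4class{RawRecording} (reference state "raw").
#' @examples
#' prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0)
#' ev <- generateParadigm(paradigmSpec(trialsPerIntensity = 2, seed = 1))
#' rec <- simulateRecording(prof, ev, fs = 512, seed = 1)
#' rec
#' @export
simulateRecording <- function(profile, events, fs = 2048,
                              montage = defaultMontage(), seed = 1L,
                              padEndS = 1, badChannels = NULL,
                              badSegments = NULL) {
  stopifnot(inherits(montage, "eegMontage"))
  if (!"Cz" %in% montage$labels) stop("montage must contain Cz")
  if (nrow(events) == 0) stop("events must contain at least one stimulus")
  prof <- as.list(profile[1, ])

  onsetSmp <- round(events$onset_s * fs)
  if (any(onsetSmp < 0)) stop("event onsets must be >= 0")
  nSmp <- max(onsetSmp) + round((0.5 + padEndS) * fs) + 1
  # pad to a 5-smooth length so whole-recording FFTs stay fast
  nSmp <- stats::nextn(nSmp, c(2, 3, 5))
  nCh <- length(montage$labels)

  g1 <- gaussKernel(fs, 0.100, 0.015, 0.35)
  g2 <- gaussKernel(fs, 0.180, 0.025, 0.35)
  kl <- length(g1)

  # evoked source time course, shared across channels
  src <- numeric(nSmp)
  aN1 <- prof$true_n1_intercept_uv +
    prof$true_n1_slope_uv_per_db * (events$intensity_db - 75)
  aP2 <- prof$true_p2_intercept_uv +
    prof$true_p2_slope_uv_per_db * (events$intensity_db - 75)
  for (i in seq_along(onsetSmp)) {
    idx <- onsetSmp[i] + seq_len(kl)
    src[idx] <- src[idx] + aN1[i] * g1 + aP2[i] * g2
  }
  data <- outer(montage$erpWeights, src)

  withSeed(seed, {
    if (prof$noise_sigma_uv > 0) {
      # Spatially correlated background: a fraction of each EEG channel's
      # noise variance comes from smooth shared spatial patterns (volume
      # conduction), the rest is channel-specific. Shared weights are two
      # quadrature pairs over the montage, so neighbouring channels stay
      # highly correlated even after average re-referencing.
      eegIdx <- which(montage$types == "EEG")
      gamma <- 0.75
      shared <- sapply(1:4, function(k) pinkNoise(nSmp, fs, 1))
      theta <- pi * (seq_along(eegIdx) - 1) / length(eegIdx)
      W <- cbind(cos(theta), sin(theta), cos(2 * theta), sin(2 * theta)) /
        sqrt(2)
      sigma <- prof$noise_sigma_uv
      for (j in seq_along(eegIdx)) {
        ch <- eegIdx[j]
        data[ch, ] <- data[ch, ] +
          sigma * (sqrt(gamma) * as.numeric(shared %*% W[j, ]) +
                     sqrt(1 - gamma) * pinkNoise(nSmp, fs, 1))
      }
      for (ch in which(montage$types == "EOG"))
        data[ch, ] <- data[ch, ] + pinkNoise(nSmp, fs, sigma)
    }
    if (prof$line_amp_uv > 0) {
      t <- seq_len(nSmp) / fs
      base <- sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      amp <- prof$line_amp_uv * stats::runif(nCh, 0.5, 1.5)
      data <- data + outer(amp, base)
    }
    if (prof$blink_rate_hz > 0) {
      nBlink <- stats::rpois(1, prof$blink_rate_hz * nSmp / fs)
      if (nBlink > 0) {
        bk <- blinkKernel(fs)
        bTimes <- sort(stats::runif(nBlink, 0, nSmp / fs - 0.45))
        bAmp <- stats::runif(nBlink, 100, 200)
        bSrc <- numeric(nSmp)
        for (i in seq_len(nBlink)) {
          idx <- round(bTimes[i] * fs) + seq_along(bk)
          bSrc[idx] <- bSrc[idx] + bAmp[i] * bk
        }
        data <- data + outer(montage$blinkWeights, bSrc)
      }
    }
    if (!is.null(badSegments)) {
      for (i in seq_len(nrow(badSegments))) {
        idx <- max(1, round(badSegments$start_s[i] * fs)) :
          min(nSmp, round(badSegments$end_s[i] * fs))
        data[, idx] <- data[, idx] +
          matrix(stats::rnorm(nCh * length(idx), sd = 100), nCh)
      }
    }
    if (!is.null(badChannels)) {  # last: a dead electrode records nothing
      for (lab in badChannels$flat)
        data[match(lab, montage$labels), ] <- 0
      for (lab in badChannels$noisy)
        data[match(lab, montage$labels), ] <- stats::rnorm(nSmp, sd = 200)
    }
    NULL
  })

  rawRecording(data, fs = fs, channelLabels = montage$labels,
               channelTypes = montage$types,
               events = data.frame(onset_s = onsetSmp / fs,
                                   intensity_db = events$intensity_db),
               reference = "raw")
}
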