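#' Average epochs by stimulus intensity
#'
#' Arithmetic mean of all kept epochs at the named channel, one averaged
#' AEP waveform per intensity.
#'
#' @param es An \linkS4class{EpochSet}.
#' @param channel electrode label (default "Cz").
#' @return Object of class \code{aepWaveforms}: \code{times} (s),
#'   \code{amplitude} (intensities x samples matrix, microvolts, rownames =
#'   intensity), \code{nEpochs} (kept epochs averaged per intensity),
#'   \code{channel}. Intensities with zero kept epochs yield an NA row.
#' @export
averageByIntensity <- function(es, channel = "Cz") {
  ci <- match(channel, channelLabels(es))
  if (is.na(ci)) stop("channel not present: ", channel)
  ints <- sort(unique(es@intensityDb))
  amp <- matrix(NA_real_, length(ints), nSamples(es),
                dimnames = list(ints, NULL))
  nEp <- setNames(integer(length(ints)), ints)
  for (i in seq_along(ints)) {
    sel <- which(es@keep & es@intensityDb == ints[i])
    nEp[i] <- length(sel)
    if (length(sel))
      amp[i, ] <- colMeans(matrix(es@data[sel, ci, ],
                                  nrow = length(sel)))
  }
  structure(list(times = es@times, amplitude = amp, nEpochs = nEp,
                 channel = channel, intensities = ints),
            class = "aepWaveforms")
}

#' Detect an ERP component peak
#'
#' Returns the signed extremum of the waveform over the component's search
#' window: the minimum in 60-140 ms for N1, the maximum in 150-250 ms for
#' P2 (windows inclusive at both ends). Ties are resolved to the earliest
#' latency; latency is reported at sample resolution.
#'
#' @param times time axis (s).
#' @param amplitude waveform (microvolts), same length as \code{times}.
#' @param component "N1" or "P2".
#' @param window optional c(start, end) s override of the search window.
#' @return list with \code{component}, \code{latency_s}, \code{amplitude_uv},
#'   \code{window}.
#' @examples
#' t <- seq(0, 0.3, by = 1/512)
#' w <- -3 * exp(-(t - 0.1)^2 / (2 * 0.015^2))
#' detectPeak(t, w, "N1")$amplitude_uv
#' @export
detectPeak <- function(times, amplitude, component = c("N1", "P2"),
                       window = NULL) {
  component <- match.arg(component)
  if (is.null(window))
    window <- if (component == "N1") c(0.060, 0.140) else c(0.150, 0.250)
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel) || window[1] < min(times) || window[2] > max(times))
    stop("search window lies outside the epoch time axis")
  w <- amplitude[sel]
  k <- if (component == "N1") which.min(w) else which.max(w)
  # which.min/max already return the first (earliest) extremum on ties
  list(component = component, latency_s = times[sel[k]],
       amplitude_uv = w[k], window = window)
}

# OLS of y on x via the QR-based fitter; returns slope/intercept/R2
olsLine <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]), r2 = r2)
}

#' Compute LDAEP slopes from per-intensity peak amplitudes
#'
#' The LDAEP is the ordinary least-squares slope of peak amplitude
#' (microvolts) on stimulus intensity (dB SPL), fitted independently for
#' N1, P2 and the peak-to-peak N1P2 amplitude (P2 - N1 at each intensity).
#' Because all three lines share the same abscissa, the fitted N1P2 slope
#' equals the P2 slope minus the N1 slope exactly.
#'
#' @param n1,p2 per-intensity N1 and P2 peak amplitudes (microvolts).
#' @param intensities stimulus intensities (dB SPL), same length.
#' @param subjectIdLabel,channel,latencies,nEpochs optional metadata.
#' @return An \linkS4class{LdaepResult}. With fewer than 2 complete design
#'   points the result is flagged and slopes are NA.
#' @examples
#' r <- computeLdaep(n1 = c(-2, -3, -4, -5, -6), p2 = c(3, 4, 5, 6, 7),
#'                   intensities = c(55, 65, 75, 85, 95))
#' slopes(r)
#' @export
computeLdaep <- function(n1, p2, intensities,
                         subjectIdLabel = "subject", channel = "Cz",
                         latencies = NULL, nEpochs = NULL) {
  stopifnot(length(n1) == length(intensities),
            length(p2) == length(intensities))
  n1p2 <- p2 - n1
  amp <- rbind(n1 = n1, p2 = p2, n1p2 = n1p2)
  colnames(amp) <- intensities
  ok <- is.finite(n1) & is.finite(p2)
  if (is.null(latencies))
    latencies <- matrix(NA_real_, 2, length(intensities),
                        dimnames = list(c("n1", "p2"), intensities))
  if (is.null(nEpochs)) nEpochs <- rep(NA_real_, length(intensities))
  if (sum(ok) < 2 || length(unique(intensities[ok])) < 2) {
    return(new("LdaepResult", subjectId = subjectIdLabel, channel = channel,
               intensities = as.numeric(intensities), amplitudes = amp,
               latencies = latencies,
               slopes = c(n1 = NA_real_, p2 = NA_real_, n1p2 = NA_real_),
               intercepts = c(n1 = NA_real_, p2 = NA_real_, n1p2 = NA_real_),
               r2 = c(n1 = NA_real_, p2 = NA_real_, n1p2 = NA_real_),
               nEpochs = as.numeric(nEpochs), flagged = TRUE,
               note = "fewer than 2 complete design points"))
  }
  x <- intensities[ok]
  fits <- lapply(list(n1 = n1[ok], p2 = p2[ok], n1p2 = n1p2[ok]),
                 function(y) olsLine(x, y))
  new("LdaepResult", subjectId = subjectIdLabel, channel = channel,
      intensities = as.numeric(intensities), amplitudes = amp,
      latencies = latencies,
      slopes = vapply(fits, `[[`, 0, "slope"),
      intercepts = vapply(fits, `[[`, 0, "intercept"),
      r2 = vapply(fits, `[[`, 0, "r2"),
      nEpochs = as.numeric(nEpochs), flagged = !all(ok),
      note = if (all(ok)) "" else "incomplete design points excluded")
}

#' LDAEP from an epoch set
#'
#' Convenience wrapper: averages kept epochs by intensity at the analysis
#' electrode, detects the N1 and P2 peaks per intensity, and fits the three
#' LDAEP lines.
#'
#' @param es An \linkS4class{EpochSet}.
#' @param channel electrode label (default "Cz").
#' @return An \linkS4class{LdaepResult}.
#' @export
ldaepFromEpochs <- function(es, channel = "Cz") {
  wf <- averageByIntensity(es, channel)
  nInt <- length(wf$intensities)
  n1 <- p2 <- rep(NA_real_, nInt)
  lat <- matrix(NA_real_, 2, nInt,
                dimnames = list(c("n1", "p2"), wf$intensities))
  for (i in seq_len(nInt)) {
    if (wf$nEpochs[i] == 0) next
    pN <- detectPeak(wf$times, wf$amplitude[i, ], "N1")
    pP <- detectPeak(wf$times, wf$amplitude[i, ], "P2")
    n1[i] <- pN$amplitude_uv; p2[i] <- pP$amplitude_uv
    lat[, i] <- c(pN$latency_s, pP$latency_s)
  }
  computeLdaep(n1, p2, wf$intensities, subjectIdLabel = subjectId(es),
               channel = channel, latencies = lat, nEpochs = wf$nEpochs)
}

#' @rdname subjectId
#' @export
setMethod("subjectId", "LdaepResult", function(x) x@subjectId)

#' @rdname slopes
#' @export
setMethod("slopes", "LdaepResult", function(x) x@slopes)

#' @rdname peakAmplitudes
#' @export
setMethod("peakAmplitudes", "LdaepResult", function(x) x@amplitudes)

setMethod("show", "LdaepResult", function(object) {
  cat("LdaepResult [", object@subjectId, "] at ", object@channel, "\n",
      sep = "")
  print(round(object@amplitudes, 3))
  cat("slopes (uV/dB): N1 ", sprintf("%.4f", object@slopes["n1"]),
      "  P2 ", sprintf("%.4f", object@slopes["p2"]),
      "  N1P2 ", sprintf("%.4f", object@slopes["n1p2"]), "\n", sep = "")
  if (object@flagged) cat("FLAGGED:", object@note, "\n")
})

#' Tabulate LDAEP results across subjects
#'
#' @param results list of \linkS4class{LdaepResult} objects.
#' @return data.frame, one row per subject: slopes, intercepts, R-squared,
#'   kept epochs per intensity.
#' @export
ldaepTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    row <- data.frame(subject_id = r@subjectId, channel = r@channel,
                      n1_slope = r@slopes["n1"], p2_slope = r@slopes["p2"],
                      n1p2_slope = r@slopes["n1p2"],
                      n1_r2 = r@r2["n1"], p2_r2 = r@r2["p2"],
                      n1p2_r2 = r@r2["n1p2"],
                      flagged = r@flagged, stringsAsFactors = FALSE)
    rownames(row) <- NULL
    row
  }))
}
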