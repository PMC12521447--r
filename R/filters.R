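# FIR filtering and Fourier resampling primitives.
#
# All filters are linear-phase windowed-sinc FIRs (signal::fir1, Hamming
# window) applied in one pass by FFT convolution with exact group-delay
# compensation, which for a symmetric FIR is equivalent to zero-phase
# filtering. Filter length is set from the transition width by the usual
# Hamming rule L ~ 3.3 * fs / transition.

firLength <- function(fs, transHz) {
  l <- ceiling(3.3 * fs / transHz)
  if (l %% 2 == 0) l <- l + 1
  l
}

#' Design a zero-phase FIR filter
#'
#' @param fs sampling rate (Hz).
#' @param type "low", "high" or "pass".
#' @param cutoff one cutoff (low/high) or c(low, high) for "pass", in Hz.
#' @param transHz transition width in Hz; default 25\% of the (lower)
#'   cutoff, floored at 1 Hz and capped at 8 Hz.
#' @return Numeric vector of symmetric FIR coefficients (odd length).
#' @export
designFir <- function(fs, type = c("low", "high", "pass"), cutoff,
                      transHz = NULL) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("cutoff must lie strictly inside (0, fs/2)")
  if (is.null(transHz))
    transHz <- min(max(min(cutoff) * 0.25, 1), 8)
  l <- firLength(fs, transHz)
  signal::fir1(l - 1, cutoff / (fs / 2), type)
}

# Zero-phase application of a symmetric odd-length FIR to a channels x
# samples matrix via FFT convolution (single pass + group-delay shift).
applyFir <- function(x, b) {
  onevec <- is.null(dim(x))
  if (onevec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  l <- length(b)
  half <- (l - 1) / 2
  nfft <- stats::nextn(n + l - 1, c(2, 3, 5))
  bf <- stats::fft(c(b, numeric(nfft - l)))
  out <- x
  for (ch in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[ch, ], numeric(nfft - n)))
    y <- Re(stats::fft(xf * bf, inverse = TRUE)) / nfft
    out[ch, ] <- y[half + seq_len(n)]
  }
  if (onevec) out[1, ] else out
}

# Fourier-method resampling of a vector: keeps the common band, implicit
# brick-wall anti-aliasing, length round(n * targetFs / fs).
fftResampleVec <- function(x, fs, targetFs) {
  n <- length(x)
  m <- round(n * targetFs / fs)
  if (m == n) return(x)
  xf <- stats::fft(x)
  yf <- complex(length.out = m)
  kmax <- min(floor((m - 1) / 2), floor((n - 1) / 2))
  yf[1] <- xf[1]
  if (kmax > 0) {
    yf[1 + seq_len(kmax)] <- xf[1 + seq_len(kmax)]
    yf[m + 1 - seq_len(kmax)] <- xf[n + 1 - seq_len(kmax)]
  }
  if (m %% 2 == 0 && m / 2 <= floor(n / 2))
    yf[m / 2 + 1] <- Re(xf[m / 2 + 1])
  Re(stats::fft(yf, inverse = TRUE)) / n
}
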