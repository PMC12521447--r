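#' Stimulation paradigm specification
#'
#' Defaults describe a five-intensity loudness paradigm: 1 kHz tones at
#' 55-95 dB SPL, 80 trials per intensity, onset-to-onset interstimulus
#' interval drawn uniformly from 1200-1800 ms, 30 ms tones.
#'
#' @param intensitiesDb distinct sound levels in dB SPL.
#' @param trialsPerIntensity trials per intensity level.
#' @param isiRangeMs length-2 numeric, (min, max) onset-to-onset ISI in ms.
#' @param toneDurationMs tone duration in ms (bookkeeping only; scheduling is
#'   onset-anchored).
#' @param seed integer seed for the trial-order shuffle and ISI draws.
#' @return An object of class \code{paradigmSpec} (validated list).
#' @examples
#' spec <- paradigmSpec(seed = 1)
#' ev <- generateParadigm(spec)
#' table(ev$intensity_db)
#' @export
paradigmSpec <- function(intensitiesDb = c(55, 65, 75, 85, 95),
                         trialsPerIntensity = 80,
                         isiRangeMs = c(1200, 1800),
                         toneDurationMs = 30,
                         seed = 1L) {
  if (length(intensitiesDb) == 0)
    stop("intensitiesDb must be non-empty")
  if (anyDuplicated(intensitiesDb))
    stop("intensitiesDb must be distinct")
  if (length(isiRangeMs) != 2 || isiRangeMs[1] >= isiRangeMs[2])
    stop("isiRangeMs must be (min, max) with min < max")
  if (trialsPerIntensity < 1)
    stop("trialsPerIntensity must be >= 1")
  structure(list(intensitiesDb = as.numeric(intensitiesDb),
                 trialsPerIntensity = as.integer(trialsPerIntensity),
                 isiRangeMs = as.numeric(isiRangeMs),
                 toneDurationMs = as.numeric(toneDurationMs),
                 seed = as.integer(seed)),
            class = "paradigmSpec")
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a pseudo-randomized stimulus event list
#'
#' Pseudo-randomization is operationalized as an independent uniform shuffle
#' within consecutive blocks containing one trial of each intensity, which
#' keeps the presentation balanced throughout the run. Onset-to-onset gaps
#' are drawn uniformly from the ISI range; the first onset is placed at
#' \code{startS}. Onsets are returned on a continuous time axis (seconds);
#' \code{\link{simulateRecording}} quantizes them to its sample grid.
#'
#' @param spec A \code{\link{paradigmSpec}}.
#' @param startS time of the first stimulus onset (s).
#' @return data.frame with columns \code{onset_s} (increasing) and
#'   \code{intensity_db}; one row per trial,
#'   \code{trialsPerIntensity * length(intensitiesDb)} rows in total.
#' @export
generateParadigm <- function(spec, startS = 2) {
  stopifnot(inherits(spec, "paradigmSpec"))
  nInt <- length(spec$intensitiesDb)
  nEv <- nInt * spec$trialsPerIntensity
  withSeed(spec$seed, {
    labels <- unlist(lapply(seq_len(spec$trialsPerIntensity), function(b) {
      spec$intensitiesDb[sample.int(nInt)]
    }))
    gaps <- stats::runif(nEv - 1, spec$isiRangeMs[1] / 1000,
                         spec$isiRangeMs[2] / 1000)
    data.frame(onset_s = startS + c(0, cumsum(gaps)),
               intensity_db = labels)
  })
}

#' Derive a reproducible stage seed from a global seed
#'
#' Every stochastic stage of the pipeline derives its own seed from the
#' global run seed plus a stage label (and optionally a subject index), so
#' stages can be re-run in isolation and remain mutually independent.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @param k optional integer (e.g. subject index).
#' @return Integer seed in [0, 2^31 - 1).
#' @export
stageSeed <- function(seed, stage, k = 0L) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 48271 + h * 1103 + k * 7919) %% 2147483647)
}
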