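# Shared fixture builders (all generated in code at test time).

# a fast noiseless subject: few trials, simulation directly at 512 Hz
cleanRecording <- function(trials = 2, fs = 512, seed = 1,
                           n1Slope = -0.08, p2Slope = 0.12) {
  prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0,
                         n1Slope = n1Slope, p2Slope = p2Slope)
  ev <- generateParadigm(paradigmSpec(trialsPerIntensity = trials,
                                      seed = seed))
  simulateRecording(prof, ev, fs = fs, seed = seed)
}

# toy epoch set with known per-trial content: one channel ("Cz"), trials
# built from a supplied matrix (trials x samples)
toyEpochs <- function(m, fs = 512, intensity = rep(75, nrow(m))) {
  arr <- array(m, dim = c(nrow(m), 1, ncol(m)))
  epochSet(arr, fs = fs,
           times = seq(0, by = 1 / fs, length.out = ncol(m)),
           intensityDb = intensity, channelLabels = "Cz",
           channelTypes = "EEG", subjectId = "toy")
}

# small cohort config for pipeline tests
tinyRunConfig <- function(seed = 1, trials = 2, nCurrent = 3, nPast = 1,
                          nNever = 1, fs = 512, noise = 0) {
  runConfig(
    paradigm = paradigmSpec(trialsPerIntensity = trials, seed = seed),
    cohort = cohortSpec(nCurrent = nCurrent, nPast = nPast, nNever = nNever,
                        noiseSigmaUv = noise, blinkRateHz = 0,
                        lineAmpUv = 0, seed = seed),
    fs = fs, seed = seed)
}
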