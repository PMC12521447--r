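test_that("noiseless construction reproduces the component amplitudes", {
  # single 75 dB event: Cz trace must show A_N1 at 100 ms, A_P2 at 180 ms
  prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0,
                         n1Intercept = -4, n1Slope = -0.08,
                         p2Intercept = 5, p2Slope = 0.12)
  ev <- data.frame(onset_s = 1, intensity_db = 75)
  rec <- simulateRecording(prof, ev, fs = 2048, seed = 1)
  cz <- recData(rec)["Cz", ]
  t <- seq_len(nSamples(rec)) / 2048 - 1  # relative to onset
  n1 <- min(cz[t >= 0.06 & t <= 0.14])
  p2 <- max(cz[t >= 0.15 & t <= 0.25])
  expect_equal(n1, -4, tolerance = 0.02)
  expect_equal(p2, 5, tolerance = 0.02)
})

test_that("component amplitudes follow the linear loudness model", {
  # A_N1(55) = -4 + (-0.08)(-20) = -2.4; A_N1(95) = -5.6
  prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0,
                         n1Intercept = -4, n1Slope = -0.08)
  ev <- data.frame(onset_s = c(1, 3), intensity_db = c(55, 95))
  rec <- simulateRecording(prof, ev, fs = 2048, seed = 1)
  cz <- recData(rec)["Cz", ]
  t <- seq_len(nSamples(rec)) / 2048
  n1a <- min(cz[t - 1 >= 0.06 & t - 1 <= 0.14])
  n1b <- min(cz[t - 3 >= 0.06 & t - 3 <= 0.14])
  expect_equal(n1a, -2.4, tolerance = 0.02)
  expect_equal(n1b, -5.6, tolerance = 0.02)
})

test_that("background noise is pink: low-frequency power dominates", {
  prof <- subjectProfile(n1Intercept = 0, n1Slope = 0, p2Intercept = 0,
                         p2Slope = 0, noiseSigmaUv = 10, blinkRateHz = 0,
                         lineAmpUv = 0)
  ev <- data.frame(onset_s = 1, intensity_db = 75)
  rec <- simulateRecording(prof, ev, fs = 512, seed = 7, padEndS = 30)
  x <- recData(rec)["Cz", ]
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * 512 / n
  low <- mean(p[f >= 1 & f <= 10])
  high <- mean(p[f >= 40 & f <= 50])
  expect_gt(low, 10 * high)
  # sample RMS of the mixed pink sources fluctuates around the target
  expect_equal(sd(x), 10, tolerance = 0.2)
})

test_that("blinks are large on EOG and frontally weighted on EEG", {
  prof <- subjectProfile(n1Intercept = 0, n1Slope = 0, p2Intercept = 0,
                         p2Slope = 0, noiseSigmaUv = 0, blinkRateHz = 0.5,
                         lineAmpUv = 0)
  ev <- data.frame(onset_s = 1, intensity_db = 75)
  rec <- simulateRecording(prof, ev, fs = 512, seed = 3, padEndS = 60)
  d <- recData(rec)
  expect_gte(max(d["EOG1", ]), 100)
  expect_gt(max(d["Fz", ]), max(d["Oz", ]))
})

test_that("ERP topography is zero-mean so re-referencing preserves Cz", {
  rec <- cleanRecording(trials = 1)
  czBefore <- recData(rec)["Cz", ]
  rr <- rereferenceAverage(rec)
  expect_equal(recData(rr)["Cz", ], czBefore, tolerance = 1e-9)
  m <- defaultMontage()
  expect_equal(mean(m$erpWeights[m$types == "EEG"]), 0, tolerance = 1e-12)
  expect_equal(m$erpWeights[m$labels == "Cz"], 1)
  m64 <- fullMontage()
  expect_equal(mean(m64$erpWeights[m64$types == "EEG"]), 0,
               tolerance = 1e-12)
  expect_equal(m64$erpWeights[m64$labels == "Cz"], 1)
  expect_equal(sum(m64$types == "EEG"), 64)
  expect_equal(sum(m64$types == "EOG"), 4)
})

test_that("simulation is bit-deterministic given the seed", {
  a <- simulateRecording(subjectProfile(),
                         generateParadigm(paradigmSpec(trialsPerIntensity = 1,
                                                       seed = 2)),
                         fs = 512, seed = 5)
  b <- simulateRecording(subjectProfile(),
                         generateParadigm(paradigmSpec(trialsPerIntensity = 1,
                                                       seed = 2)),
                         fs = 512, seed = 5)
  expect_identical(recData(a), recData(b))
})

test_that("event bookkeeping is conserved through simulation", {
  ev <- generateParadigm(paradigmSpec(trialsPerIntensity = 3, seed = 4))
  rec <- simulateRecording(subjectProfile(noiseSigmaUv = 0,
                                          blinkRateHz = 0, lineAmpUv = 0),
                           ev, fs = 512, seed = 1)
  expect_equal(as.vector(table(recEvents(rec)$intensity_db)), rep(3, 5))
  expect_gte(recordingDuration(rec), max(ev$onset_s) + 0.5)
})

test_that("a montage without Cz is rejected", {
  expect_error(eegMontage(c("Fz", "Pz"), c("EEG", "EEG"), c(1, -1),
                          c(0, 0)), "Cz")
})

test_that("injected bad channels and segments appear in the data", {
  prof <- subjectProfile(noiseSigmaUv = 0, blinkRateHz = 0, lineAmpUv = 0)
  ev <- data.frame(onset_s = 1, intensity_db = 75)
  rec <- simulateRecording(prof, ev, fs = 512, seed = 1, padEndS = 10,
                           badChannels = list(flat = "Oz", noisy = "Pz"),
                           badSegments = data.frame(start_s = 4,
                                                    end_s = 6))
  d <- recData(rec)
  expect_true(all(d["Oz", ] == 0))
  expect_gt(sd(d["Pz", ]), 100)
  t <- seq_len(ncol(d)) / 512
  expect_gt(sd(d["Cz", t > 4 & t < 6]), 10 * sd(d["Cz", t > 7 & t < 9]))
})
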