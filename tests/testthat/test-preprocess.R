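twoChan <- function(m, types = c("EEG", "EEG"),
                    labels = c("Cz", "Pz")) {
  rawRecording(m, fs = 100, channelLabels = labels, channelTypes = types)
}

test_that("average re-referencing subtracts the channel mean", {
  rec <- twoChan(matrix(c(1, 3, 3, 5), 2, byrow = TRUE))
  out <- recData(rereferenceAverage(rec))
  expect_equal(out, matrix(c(-1, -1, 1, 1), 2, byrow = TRUE,
                           dimnames = list(c("Cz", "Pz"), NULL)))
})

test_that("re-referencing is idempotent and zero-mean at every sample", {
  set.seed(1)
  rec <- rawRecording(matrix(rnorm(5 * 200), 5), fs = 100,
                      channelLabels = c("Cz", "Pz", "Fz", "Oz", "EOG1"),
                      channelTypes = c(rep("EEG", 4), "EOG"))
  once <- rereferenceAverage(rec)
  twice <- rereferenceAverage(once)
  expect_equal(recData(once), recData(twice), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(recData(once)[1:4, ]))), 1e-9)
  # EOG untouched
  expect_equal(recData(once)[5, ], recData(rec)[5, ])
})

test_that("re-referencing to a subset leaves excluded channels unchanged", {
  set.seed(2)
  rec <- rawRecording(matrix(rnorm(3 * 50), 3), fs = 100,
                      channelLabels = c("Cz", "Pz", "Fz"),
                      channelTypes = rep("EEG", 3))
  out <- rereferenceAverage(rec, c("Cz", "Pz"))
  expect_lt(max(abs(colMeans(recData(out)[1:2, ]))), 1e-9)
  expect_equal(recData(out)[3, ], recData(rec)[3, ])
  expect_error(rereferenceAverage(rec, character(0)), "empty")
})

test_that("bad-channel detection flags degenerate and uncorrelated channels", {
  set.seed(3)
  n <- 512 * 20
  common <- rnorm(n)
  labs <- c("Cz", "Fz", "C3", "C4", "Pz", "TP9", "TP10", "Oz")
  d <- t(sapply(1:8, function(i) common + 0.3 * rnorm(n)))
  d[7, ] <- 0                            # flatline
  d[8, ] <- sd(d[1, ]) * rnorm(n)        # independent, variance-matched
  rec <- rawRecording(d, fs = 512, channelLabels = labs,
                      channelTypes = rep("EEG", 8))
  rep_ <- detectBadChannels(rec)
  expect_true(rep_$flag[7] %in% c("bad_variance", "bad_correlation"))
  expect_equal(rep_$flag[8], "bad_correlation")
  expect_true(all(rep_$flag[1:6] == "good"))
})

test_that("identical channels: correlation 1, none flagged by variance", {
  x <- sin(2 * pi * 3 * seq(0, 10, by = 1 / 512))[-1]
  d <- matrix(rep(x, 4), 4, byrow = TRUE)
  rec <- rawRecording(d, fs = 512,
                      channelLabels = c("Cz", "Pz", "Fz", "Oz"),
                      channelTypes = rep("EEG", 4))
  rep_ <- detectBadChannels(rec)
  expect_true(all(rep_$flag == "good"))
  expect_true(all(abs(rep_$maxAbsCorrelation - 1) < 1e-12))
})

test_that("correlation criterion is skipped below 4 channels", {
  rec <- rawRecording(matrix(rnorm(3 * 100), 3), fs = 100,
                      channelLabels = c("Cz", "Pz", "Fz"),
                      channelTypes = rep("EEG", 3))
  expect_warning(rep_ <- detectBadChannels(rec), "correlation")
  expect_true(all(is.na(rep_$maxAbsCorrelation)))
})

test_that("segment rule: strict inequality on both fraction and SD", {
  fs <- 100
  mk <- function(nHot) {
    d <- matrix(rnorm(8 * fs * 10, sd = 5), 8)   # quiet background
    if (nHot > 0)
      d[seq_len(nHot), seq_len(fs * 5)] <-
        rnorm(nHot * fs * 5, sd = 30)            # SD 30 > 25 in block 1
    rawRecording(d, fs = fs,
                 channelLabels = paste0("ch", 1:8),
                 channelTypes = rep("EEG", 8))
  }
  set.seed(4)
  # 2 of 8 channels hot: fraction 0.25, not > 0.25 -> kept
  m2 <- detectBadSegments(mk(2))
  expect_true(m2$keep[1])
  # 3 of 8: fraction 0.375 > 0.25 -> dropped
  set.seed(4)
  m3 <- detectBadSegments(mk(3))
  expect_false(m3$keep[1])
  expect_true(all(m3$keep[-1]))
  # all-zero recording: everything kept; blocks tile the recording
  m0 <- detectBadSegments(rawRecording(matrix(0, 8, fs * 12), fs = fs,
                                       channelLabels = paste0("ch", 1:8),
                                       channelTypes = rep("EEG", 8)))
  expect_true(all(m0$keep))
  expect_equal(m0$startSample[1], 1)
  expect_equal(m0$endSample[length(m0$endSample)], fs * 12)
  # SD below the 25 uV limit never counts, however many channels reach it
  set.seed(5)
  dlo <- matrix(rnorm(8 * fs * 5), 8)
  dlo <- dlo / apply(dlo, 1, sd) * 24.9
  recLo <- rawRecording(dlo, fs = fs, channelLabels = paste0("ch", 1:8),
                        channelTypes = rep("EEG", 8))
  expect_true(all(detectBadSegments(recLo)$keep))
})

test_that("EOG regression removes exact linear contamination", {
  set.seed(5)
  n <- 2000
  clean <- sin(2 * pi * 5 * seq_len(n) / 100)
  # EOG orthogonalized to the clean signal so the contamination is exact
  eog <- unname(resid(lm(cumsum(rnorm(n)) ~ clean)))
  d <- rbind(clean + 0.5 * eog, clean - 0.2 * eog, eog)
  rec <- rawRecording(d, fs = 100,
                      channelLabels = c("Cz", "Pz", "EOG1"),
                      channelTypes = c("EEG", "EEG", "EOG"))
  out <- recData(removeOcularArtifacts(rec))
  expect_equal(out["Cz", ], clean - mean(clean), tolerance = 1e-6)
  expect_equal(out["EOG1", ], eog)  # EOG preserved
})

test_that("EOG regression degenerate cases: zero EOG, missing EOG", {
  d <- rbind(rnorm(100), numeric(100))
  rec <- rawRecording(d, fs = 100, channelLabels = c("Cz", "EOG1"),
                      channelTypes = c("EEG", "EOG"))
  expect_equal(recData(removeOcularArtifacts(rec)), recData(rec))
  rec2 <- rawRecording(matrix(rnorm(100), 1), fs = 100,
                       channelLabels = "Cz", channelTypes = "EEG")
  expect_warning(out <- removeOcularArtifacts(rec2), "no EOG")
  expect_equal(recData(out), recData(rec2))
})

test_that("epoching: sample arithmetic, baseline, and bookkeeping", {
  fs <- 512
  n <- fs * 20
  d <- rbind(5 + numeric(n), rnorm(n))
  ev <- data.frame(onset_s = c(2, 5, 19.9), intensity_db = c(55, 95, 75))
  rec <- rawRecording(d, fs = fs, channelLabels = c("Cz", "Pz"),
                      channelTypes = c("EEG", "EEG"), events = ev)
  es <- epochRecording(rec)
  expect_equal(nSamples(es), 307)          # round(0.6 * 512)
  expect_equal(es@times[52], 0)            # onset at 1-based index 52
  expect_equal(nTrials(es), 3)
  expect_false(keptEpochs(es)[3])          # too close to the end
  expect_equal(es@dropReason[3], "edge")
  # constant channel is all zero after baseline correction
  expect_equal(max(abs(es@data[1, 1, ])), 0)
})

test_that("epochs inside dropped segments are excluded", {
  fs <- 100
  rec <- rawRecording(matrix(rnorm(2 * fs * 20), 2), fs = fs,
                      channelLabels = c("Cz", "Pz"),
                      channelTypes = c("EEG", "EEG"),
                      events = data.frame(onset_s = c(2, 7),
                                          intensity_db = c(55, 65)))
  segs <- structure(list(keep = c(TRUE, FALSE, TRUE, TRUE),
                         startSample = c(1, 501, 1001, 1501),
                         endSample = c(500, 1000, 1500, 2000)),
                    class = "segmentMask")
  es <- epochRecording(rec, segments = segs)
  expect_true(keptEpochs(es)[1])
  expect_false(keptEpochs(es)[2])
  expect_equal(es@dropReason[2], "bad_segment")
})

test_that("epoch screening rejects only gross outliers", {
  set.seed(6)
  m <- matrix(rnorm(100 * 50), 100)
  m[17, ] <- m[17, ] * 50
  es <- rejectEpochs(toyEpochs(m))
  expect_false(keptEpochs(es)[17])
  expect_equal(sum(!keptEpochs(es)), 1)
  expect_equal(es@dropReason[17], "rejected")
  # identical epochs: nothing rejected (z = 0 everywhere)
  es0 <- rejectEpochs(toyEpochs(matrix(1, 20, 10)))
  expect_true(all(keptEpochs(es0)))
  # infinite threshold keeps everything
  esInf <- rejectEpochs(toyEpochs(m), zThreshold = Inf)
  expect_true(all(keptEpochs(esInf)))
  # too few epochs: skipped with warning
  expect_warning(rejectEpochs(toyEpochs(matrix(rnorm(20), 2))), "fewer")
})

test_that("clean recordings pass through the whole chain untouched", {
  rec <- cleanRecording(trials = 2)
  pp <- preprocess(rec, subjectIdLabel = "clean")
  cnt <- pp$manifest$counts
  expect_equal(cnt$badChannels, 0)
  expect_equal(cnt$badSegments, 0)
  expect_equal(cnt$rejectedEpochs, 0)
  expect_equal(cnt$keptEpochs, 10)
  # stage order contract
  expect_equal(pp$manifest$stageOrder,
               c("rereference_average", "resample",
                 "bad_channel_detection", "rereference_remaining",
                 "bandpass", "line_suppression", "bad_segment_detection",
                 "ocular_regression", "final_lowpass", "epoching",
                 "epoch_rejection"))
  # per-intensity bookkeeping: kept + dropped = scheduled
  es <- pp$epochs
  tab <- table(intensityLabels(es))
  expect_true(all(tab == 2))
})

test_that("injected artifacts are caught and excluded by the chain", {
  prof <- subjectProfile(noiseSigmaUv = 3, blinkRateHz = 0, lineAmpUv = 0)
  ev <- generateParadigm(paradigmSpec(trialsPerIntensity = 4, seed = 8))
  rec <- simulateRecording(prof, ev, fs = 1024, seed = 8,
                           badChannels = list(noisy = "Oz"),
                           badSegments = data.frame(start_s = 11,
                                                    end_s = 13))
  pp <- preprocess(rec, subjectIdLabel = "dirty")
  expect_true("Oz" %in% pp$manifest$badChannels)
  expect_gt(pp$manifest$counts$badSegments, 0)
  expect_gt(pp$manifest$counts$segmentDroppedEpochs, 0)
  expect_equal(pp$manifest$counts$keptEpochs +
                 pp$manifest$counts$segmentDroppedEpochs +
                 pp$manifest$counts$rejectedEpochs +
                 pp$manifest$counts$edgeDroppedEpochs, 20)
})

test_that("preprocessing config validates its frequencies", {
  expect_error(preprocConfig(finalLowpass = 300), "below")
})
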