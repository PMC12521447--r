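test_that("averaging by intensity: identical epochs, keep flags, counts", {
  m <- matrix(rep(sin(seq(0, 2 * pi, length.out = 40)), 10), 10,
              byrow = TRUE)
  es <- toyEpochs(m, intensity = rep(c(55, 95), each = 5))
  wf <- averageByIntensity(es)
  expect_equal(unname(wf$nEpochs), c(5, 5))
  expect_equal(wf$amplitude["55", ], m[1, ])
  # excluded epochs do not contribute
  es@keep[1:3] <- FALSE
  wf2 <- averageByIntensity(es)
  expect_equal(unname(wf2$nEpochs), c(2, 5))
  expect_error(averageByIntensity(es, "Fp1"), "not present")
})

test_that("average converges to the signal as 1/sqrt(n)", {
  set.seed(10)
  sig <- 3 * sin(seq(0, 2 * pi, length.out = 60))
  mk <- function(n) {
    m <- matrix(rep(sig, n), n, byrow = TRUE) + rnorm(n * 60, sd = 4)
    averageByIntensity(toyEpochs(m))$amplitude[1, ]
  }
  rmse <- function(a) sqrt(mean((a - sig)^2))
  e10 <- rmse(mk(10)); e1000 <- rmse(mk(1000))
  expect_lt(e1000, e10 / 5)          # ~ sqrt(100) = 10 expected
  expect_lt(e1000, 4 / sqrt(1000) * 2)
})

test_that("peak detection: construction, windows, tie rules", {
  t <- seq(-0.1, 0.5, by = 1 / 2048)
  w <- -3 * exp(-(t - 0.1)^2 / (2 * 0.015^2))
  pk <- detectPeak(t, w, "N1")
  expect_equal(pk$amplitude_uv, -3, tolerance = 1e-4)
  expect_lt(abs(pk$latency_s - 0.1), 1 / 2048)
  # flat zero waveform: amplitude 0, latency = window start
  pk0 <- detectPeak(t, numeric(length(t)), "N1")
  expect_equal(pk0$amplitude_uv, 0)
  expect_equal(pk0$latency_s, min(t[t >= 0.06]))
  # two equal minima at 90 and 120 ms: earliest wins
  w2 <- numeric(length(t))
  w2[which.min(abs(t - 0.09))] <- -2
  w2[which.min(abs(t - 0.12))] <- -2
  expect_lt(abs(detectPeak(t, w2, "N1")$latency_s - 0.09), 1 / 2048)
  # P2 is a maximum in 150-250 ms
  w3 <- 4 * exp(-(t - 0.18)^2 / (2 * 0.025^2))
  expect_equal(detectPeak(t, w3, "P2")$amplitude_uv, 4, tolerance = 1e-4)
  expect_error(detectPeak(seq(0, 0.1, by = 1 / 512), w[1:52], "P2"),
               "outside")
})

test_that("LDAEP slopes: exact lines, flat response, hand-computed OLS", {
  ints <- c(55, 65, 75, 85, 95)
  r <- computeLdaep(n1 = -(2:6), p2 = c(0, 2, 4, 6, 8) - (2:6) * 0,
                    intensities = ints)
  # N1P2 {2,4,6,8,10} built from p2 - n1
  r2 <- computeLdaep(n1 = numeric(5), p2 = c(2, 4, 6, 8, 10),
                     intensities = ints)
  expect_equal(unname(slopes(r2)["n1p2"]), 0.2)
  # constant amplitudes give zero slope
  r3 <- computeLdaep(n1 = rep(-3, 5), p2 = rep(4, 5), intensities = ints)
  expect_equal(unname(slopes(r3)), c(0, 0, 0))
  # hand OLS: {3,2,6,7,9} -> 0.17
  r4 <- computeLdaep(n1 = numeric(5), p2 = c(3, 2, 6, 7, 9),
                     intensities = ints)
  expect_equal(unname(slopes(r4)["p2"]), 0.17)
  expect_equal(unname(r4@r2["p2"]),
               1 - sum(lm(c(3, 2, 6, 7, 9) ~ ints)$residuals^2) /
                 sum((c(3, 2, 6, 7, 9) - 5.4)^2))
})

test_that("N1P2 slope identity and the normal-equations oracle hold", {
  set.seed(11)
  ints <- c(55, 65, 75, 85, 95)
  for (i in 1:25) {
    n1 <- -runif(1, 2, 6) - runif(1, 0, 0.15) * (ints - 75) + rnorm(5)
    p2 <- runif(1, 2, 6) + runif(1, 0, 0.15) * (ints - 75) + rnorm(5)
    r <- computeLdaep(n1, p2, ints)
    s <- slopes(r)
    expect_equal(unname(s["n1p2"]), unname(s["p2"] - s["n1"]),
                 tolerance = 1e-12)
    expect_equal(unname(s["n1"]), unname(oracleOls(ints, n1)["slope"]),
                 tolerance = 1e-10)
    expect_equal(unname(s["p2"]), unname(oracleOls(ints, p2)["slope"]),
                 tolerance = 1e-10)
  }
})

test_that("subjects with missing design points are flagged", {
  r <- computeLdaep(n1 = c(-2, NA, NA, NA, NA), p2 = c(2, NA, NA, NA, NA),
                    intensities = c(55, 65, 75, 85, 95))
  expect_true(r@flagged)
  expect_true(all(is.na(slopes(r))))
  es <- toyEpochs(matrix(rnorm(5 * 320), 5), intensity = rep(55, 5))
  r2 <- ldaepFromEpochs(es)   # single intensity -> flagged
  expect_true(r2@flagged)
})

test_that("noiseless subjects are recovered through the full chain", {
  # measurement transfer bias of the filter chain is ~<= 4% of the slope;
  # 0.01 uV/dB bounds it comfortably for physiological slope magnitudes
  for (sl in list(c(-0.08, 0.12), c(-0.05, 0.08))) {
    rec <- cleanRecording(trials = 2, fs = 2048, n1Slope = sl[1],
                          p2Slope = sl[2])
    pp <- preprocess(rec, subjectIdLabel = "clean")
    s <- slopes(ldaepFromEpochs(pp$epochs))
    expect_lt(abs(s["n1"] - sl[1]), 0.01)
    expect_lt(abs(s["p2"] - sl[2]), 0.01)
    expect_lt(abs(s["n1p2"] - (sl[2] - sl[1])), 0.015)
  }
})

test_that("slope error shrinks with the number of trials", {
  maeAt <- function(tr) {
    errs <- sapply(1:4, function(k) {
      prof <- subjectProfile(noiseSigmaUv = 6, blinkRateHz = 0,
                             lineAmpUv = 0)
      ev <- generateParadigm(paradigmSpec(trialsPerIntensity = tr,
                                          seed = 14 + k))
      rec <- simulateRecording(prof, ev, fs = 1024, seed = 14 + k)
      s <- slopes(ldaepFromEpochs(preprocess(rec)$epochs))
      mean(abs(s - c(-0.08, 0.12, 0.20)))
    })
    mean(errs)
  }
  expect_lt(maeAt(32), maeAt(2))
})

test_that("ldaepTable collects one row per subject", {
  rs <- list(computeLdaep(-(1:5), 1:5, c(55, 65, 75, 85, 95),
                          subjectIdLabel = "a"),
             computeLdaep(-(1:5), 2 * (1:5), c(55, 65, 75, 85, 95),
                          subjectIdLabel = "b"))
  tab <- ldaepTable(rs)
  expect_equal(tab$subject_id, c("a", "b"))
  expect_equal(tab$n1p2_slope, tab$p2_slope - tab$n1_slope)
})
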