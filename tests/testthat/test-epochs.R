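test_that("amplitude rejection matches a brute-force recount", {
  z <- epochsFromArray(matrix(0, 5, 100))
  expect_equal(rejectAmplitude(z, 100)$rejectedFraction, 0)

  a <- array(rnorm(10 * 2 * 50, sd = 1), c(10, 2, 50))
  a[4, 2, 30] <- a[4, 2, 29] + 120           # constructed exceedance
  es <- epochsFromArray(a)
  res <- rejectAmplitude(es, 100)
  expect_equal(nTrials(res$epochs), 9)

  set.seed(5)
  a <- array(rnorm(100 * 8 * 400, sd = 15), c(100, 8, 400))
  es <- epochsFromArray(a)
  res <- rejectAmplitude(es, 100)
  expect_gt(res$rejectedFraction, 0)
  expect_lt(res$rejectedFraction, 1)
  manual <- mean(vapply(1:100, function(k)
    any(apply(a[k, , ], 1, function(v) max(v) - min(v)) >= 100),
    logical(1)))
  expect_equal(res$rejectedFraction, manual)
  expect_warning(rejectAmplitude(es, 1e-9), "all")
})

test_that("epoch-count equalization subsamples reproducibly", {
  a <- epochsFromArray(matrix(rnorm(100 * 10), 100, 10))
  b <- epochsFromArray(matrix(rnorm(70 * 10), 70, 10))
  expect_identical(equalizeEpochCounts(a, a), a)
  e1 <- equalizeEpochCounts(a, b, seed = 2)
  expect_equal(nTrials(e1), 70)
  e2 <- equalizeEpochCounts(a, b, seed = 2)
  expect_identical(epochData(e1), epochData(e2))
  # retained trials are an ordered subset of the originals
  expect_true(all(apply(epochData(e1), 1, paste, collapse = ",") %in%
                    apply(epochData(a), 1, paste, collapse = ",")))
  expect_error(equalizeEpochCounts(b, a), "swap")
})

test_that("pairing and differencing is a seeded bijection with 50-80 sign", {
  m <- matrix(rnorm(12 * 30), 12, 30)
  s50 <- epochsFromArray(m, condition = "nonpredictive_50")
  s80 <- epochsFromArray(m, condition = "predictive_80")
  # identical trial-for-trial sets: pairs mapping a trial to itself are zero
  d0 <- pairAndDifference(s50, s50, seed = 1)
  pm <- pairMap(d0)
  same <- pm[, 1] == pm[, 2]
  expect_true(all(abs(epochData(d0)[same, , ]) < 1e-15))

  z <- epochsFromArray(matrix(0, 12, 30))
  dz <- pairAndDifference(s50, z, seed = 2)
  expect_equal(epochData(dz)[, 1, ], epochData(s50)[pairMap(dz)[, 1], 1, ])

  # linearity: the mean difference equals mean(50) - mean(80) per pairing
  s80b <- epochsFromArray(matrix(rnorm(12 * 30), 12, 30))
  for (s in c(3, 4, 5)) {
    dd <- pairAndDifference(s50, s80b, seed = s)
    expect_equal(mean(epochData(dd)),
                 mean(epochData(s50)) - mean(epochData(s80b)),
                 tolerance = 1e-12)
    # each source trial used exactly once
    expect_setequal(pairMap(dd)[, 2], 1:12)
  }
  expect_error(pairAndDifference(s50, epochsFromArray(matrix(0, 5, 30))),
               "equal trial counts")
})

test_that("window extraction does exact half-open sample arithmetic", {
  a <- array(rnorm(2 * 3 * 5000), c(2, 3, 5000))
  es <- EpochSet(a, fsHz = 1000, t0Ms = -500)
  w <- extractWindow(es, 900, 1300)
  expect_equal(nSamples(w), 400)
  expect_equal(epochStartMs(w), 900)
  expect_identical(epochData(w), a[, , 1401:1800, drop = FALSE])
  w2 <- extractWindow(es, 1400, 1800)
  expect_identical(epochData(w2), a[, , 1901:2300, drop = FALSE])
  idf <- extractWindow(es, -500, 4500)
  expect_identical(epochData(idf), a)
  expect_error(extractWindow(es, 4000, 5000), "span")
  expect_error(extractWindow(es, 300, 300))
})

test_that("zero-phase filtering attenuates and preserves the right bands", {
  fs <- 1000; t <- (0:3999) / fs
  # DC rejection of a constant trace exceeds 40 dB
  hp <- highpassEpochs(epochFromVector(rep(5, 2000)), 2.5)
  expect_lt(max(abs(epochData(hp))) / 5, 10^(-40 / 20))
  # passband amplitude preserved within 5%
  hp10 <- highpassEpochs(epochFromVector(sin(2 * pi * 10 * t)), 2.5)
  expect_lt(abs(fftAmplitude(hp10, 10) - 1), 0.05)
  # 1 Hz component of a 1 + 10 Hz mixture suppressed below 0.1
  mix <- highpassEpochs(
    epochFromVector(sin(2 * pi * 1 * t) + sin(2 * pi * 10 * t)), 2.5)
  expect_lt(fftAmplitude(mix, 1), 0.1)
  expect_lt(abs(fftAmplitude(mix, 10) - 1), 0.05)
  expect_error(highpassEpochs(epochFromVector(rnorm(100), fs = 100), 60),
               "Nyquist")
  # output length and metadata preserved
  expect_equal(nSamples(hp10), 4000)
  expect_equal(epochStartMs(hp10), 0)
})

test_that("epoch container round-trips losslessly at float32", {
  a <- array(rnorm(3 * 2 * 40), c(3, 2, 40))
  es <- EpochSet(a, fsHz = 500, t0Ms = -100, regionLabels = c("A1", "M1"),
                 condition = c("predictive_80", "nonpredictive_50",
                               "predictive_80"),
                 participantId = 7L)
  base <- file.path(tempdir(), "epochs_rt")
  writeEpochSet(es, base)
  back <- readEpochSet(base)
  expect_equal(epochData(back), a, tolerance = 1e-6)
  # a second round trip through float32 is exactly lossless
  writeEpochSet(back, base)
  again <- readEpochSet(base)
  expect_identical(epochData(again), epochData(back))
  expect_identical(regionLabels(back), c("A1", "M1"))
  expect_identical(conditions(back), conditions(es))
  expect_equal(samplingRate(back), 500)
  expect_equal(epochStartMs(back), -100)
  expect_identical(participantId(back), 7L)
  # text fallback
  writeEpochSet(es, base, format = "tsv")
  backTsv <- readEpochSet(base)
  expect_equal(epochData(backTsv), a, tolerance = 1e-12)
})
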