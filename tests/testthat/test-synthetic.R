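test_that("trial sequence honors the printed design counts", {
  tt <- simulateTrialSequence(1, 3, 50, seed = 1)
  expect_equal(nrow(tt), 300)
  expect_equal(unname(table(tt$condition)["predictive_80"]), 150,
               ignore_attr = TRUE)
  expect_equal(unname(table(tt$condition)["nonpredictive_50"]), 150,
               ignore_attr = TRUE)
  expect_true(all(tt$cue_target_interval_ms %in% c(1200, 2400)))
  expect_true(all((tt$target_latency == "early") ==
                    (tt$cue_target_interval_ms == 1200)))
  expect_true(all(tt$iti_ms >= 200 & tt$iti_ms <= 1000))
  expect_true(all(tt$cue_duration_ms == 100))
})

test_that("degenerate and sampled early-target probabilities behave", {
  tt <- simulateTrialSequence(1, 2, 10, pEarlyPredictive = 1, seed = 2)
  pred <- tt[tt$condition == "predictive_80", ]
  expect_true(all(pred$target_latency == "early"))

  tt <- simulateTrialSequence(1, 40, 50, seed = 7)
  pred <- tt[tt$condition == "predictive_80", ]
  frac <- mean(pred$target_latency == "early")
  se <- sqrt(0.8 * 0.2 / nrow(pred))
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("trial simulation is deterministic and validates inputs", {
  expect_identical(simulateTrialSequence(2, 2, 5, seed = 9),
                   simulateTrialSequence(2, 2, 5, seed = 9))
  expect_error(simulateTrialSequence(1, 1, 10, pEarlyPredictive = 1.2),
               "probability")
  expect_error(simulateTrialSequence(0, 1, 10), "integer")
})

test_that("VAR generator reproduces the planted lag-1 cross-covariance", {
  # y_t = 0.5 x_{t-1} + noise  =>  cov(y_t, x_{t-1}) = 0.5
  spec <- chainSpec(2, self = 0, pairs = cbind(2L, 1L), weight = 0.5)
  tt <- quickTrials(10, conditions = "nonpredictive_50")
  es <- generateVarEpochs(spec, tt, c(0, 2000), seed = 3)
  d <- epochData(es)
  cc <- mean(vapply(seq_len(nTrials(es)), function(k) {
    x <- d[k, 1, ]; y <- d[k, 2, ]
    mean((y[-1] - mean(y)) * (x[-length(x)] - mean(x)))
  }, numeric(1)))
  expect_lt(abs(cc - 0.5), 0.05)
})

test_that("VAR epochs have the contracted shape and are seeded", {
  spec <- chainSpec(62, self = 0.3)
  tt <- quickTrials(10)  # 2 conditions x 10
  es <- generateVarEpochs(spec, tt, c(0, 400), seed = 5)
  expect_identical(dim(epochData(es)), c(20L, 62L, 400L))
  es2 <- generateVarEpochs(spec, tt, c(0, 400), seed = 5)
  expect_identical(epochData(es), epochData(es2))
})

test_that("non-stationary coupling specs are rejected with the radius", {
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 1.05; A[2, 2, 1] <- 0.2
  expect_error(groundTruthSpec(2, baseCoupling = A), "spectral radius")
  expect_error(groundTruthSpec(2, baseCoupling = A), "1.05")
})

test_that("null condition delta leaves the two conditions exchangeable", {
  # zero delta: identical coefficient arrays drive both conditions, and
  # across replicates the between-condition variance test is calibrated
  spec <- chainSpec(2, self = 0.4)
  tt <- quickTrials(15)
  trialVar <- function(d) apply(d, 1, function(m) var(as.vector(m)))
  ps <- vapply(1:20, function(s) {
    es <- generateVarEpochs(spec, tt, c(0, 300), seed = 110 + s)
    d <- epochData(es)
    v50 <- trialVar(d[conditions(es) == "nonpredictive_50", , , drop = FALSE])
    v80 <- trialVar(d[conditions(es) == "predictive_80", , , drop = FALSE])
    t.test(v50, v80)$p.value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.2)
})

test_that("planted club matrix has the promised block structure", {
  M <- plantRichClub(10, 1:3, inWeight = 5, outWeight = 1, background = 1)
  expect_true(all(diag(M) == 0))
  expect_true(all(M[1:3, ][M[1:3, ] != 0] == 5))           # into/within club
  expect_true(all(M[4:10, 1:3] == 1))                      # club -> outside
  expect_true(all(M[4:10, 4:10][diag(7) == 0] == 1))       # background
  expect_error(plantRichClub(5, 1:5, 5, 1, 1), "proper subset")
  expect_error(plantRichClub(10, 1:3, 1, 0.5, 2), "inWeight > background")
})

test_that("reaction times follow the additive model and truncation", {
  tt <- simulateTrialSequence(6, 1, 4, seed = 1)
  # near-degenerate noise: every RT equals its condition mean
  rt <- generateRtTable(tt, 330, 360, withinSd = 1e-9, betweenSd = 1e-9,
                        seed = 2)
  expect_true(all(abs(rt$rt_ms[rt$condition == "predictive_80"] - 330) <
                    1e-6))
  expect_true(all(abs(rt$rt_ms[rt$condition == "nonpredictive_50"] - 360) <
                    1e-6))
  # equal means: per-participant differences centered on zero
  diffs <- replicate(40, {
    r <- generateRtTable(tt, 340, 340, 30, 10,
                         seed = sample.int(1e6, 1))
    mean(rtConditionDifference(r, cutoffMs = 1e5, earlyOnly = FALSE))
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 2)
  expect_true(all(generateRtTable(tt, 60, 60, 400, 1, seed = 3)$rt_ms >= 50))
})

test_that("paired RT effect size lands in the plausible range", {
  # 20 participants, 2 trials per condition: expected paired d
  # = 30 / (40 * sqrt(2/2)) = 0.75
  tt <- simulateTrialSequence(20, 1, 2, seed = 4)
  ds <- replicate(60, {
    r <- generateRtTable(tt, 330, 360, 40, 20, seed = sample.int(1e6, 1))
    dd <- rtConditionDifference(r, cutoffMs = 1e5, earlyOnly = FALSE)
    mean(dd) / sd(dd)
  })
  expect_gt(mean(ds), 0.4)
  expect_lt(mean(ds), 1.2)
})

test_that("phase-locked epochs produce the derived phase concentration", {
  # zero jitter, no noise: all trials identical
  es <- generatePhaseLockedEpochs(5, 250, 8, 0, seed = 1)
  d <- epochData(es)
  expect_true(all(apply(d, 3, function(v) diff(range(v))) < 1e-12))
  expect_error(generatePhaseLockedEpochs(5, 100, 60, 0), "alias")
  # wrapped Gaussian, sd 0.5: |E exp(i phi)| = exp(-sd^2/2) ~ 0.8825
  es <- generatePhaseLockedEpochs(500, 250, 8, 0.5, noiseSd = 0.05,
                                  seed = 6)
  it <- morletItpc(es, 4, 16, 7)
  fidx <- which.min(abs(as.numeric(dimnames(it)[[2]]) - 8))
  mid <- it[1, fidx, ]
  expect_lt(abs(mean(mid, na.rm = TRUE) - exp(-0.125)), 0.05)
  # uniform phases: ITPC near zero at large n
  esu <- generatePhaseLockedEpochs(500, 250, 8, 1, uniformPhase = TRUE,
                                   noiseSd = 0.05, seed = 7)
  itu <- morletItpc(esu, 4, 16, 7)
  expect_lt(mean(itu[1, fidx, ], na.rm = TRUE), 0.1)
})
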