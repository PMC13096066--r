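test_that("circular shifts preserve values and the amplitude spectrum", {
  x <- rnorm(64)
  expect_identical(circularShift(x, offset = 0), x)
  s <- circularShift(x, seed = 5)
  expect_identical(sort(s), sort(x))
  expect_false(identical(s, x))
  expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-10)
  # seeded offsets stay away from the ends
  for (k in 1:20) {
    s2 <- circularShift(x, seed = k)
    off <- which(s2[1] == x)[1] # recover the rotation
    expect_true(is.finite(off))
  }
  expect_error(circularShift(1:3), "length")
})

test_that("shifting the source destroys directed coupling", {
  set.seed(12)
  n <- 400
  x <- rnorm(n); y <- 0.6 * c(0, x[-n]) + 0.3 * rnorm(n)
  obs <- ndtePair(x, y, 1)
  surr <- vapply(1:100, function(k)
    ndtePair(circularShift(x, seed = k), y, 1), numeric(1))
  expect_lt(mean(surr), obs)
})

test_that("surrogate p-values follow the add-one rule and null uniformity", {
  set.seed(2)
  n <- 400
  x <- rnorm(n); y <- 0.8 * c(0, x[-n]) + 0.2 * rnorm(n)
  m <- rbind(x, y); rownames(m) <- c("x", "y")
  sp <- surrogatePvalues(m, 1L, 100L, seed = 3)
  expect_equal(sp$pTrial["y", "x"], 1 / 101)   # beats every surrogate
  expect_true(all(sp$pTrial[row(sp$pTrial) != col(sp$pTrial)] >= 1 / 101))
  expect_true(all(sp$pTrial[row(sp$pTrial) != col(sp$pTrial)] <= 1))
  expect_true(all(sp$surrogateSd[row(sp$pTrial) != col(sp$pTrial)] >= 0))
  expect_error(surrogatePvalues(m, 1L, 10L), ">= 19")
})

test_that("Stouffer combination matches the normal-CDF oracle", {
  expect_equal(stoufferCombine(0.3), 0.3, tolerance = 1e-12)
  expect_equal(stoufferCombine(rep(0.5, 7)), 0.5, tolerance = 1e-12)
  oracle <- pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE)
  expect_equal(stoufferCombine(c(0.05, 0.05)), oracle, tolerance = 1e-12)
  expect_equal(round(stoufferCombine(c(0.05, 0.05)), 4), 0.0100)
  expect_warning(stoufferCombine(c(0.5, 1)), "clipped")
  # permutation invariance and monotonicity
  set.seed(6)
  for (k in 1:20) {
    p <- runif(5, 0.01, 0.99)
    expect_equal(stoufferCombine(p), stoufferCombine(sample(p)),
                 tolerance = 1e-12)
    p2 <- p; p2[3] <- p2[3] * 0.5
    expect_lte(stoufferCombine(p2), stoufferCombine(p))
  }
})

test_that("BH step-up rejects the hand-computed sets", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bhFdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_true(bhFdr(0.04, 0.05))
  expect_false(bhFdr(0.06, 0.05))
  expect_identical(bhFdr(numeric(0), 0.05), logical(0))
  # step-up: a large p can be rescued by smaller ones below the line
  expect_equal(bhFdr(c(0.001, 0.024, 0.04), 0.05), c(TRUE, TRUE, TRUE))
})

test_that("standardization yields zero z when flows equal surrogate mean", {
  R <- 3
  labs <- paste0("R", 1:R)
  mk <- function(p) {
    F <- matrix(0.4, R, R, dimnames = list(labs, labs)); diag(F) <- 0
    list(flow = new("FlowMatrix", flow = F,
                    lag = new("ModelOrder", lagSamples = 1L, lagMs = 1,
                              perUnitLags = 1)),
         pTrial = matrix(p, R, R, dimnames = list(labs, labs)),
         surrogateMean = matrix(0.4, R, R, dimnames = list(labs, labs)),
         surrogateSd = matrix(0.1, R, R, dimnames = list(labs, labs)),
         nSurrogates = 50L)
  }
  parts <- list(list(mk(0.005), mk(0.005)), list(mk(0.005), mk(0.005)))
  nd <- standardizeAndMask(parts, q = 0.5)
  expect_true(any(significanceMask(nd)))
  expect_true(all(abs(flows(nd)[significanceMask(nd)]) < 1e-12))
  expect_true(all(is.na(flows(nd)[!significanceMask(nd)])))
})

test_that("planted directed coupling is masked and its reverse is not", {
  spec <- chainSpec(3, self = 0.5, pairs = cbind(2L, 1L), weight = 0.5,
                    effectWindowMs = c(0, 400), delta = TRUE)
  parts <- lapply(1:4, function(pi) {
    es <- generateVarEpochs(spec, quickTrials(8, participant = pi),
                            c(0, 400), seed = 50 + pi)
    s50 <- es[conditions(es) == "nonpredictive_50"]
    s80 <- es[conditions(es) == "predictive_80"]
    dif <- pairAndDifference(s50, s80, seed = 60 + pi)
    lapply(seq_len(nTrials(dif)), function(k)
      suppressWarnings(
        surrogatePvalues(dif, 1L, 30L, trial = k, seed = 70 * pi + k)))
  })
  nd <- suppressWarnings(standardizeAndMask(parts, q = 0.05))
  expect_true(significanceMask(nd)["R2", "R1"])
  expect_false(significanceMask(nd)["R1", "R2"])
  # the shared mask gates every participant's flows identically
  Zp <- participantFlows(nd)
  for (pi in 1:4)
    expect_identical(is.na(Zp[pi, , ]), unname(!significanceMask(nd)))
})
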