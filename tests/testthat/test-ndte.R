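test_that("model order finds the first autocorrelation minimum", {
  co <- epochFromVector(cos(2 * pi * (0:399) / 100))
  expect_lte(abs(lagSamples(estimateModelOrder(co, 60)) - 50), 1)

  td <- 0:799
  damped <- exp(-td / 200) * cos(2 * pi * td / 60)
  expect_lte(abs(lagSamples(estimateModelOrder(epochFromVector(damped),
                                               50)) - 30), 1)

  # white noise: equals an independent brute-force ACF scan
  set.seed(9)
  v <- rnorm(400)
  got <- lagSamples(estimateModelOrder(epochFromVector(v), 50))
  xc <- v - mean(v)
  acfU <- vapply(1:50, function(tau)
    sum(xc[1:(400 - tau)] * xc[(tau + 1):400]) /
      ((400 - tau) * mean(xc^2)), numeric(1))
  oracle <- NA
  for (tau in 1:49) if (acfU[tau] < acfU[tau + 1]) { oracle <- tau; break }
  expect_equal(got, oracle)

  expect_error(estimateModelOrder(epochFromVector(rep(1, 100)), 20),
               "constant")
  expect_error(estimateModelOrder(epochFromVector(rnorm(40)), 30),
               "half")
})

test_that("Gaussian entropy matches hand-evaluated covariances", {
  h1 <- 0.5 * log(2 * pi * exp(1))
  expect_equal(gaussianEntropy(matrix(1)), h1, tolerance = 1e-9)
  expect_equal(gaussianEntropy(diag(2)), 2 * h1, tolerance = 1e-9)
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(gaussianEntropy(S), 2 * h1 + 0.5 * log(0.64),
               tolerance = 1e-9)
  expect_error(gaussianEntropy(matrix(1:6, 2)), "square")
})

test_that("Gaussian MI estimate is accurate for a known correlation", {
  set.seed(10)
  n <- 50000; rho <- 0.8
  z <- matrix(rnorm(2 * n), ncol = 2)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  S <- stats::cov(z)
  mi <- gaussianEntropy(S[1, 1, drop = FALSE]) +
    gaussianEntropy(S[2, 2, drop = FALSE]) - gaussianEntropy(S)
  expect_lt(abs(mi - (-0.5 * log(1 - rho^2))) / (-0.5 * log(1 - rho^2)),
            0.02)
})

test_that("NDTE recovers the VAR(1) closed-form flow", {
  # y_t = 0.5 x_{t-1} + 0.5 y_{t-1} + e: F = log(1.25)/log(5/3)
  set.seed(21)
  n <- 20000
  x <- rnorm(n + 1); y <- numeric(n + 1)
  for (t in 2:(n + 1)) y[t] <- 0.5 * x[t - 1] + 0.5 * y[t - 1] + rnorm(1)
  expect_lt(abs(ndtePair(x[-1], y[-1], 1) - log(1.25) / log(5 / 3)), 0.05)
})

test_that("NDTE saturates for a noiseless copy and is scale invariant", {
  set.seed(3)
  x <- rnorm(500)
  y <- c(0, x[-500])  # y is x delayed by one sample
  expect_gt(ndtePair(x, y, 1), 0.999)
  # invariance under separate affine rescaling of source and target
  a <- rnorm(400); b <- 0.4 * c(0, a[-400]) + rnorm(400)
  f0 <- ndtePair(a, b, 2)
  f1 <- ndtePair(5 * a - 3, -0.2 * b + 7, 2)
  expect_equal(f0, f1, tolerance = 1e-7)
  expect_error(ndtePair(rnorm(10), rnorm(10), 4), "exceed")
})

test_that("uncoupled series stay below their own surrogate criterion", {
  set.seed(14)
  below <- vapply(1:100, function(k) {
    m <- rbind(rnorm(300), rnorm(300))
    rownames(m) <- c("a", "b")
    sp <- surrogatePvalues(m, 1L, 19L, seed = k)
    sp$pTrial[2, 1] > 0.05
  }, logical(1))
  expect_gte(mean(below), 0.9)
})

test_that("NDTE equals a brute-force four-entropy evaluation", {
  set.seed(8)
  for (rep in 1:10) {
    lag <- sample(1:3, 1)
    n <- 60
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    # independent oracle: explicit embedding, 1/m covariance, determinant
    m <- n - lag
    idx <- (lag + 1):n
    E <- cbind(y[idx],
               vapply(1:lag, function(k) y[idx - k], numeric(m)),
               vapply(1:lag, function(k) x[idx - k], numeric(m)))
    E <- sweep(E, 2, colMeans(E))
    S <- crossprod(E) / m
    ld <- function(ii) {           # includes the documented jitter floor
      S2 <- S[ii, ii, drop = FALSE]
      log(det(S2 + diag(1e-10 * mean(diag(S2)), nrow(S2))))
    }
    f <- 1; yp <- 1 + (1:lag); xp <- 1 + lag + (1:lag)
    num <- 0.5 * (ld(c(f, yp)) - ld(yp) - ld(seq_len(2 * lag + 1)) +
                    ld(c(yp, xp)))
    den <- 0.5 * (ld(f) + ld(c(yp, xp)) - ld(seq_len(2 * lag + 1)))
    oracle <- min(1, max(0, num / den))
    expect_equal(ndtePair(x, y, lag), oracle, tolerance = 1e-10)
  }
})

test_that("flow matrices follow the j-to-i orientation and relabeling", {
  set.seed(4)
  m <- rbind(rnorm(200), rnorm(200))
  m[2, ] <- m[2, ] + 0.5 * c(0, m[1, -200])
  rownames(m) <- c("src", "tgt")
  fm <- flows(ndteMatrix(m, 1))
  expect_equal(fm["tgt", "src"], ndtePair(m["src", ], m["tgt", ], 1))
  expect_equal(fm["src", "tgt"], ndtePair(m["tgt", ], m["src", ], 1))
  expect_true(all(diag(fm) == 0))
  # permuting regions permutes rows and columns consistently
  m3 <- rbind(m, extra = rnorm(200))
  f3 <- flows(ndteMatrix(m3, 1))
  perm <- c(3, 1, 2)
  fp <- flows(ndteMatrix(m3[perm, ], 1))
  expect_equal(fp, f3[perm, perm], tolerance = 1e-12)
})

test_that("a planted causal chain carries more flow than unplanted pairs", {
  spec <- chainSpec(5, self = 0.3,
                    pairs = rbind(c(2L, 1L), c(3L, 2L)), weight = 0.5)
  tt <- quickTrials(25, conditions = "nonpredictive_50")
  es <- generateVarEpochs(spec, tt, c(0, 300), seed = 16)
  fl <- lapply(seq_len(nTrials(es)), function(k)
    flows(ndteMatrix(es, 1, trial = k)))
  avg <- Reduce(`+`, fl) / length(fl)
  planted <- c(avg[2, 1], avg[3, 2])
  off <- avg[row(avg) != col(avg)]
  unplanted <- setdiff(off, planted)
  expect_gt(min(planted), mean(unplanted))
})
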