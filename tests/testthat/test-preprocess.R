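test_that("morletDecompose recovers amplitude and phase of a pure cosine", {
  f0 <- 10; phi0 <- 0.6
  es <- makeEpochSet(nEpochs = 2L, fs = 250, window = c(-1, 2),
                     channels = "RATN",
                     signal = function(t, e, ch) 3 * cos(2 * pi * f0 * t +
                                                           phi0))
  tf <- morletDecompose(es, "RATN", freqs = c(8, 10, 12), nCycles = 5)
  fi <- which(tfFreqs(tf) == f0)
  ti <- thetaPLF:::closedIndices(tfTimes(tf), c(-0.3, 1.3))
  expect_equal(unname(tfAmplitude(tf)[1L, fi, ti]),
               rep(3, length(ti)), tolerance = 1e-3)
  want <- thetaPLF:::wrapPhase(2 * pi * f0 * tfTimes(tf)[ti] + phi0)
  got  <- tfPhase(tf)[1L, fi, ti]
  expect_lt(max(abs(thetaPLF:::wrapPhase(got - want))), 1e-3)
  # off-frequency response is attenuated
  expect_lt(max(tfAmplitude(tf)[1L, which(tfFreqs(tf) == 12), ti]), 3)
})

test_that("decomposition is linear in the input gain", {
  sig <- function(t, e, ch) cos(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 15 * t)
  es1 <- makeEpochSet(nEpochs = 2L, channels = "RATN", signal = sig,
                      window = c(-1, 1.5))
  es4 <- makeEpochSet(nEpochs = 2L, channels = "RATN",
                      signal = function(t, e, ch) 4 * sig(t, e, ch),
                      window = c(-1, 1.5))
  tf1 <- morletDecompose(es1, "RATN", freqs = c(6, 15))
  tf4 <- morletDecompose(es4, "RATN", freqs = c(6, 15))
  expect_equal(tfAmplitude(tf4), 4 * tfAmplitude(tf1), tolerance = 1e-9)
  expect_equal(tfPhase(tf4), tfPhase(tf1), tolerance = 1e-9)
})

test_that("edge trimming removes half the longest wavelet on both sides", {
  es <- makeEpochSet(nEpochs = 2L, fs = 250, window = c(-1, 2),
                     channels = "RATN",
                     signal = function(t, e, ch) sin(2 * pi * 5 * t))
  tf <- morletDecompose(es, "RATN", freqs = c(4, 10), nCycles = 5)
  sigma <- 5 / (2 * pi * 4)                     # slowest wavelet
  half  <- ceiling(3 * sigma * 250) / 250
  expect_gte(min(tfTimes(tf)), -1 + half - 1e-9)
  expect_lte(max(tfTimes(tf)), 2 - half + 1e-9)
  expect_equal(mean(diff(tfTimes(tf))), 1 / 250, tolerance = 1e-12)
})

test_that("time decimation subsamples the retained axis", {
  es <- makeEpochSet(nEpochs = 2L, channels = "RATN",
                     signal = function(t, e, ch) sin(2 * pi * 8 * t))
  tf1 <- morletDecompose(es, "RATN", freqs = 8)
  tf3 <- morletDecompose(es, "RATN", freqs = 8, decim = 3L)
  expect_equal(tfTimes(tf3), tfTimes(tf1)[seq(1, length(tfTimes(tf1)),
                                              by = 3)])
  expect_equal(tfAmplitude(tf3)[1L, 1L, ],
               tfAmplitude(tf1)[1L, 1L, seq(1, length(tfTimes(tf1)),
                                            by = 3)])
})

test_that("decomposition input validation", {
  es <- makeEpochSet(nEpochs = 2L, fs = 250, channels = "RATN",
                     signal = function(t, e, ch) sin(2 * pi * 8 * t))
  expect_error(morletDecompose(es, "RATN", freqs = c(10, 130)), "Nyquist")
  expect_error(morletDecompose(es, "RATN", freqs = c(10, 8)), "ascending")
  expect_error(morletDecompose(es, "RATN", freqs = 10, nCycles = 2),
               "nCycles")
  expect_error(morletDecompose(es, "nonexistent", freqs = 10), "channel")
})

test_that("bipolarRereference subtracts the deeper neighbour", {
  a <- matrix(rnorm(20), 4, 5)
  b <- matrix(rnorm(20), 4, 5)
  expect_equal(bipolarRereference(a, b), a - b)
  expect_error(bipolarRereference(a, b[, 1:3]), "equal length")
})

test_that("bandComplexMean averages amp * exp(i phase) over in-band rows", {
  es <- makeEpochSet(nEpochs = 3L, channels = "RATN", noiseSD = 1,
                     signal = function(t, e, ch) sin(2 * pi * 7 * t))
  tf <- morletDecompose(es, "RATN", freqs = 5:9)
  z  <- bandComplexMean(tf, c(6, 8))
  fi <- which(tfFreqs(tf) >= 6 & tfFreqs(tf) <= 8)
  manual <- apply(tfAmplitude(tf)[, fi, , drop = FALSE] *
                    exp(1i * tfPhase(tf)[, fi, , drop = FALSE]),
                  c(1, 3), mean)
  expect_equal(z, manual, tolerance = 1e-12)
})
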