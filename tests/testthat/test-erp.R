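test_that("computeERP baselines, averages, and band-passes", {
  f0 <- 4
  sig <- function(t, e, ch) {
    5 * sin(2 * pi * f0 * t) * (t >= 0) +        # in-band component
      3 * sin(2 * pi * 40 * t) +                 # out-of-band component
      2                                          # DC offset
  }
  es <- makeEpochSet(nEpochs = 8L, fs = 250, window = c(-0.5, 1.5),
                     channels = "frontal", signal = sig, noiseSD = 0.5)
  erp <- computeERP(es, "frontal", "SE")
  expect_s4_class(erp, "ERPWave")
  # baseline window mean is removed
  bi <- thetaPLF:::closedIndices(epochTimes(erp), c(-0.2, 0))
  expect_lt(abs(mean(erpValues(erp)[bi])), 1e-8)
  # the 4 Hz component survives largely intact away from onset transients
  mid <- thetaPLF:::closedIndices(epochTimes(erp), c(0.4, 1.2))
  expect_gt(max(abs(erpValues(erp)[mid])), 3.5)
  # 40 Hz and DC are strongly attenuated: correlate residual with 40 Hz
  t <- epochTimes(erp)[mid]
  proj40 <- 2 * mean(erpValues(erp)[mid] * sin(2 * pi * 40 * t))
  expect_lt(abs(proj40), 0.3)
  expect_error(computeERP(es, "RATN", "SE"), "channel")
  expect_error(computeERP(es, "frontal", "SE",
                          baselineWindow = c(-2, -1.5)), "baseline")
})

test_that("computeERP averages only the requested condition", {
  # odd epochs (condition "UE") carry an inverted 4 Hz burst
  sig <- function(t, e, ch) {
    s <- if (e %% 2L == 0L) 1 else -1          # even epochs are "SE" below
    s * sin(2 * pi * 4 * t) * (t >= 0.2 & t <= 1.2)
  }
  es <- makeEpochSet(nEpochs = 10L, fs = 250, window = c(-0.5, 1.5),
                     channels = "frontal", signal = sig,
                     condition = rep(c("UE", "SE"), 5))
  se <- computeERP(es, "frontal", "SE", filterBand = c(1, 8))
  ue <- computeERP(es, "frontal", "UE", filterBand = c(1, 8))
  mid <- thetaPLF:::closedIndices(epochTimes(se), c(0.4, 1.0))
  t <- epochTimes(se)[mid]
  projSE <- 2 * mean(erpValues(se)[mid] * sin(2 * pi * 4 * t))
  projUE <- 2 * mean(erpValues(ue)[mid] * sin(2 * pi * 4 * t))
  expect_gt(projSE, 0.5)
  expect_lt(projUE, -0.5)
  expect_equal(erpValues(se), -erpValues(ue), tolerance = 1e-9)
})

test_that("erpPeak finds the largest absolute excursion, earliest on ties", {
  es <- makeEpochSet(nEpochs = 2L, fs = 250, window = c(-0.5, 1.5),
                     channels = "frontal",
                     signal = function(t, e, ch)
                       -6 * exp(-(t - 0.4)^2 / (2 * 0.05^2)))
  erp <- computeERP(es, "frontal", "SE", filterBand = c(1, 12))
  pk <- erpPeak(erp, c(0, 1))
  expect_lt(pk$amplitude, -3)           # sign preserved
  expect_equal(pk$latency, 0.4, tolerance = 0.05)
  # tie-break: symmetric double peak returns the earlier one
  v <- erpValues(erp)
  sym <- erp
  ti1 <- which.min(abs(epochTimes(erp) - 0.4))
  ti2 <- which.min(abs(epochTimes(erp) - 0.9))
  v[] <- 0; v[ti1] <- -5; v[ti2] <- -5
  sym@values <- v
  pk2 <- erpPeak(sym, c(0, 1))
  expect_equal(pk2$latency, epochTimes(erp)[ti1])
})

test_that("erpAlignmentCorrelation pools participants and validates input", {
  cfg <- synthConfig(nParticipants = 3L, nTrialsPerCondition = 10L,
                     channelRoles = "frontal", samplingRate = 250,
                     seed = 55L)
  sets <- generateCohort(cfg)$epochSets
  erps <- lapply(sets, computeERP, channel = "frontal", condition = "SE")
  tfs  <- lapply(sets, morletDecompose, channel = "frontal", freqs = 4:12,
                 decim = 3L)
  pais <- lapply(tfs, paiFromTF, condition = "SE")
  cr <- erpAlignmentCorrelation(erps, pais, window = c(0, 0.5),
                                band = c(4, 12))
  expect_s4_class(cr, "CorrelationResult")
  nPts <- length(thetaPLF:::closedIndices(tfTimes(pais[[1L]]), c(0, 0.5)))
  expect_equal(cr@n, 3L * nPts)
  expect_true(cr@r >= -1 && cr@r <= 1)
  expect_error(erpAlignmentCorrelation(erps, pais[1:2], band = c(4, 12)),
               "one PAIMap per ERPWave")
})
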