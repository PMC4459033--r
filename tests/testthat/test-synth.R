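smallCfg <- function(seed = 314L, ...) {
  synthConfig(nParticipants = 3L, nTrialsPerCondition = 5L,
              channelRoles = c("frontal", "RATN"), samplingRate = 250,
              seed = seed, ...)
}

test_that("generateCohort is fully deterministic from the config seed", {
  a <- generateCohort(smallCfg())
  b <- generateCohort(smallCfg())
  expect_identical(a, b)
  c <- generateCohort(smallCfg(seed = 315L))
  expect_false(identical(a$epochSets[[1L]]@data, c$epochSets[[1L]]@data))
})

test_that("cohort shapes, labels and axes are as configured", {
  cfg <- smallCfg()
  out <- generateCohort(cfg)
  expect_length(out$epochSets, 3L)
  es <- out$epochSets[[2L]]
  expect_s4_class(es, "EpochSet")
  expect_equal(dim(epochData(es)), c(10L, 2L, 751L))
  expect_equal(channelRoles(es), c("frontal", "RATN"))
  expect_equal(samplingRate(es), 250)
  expect_equal(range(epochTimes(es)), c(-1, 2))
  expect_equal(as.vector(table(conditions(es))), c(5L, 5L))
  expect_equal(nEpochs(es), 10L)
})

test_that("ground-truth parameters respect their construction", {
  cfg <- synthConfig(nParticipants = 200L, kappaSE = 1.5, kappaUE = 0.2,
                     kappaSpread = 0.3, pacGainMean = 0.5, pacGainSD = 0.15,
                     participantEffectRho = 0.9, seed = 8L)
  p <- drawParticipantParams(cfg)
  expect_equal(nrow(p), 200L)
  expect_true(all(p$kappaSE > 0))
  # the same lognormal multiplier scales both conditions
  expect_equal(p$kappaUE / p$kappaSE, rep(0.2 / 1.5, 200L), tolerance = 1e-12)
  expect_true(all(p$pacGain >= 0 & p$pacGain <= 1))
  # unit-mean multiplier and the latent-factor correlation at large n
  expect_equal(mean(p$kappaSE), 1.5, tolerance = 0.1)
  expect_gt(cor(log(p$kappaSE), p$pacGain), 0.75)
})

test_that("rho = 0 decouples reset strength from coupling gain", {
  cfg <- synthConfig(nParticipants = 400L, participantEffectRho = 0,
                     seed = 9L)
  p <- drawParticipantParams(cfg)
  expect_lt(abs(cor(log(p$kappaSE), p$pacGain)), 0.12)
})

test_that("background noise has the configured scale", {
  cfg <- smallCfg(thetaAmplitude = 0, earlyAmplitude = 0,
                  gammaAmplitude = 0, erpAmplitude = 0, noiseRMS = 10)
  es <- generateCohort(cfg)$epochSets[[1L]]
  expect_equal(sqrt(mean(epochData(es)^2)), 10, tolerance = 0.15)
})

test_that("the SE theta reset is visible in raw phase at the reset latency", {
  cfg <- synthConfig(nParticipants = 1L, nTrialsPerCondition = 60L,
                     channelRoles = "RATN", samplingRate = 250,
                     kappaSE = 8, kappaUE = 0, noiseRMS = 2, seed = 21L)
  out <- generateCohort(cfg)
  es  <- out$epochSets[[1L]]
  tf  <- morletDecompose(es, "RATN", freqs = 6:9, nCycles = 5)
  ti  <- which.min(abs(tfTimes(tf) - 1.0))
  fi  <- which(tfFreqs(tf) == 8)
  r <- function(cond) Mod(mean(exp(1i * tfPhase(tf)[conditions(tf) == cond,
                                                    fi, ti])))
  expect_gt(r("SE"), 0.75)
  expect_lt(r("UE"), 0.45)
})

test_that("synthesizeEpoch is deterministic given the trial seed", {
  cfg <- smallCfg()
  p <- drawParticipantParams(cfg)
  a <- synthesizeEpoch(cfg, p[1L, ], "SE", trialSeed = 42L)
  b <- synthesizeEpoch(cfg, p[1L, ], "SE", trialSeed = 42L)
  expect_identical(a, b)
  expect_equal(dim(a), c(2L, 751L))
  expect_false(identical(a, synthesizeEpoch(cfg, p[1L, ], "SE",
                                            trialSeed = 43L)))
})

test_that("synthConfig validates physical consistency", {
  expect_error(synthConfig(samplingRate = 80), "sampling")
  expect_error(synthConfig(epochWindow = c(0.1, 2)), "straddle")
  expect_error(synthConfig(epochWindow = c(-0.2, 1)), "1.5 s")
  expect_error(synthConfig(participantEffectRho = 1.2), "Rho")
})

test_that("readSynthConfig round-trips YAML and JSON and rejects unknowns", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("nParticipants: 4", "nTrialsPerCondition: 6",
               "samplingRate: 250", "kappaSE: 2.5", "seed: 77"), y)
  cfg <- readSynthConfig(y)
  expect_s4_class(cfg, "SynthConfig")
  expect_equal(cfg@nParticipants, 4L)
  expect_equal(cfg@kappaSE, 2.5)
  expect_equal(cfg@samplingRate, 250)

  j <- tempfile(fileext = ".json")
  writeLines('{"nParticipants": 4, "samplingRate": 250, "kappaSE": 2.5}', j)
  cfgj <- readSynthConfig(j)
  expect_equal(cfgj@kappaSE, 2.5)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("nParticipants: 4", "notAField: 1"), bad)
  expect_error(readSynthConfig(bad), "notAField")
})

test_that("writeGroundTruth emits a readable TSV", {
  p <- drawParticipantParams(smallCfg())
  f <- tempfile(fileext = ".tsv")
  writeGroundTruth(p, f)
  back <- read.delim(f)
  expect_equal(back$kappaSE, p$kappaSE, tolerance = 1e-9)
  expect_equal(back$participantID, p$participantID)
})
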