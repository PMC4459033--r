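test_that("modulationIndex matches analytic worked values", {
  phi <- seq(0, 2 * pi, length.out = 2001)[-1]     # exact full cycles
  expect_equal(modulationIndex(phi, 1 + cos(phi)), 0.5, tolerance = 1e-12)
  # no modulation -> 0
  expect_equal(modulationIndex(phi, rep(2, length(phi))), 0,
               tolerance = 1e-12)
  # modulation aligned to sine is orthogonal in angle, same magnitude
  expect_equal(modulationIndex(phi, 1 + sin(phi)), 0.5, tolerance = 1e-12)
  # gain scales linearly
  expect_equal(modulationIndex(phi, 3 * (1 + cos(phi))), 1.5,
               tolerance = 1e-12)
  expect_error(modulationIndex(phi, 1:3), "equal length")
})

test_that("surrogateMIZscore flags genuine coupling and not its absence", {
  set.seed(12)
  n <- 1500; fs <- 100
  # drifting (aperiodic) phase: circular shifts genuinely destroy coupling
  ph <- thetaPLF:::wrapPhase(2 * pi * 6 * seq_len(n) / fs +
                               cumsum(rnorm(n, 0, 0.25)))
  coupled   <- 1 + 0.6 * cos(ph) + rnorm(n, 0, 0.3)
  uncoupled <- 1 + rnorm(n, 0, 0.3)
  zc <- surrogateMIZscore(ph, coupled, 200L, minShift = 0.5,
                          samplingRate = fs, seed = 1L)
  zu <- surrogateMIZscore(ph, uncoupled, 200L, minShift = 0.5,
                          samplingRate = fs, seed = 1L)
  expect_gt(zc$miZ, 4)
  expect_lt(abs(zu$miZ), 3)
  expect_length(zc$surrogates, 200L)
  expect_equal(zc$miRaw, modulationIndex(ph, coupled), tolerance = 1e-9)
})

test_that("surrogateMIZscore matrix form uses independent per-epoch shifts", {
  set.seed(13)
  K <- 12L; n <- 300L; fs <- 100
  t <- seq_len(n) / fs
  ph <- t(vapply(seq_len(K),
                 function(k) thetaPLF:::wrapPhase(2 * pi * 6 * t +
                                                    runif(1, -pi, pi)),
                 numeric(n)))
  am <- 1 + 0.7 * cos(ph) + matrix(rnorm(K * n, 0, 0.2), K, n)
  res <- surrogateMIZscore(ph, am, 200L, minShift = 0.3, samplingRate = fs,
                           seed = 2L)
  expect_gt(res$miZ, 4)
  expect_equal(res$miRaw,
               modulationIndex(as.vector(t(ph)), as.vector(t(am))),
               tolerance = 1e-9)
  # matrix-mode surrogates are brute-force reproducible for a tiny case
  K2 <- 2L; n2 <- 40L
  ph2 <- matrix(runif(K2 * n2, -pi, pi), K2, n2)
  am2 <- matrix(rexp(K2 * n2), K2, n2)
  minSamp <- ceiling(0.1 * fs)
  shifts <- thetaPLF:::withSeed(7L,
    matrix(sample.int(n2 - 2L * minSamp, 150L * K2, replace = TRUE) +
             minSamp, 150L, K2))
  brute <- vapply(seq_len(150L), function(s) {
    tot <- 0i
    for (k in seq_len(K2)) {
      idx <- ((seq_len(n2) - 1L + shifts[s, k]) %% n2) + 1L
      tot <- tot + sum(am2[k, idx] * exp(1i * ph2[k, ]))
    }
    Mod(tot) / (K2 * n2)
  }, numeric(1))
  res2 <- surrogateMIZscore(ph2, am2, 150L, minShift = 0.1,
                            samplingRate = fs, seed = 7L)
  expect_equal(res2$surrogates, brute, tolerance = 1e-9)
})

test_that("surrogateMIZscore validates inputs and degenerate nulls", {
  ph <- runif(200, -pi, pi)
  expect_error(surrogateMIZscore(ph, runif(100), samplingRate = 100),
               "identical shapes")
  expect_error(surrogateMIZscore(ph, runif(200), nSurrogates = 50L,
                                 samplingRate = 100), ">= 100")
  expect_error(surrogateMIZscore(ph, runif(200), minShift = 2,
                                 samplingRate = 100), "duration/2")
  expect_error(surrogateMIZscore(ph, rep(1, 200), samplingRate = 100,
                                 minShift = 0.2), "degenerate")
})

test_that("cfcFromTF detects the generator's injected coupling", {
  cfg <- synthConfig(nParticipants = 1L, nTrialsPerCondition = 30L,
                     channelRoles = "RATN", samplingRate = 250,
                     kappaSE = 1.5, kappaUE = 1.5, kappaSpread = 0,
                     pacGainMean = 0.8, pacGainSD = 0, seed = 33L)
  es <- generateCohort(cfg)$epochSets[[1L]]
  tf <- morletDecompose(es, "RATN", freqs = c(7, 8, 40:50), decim = 2L)
  cfc <- cfcFromTF(tf, "SE", window = c(0.5, 1.4), seed = 5L)
  expect_s4_class(cfc, "CFCResult")
  expect_gt(miZ(cfc), 2)
  expect_gt(miRaw(cfc), 0)
  expect_error(cfcFromTF(tf, "SE", window = c(1.9, 2.5)), "window")
})

test_that("phaseLockingValue hits its extremes and validates shapes", {
  set.seed(14)
  a <- array(runif(20 * 2 * 3, -pi, pi), dim = c(20, 2, 3))
  # constant lag -> 1
  expect_equal(phaseLockingValue(a, a - 0.8), matrix(1, 2, 3),
               tolerance = 1e-9)
  # independent phases -> near the 1/sqrt(K) null level
  b <- array(runif(500 * 1 * 200, -pi, pi), dim = c(500, 1, 200))
  d <- array(runif(500 * 1 * 200, -pi, pi), dim = c(500, 1, 200))
  expect_lt(mean(phaseLockingValue(b, d)), 0.08)
  expect_error(phaseLockingValue(a, a[1:5, , , drop = FALSE]),
               "identical shapes")
})

test_that("plvFromTF produces a consistent SynchronyMap", {
  es <- makeEpochSet(nEpochs = 8L, channels = c("frontal", "RATN"),
                     noiseSD = 0.5,
                     signal = function(t, e, ch) sin(2 * pi * 7 * t + 0.2 *
                                                       ch))
  tfA <- morletDecompose(es, "frontal", freqs = 6:8)
  tfB <- morletDecompose(es, "RATN", freqs = 6:8)
  sm <- plvFromTF(tfA, tfB, "SE")
  expect_s4_class(sm, "SynchronyMap")
  sel <- conditions(tfA) == "SE"
  expect_equal(plvValues(sm),
               phaseLockingValue(tfPhase(tfA)[sel, , , drop = FALSE],
                                 tfPhase(tfB)[sel, , , drop = FALSE]),
               tolerance = 1e-12)
  # identical deterministic signals lock perfectly
  expect_gt(min(plvValues(sm)), 0.8)
  tfC <- morletDecompose(es, "RATN", freqs = 5:7)
  expect_error(plvFromTF(tfA, tfC, "SE"), "axes")
})
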