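# Seeded simulation studies over whole synthetic cohorts. These drive the
# package's calibration and power claims and are reused by the test suite and
# by scripts/acceptance.R. All of them run at a reduced scale chosen for a
# single CPU: 250 Hz sampling, one analysed channel, a 4-23 Hz x ~150-point
# decomposition grid.

# reduced-scale single-channel cohort configuration shared by the studies
.studyConfig <- function(seed, nTrialsPerCondition, kappaSE, kappaUE,
                         participantEffectRho = 0, kappaSpread = 0.3) {
  synthConfig(nParticipants = 7L,
              nTrialsPerCondition = nTrialsPerCondition,
              channelRoles = "RATN",
              samplingRate = 250,
              kappaSE = kappaSE, kappaUE = kappaUE,
              kappaSpread = kappaSpread,
              participantEffectRho = participantEffectRho,
              seed = seed)
}

# stack per-participant PAI maps of one condition into participants x F x T
.paiStack <- function(tfs, condition) {
  maps <- lapply(tfs, paiFromTF, condition = condition)
  arr <- array(0, dim = c(length(maps), length(tfFreqs(maps[[1L]])),
                          length(tfTimes(maps[[1L]]))))
  for (p in seq_along(maps)) arr[p, , ] <- paiValues(maps[[p]])
  list(arr = arr, freqs = tfFreqs(maps[[1L]]), times = tfTimes(maps[[1L]]))
}

#' Type-I-error calibration of the cluster-size permutation test
#'
#' Simulates cohorts under the global null (identical reset concentration in
#' both conditions, no participant-level condition difference), runs the full
#' generate - decompose - align - cluster-test chain on each, and reports
#' whether any cluster reached significance. With a valid test the fraction of
#' cohorts with any cluster p < 0.05 stays near (at most) the nominal 5%.
#'
#' @param nCohorts number of simulated cohorts; default 200.
#' @param seed master seed.
#' @param nTrialsPerCondition trials per condition; default 20.
#' @param kappa common reset concentration for both conditions; default 1.5.
#' @param nPermutations permutations per cohort; default 1000.
#' @param freqs decomposition grid; default 4-23 Hz.
#' @param decim time decimation; default 3 (about 150 retained points).
#' @param alpha cluster-level significance threshold examined; default 0.05.
#' @return logical vector, one entry per cohort: any cluster p < alpha.
#' @export
nullClusterCalibration <- function(nCohorts = 200L, seed = 1L,
                                   nTrialsPerCondition = 20L, kappa = 1.5,
                                   nPermutations = 1000L, freqs = 4:23,
                                   decim = 3L, alpha = 0.05) {
  vapply(seq_len(nCohorts), function(b) {
    cfg <- .studyConfig(deriveSeed(seed, b), nTrialsPerCondition,
                        kappaSE = kappa, kappaUE = kappa)
    sets <- generateCohort(cfg)$epochSets
    tfs  <- lapply(sets, morletDecompose, channel = "RATN", freqs = freqs,
                   nCycles = 5, decim = decim)
    se <- .paiStack(tfs, "SE"); ue <- .paiStack(tfs, "UE")
    ct <- clusterSizePermutation(se$arr, ue$arr, nPermutations,
                                 alpha = 0.05,
                                 seed = deriveSeed(seed, b + 500000L),
                                 freqs = se$freqs, times = se$times)
    length(clusterP(ct)) > 0 && any(clusterP(ct) < alpha)
  }, logical(1))
}

#' Power to detect the late theta reset difference
#'
#' Simulates cohorts in which successful encoding carries a theta phase reset
#' at 1.0 s poststimulus (concentration \code{kappaSE}) that unsuccessful
#' encoding lacks (\code{kappaUE}), runs the cluster permutation contrast, and
#' reports whether a significant cluster overlaps the late theta
#' window (0.9-1.1 s x 4-8 Hz).
#'
#' @param nCohorts default 20.
#' @param seed master seed.
#' @param kappaSE,kappaUE reset concentrations; defaults 1.5 and 0.
#' @param nTrialsPerCondition default 40.
#' @param nPermutations default 1000.
#' @param freqs,decim decomposition grid; defaults 4-23 Hz, 3.
#' @param window,band the target window and band; defaults c(0.9, 1.1) s and
#'   c(4, 8) Hz.
#' @return logical vector per cohort: significant overlapping cluster found.
#' @export
lateThetaDetection <- function(nCohorts = 20L, seed = 1L, kappaSE = 1.5,
                               kappaUE = 0, nTrialsPerCondition = 40L,
                               nPermutations = 1000L, freqs = 4:23,
                               decim = 3L, window = c(0.9, 1.1),
                               band = c(4, 8)) {
  vapply(seq_len(nCohorts), function(b) {
    cfg <- .studyConfig(deriveSeed(seed, b), nTrialsPerCondition,
                        kappaSE = kappaSE, kappaUE = kappaUE)
    sets <- generateCohort(cfg)$epochSets
    tfs  <- lapply(sets, morletDecompose, channel = "RATN", freqs = freqs,
                   nCycles = 5, decim = decim)
    se <- .paiStack(tfs, "SE"); ue <- .paiStack(tfs, "UE")
    ct <- clusterSizePermutation(se$arr, ue$arr, nPermutations,
                                 alpha = 0.05,
                                 seed = deriveSeed(seed, b + 500000L),
                                 freqs = se$freqs, times = se$times)
    cls <- clusters(ct); cp <- clusterP(ct)
    any(vapply(seq_along(cls), function(i) {
      if (cp[i] >= 0.05) return(FALSE)
      f <- se$freqs[cls[[i]]$points[, "freq"]]
      t <- se$times[cls[[i]]$points[, "time"]]
      any(f >= band[1L] & f <= band[2L] &
            t >= window[1L] & t <= window[2L])
    }, logical(1)))
  }, logical(1))
}

#' Recovery of the alignment-coupling correlation across participants
#'
#' Simulates cohorts in which participant-level reset strength and coupling
#' gain share a latent factor with correlation \code{rho}, measures from the
#' signals the late-window RATN theta alignment and the surrogate-normalised
#' coupling z-score of each participant's successful-encoding trials, and
#' returns the across-participant Pearson correlation of the two measured
#' quantities per cohort.
#'
#' @param nCohorts default 100.
#' @param seed master seed.
#' @param rho target latent correlation; default 0.9.
#' @param nTrialsPerCondition default 40.
#' @param window,band alignment summary window and band; defaults
#'   c(0.9, 1.1) s and c(4, 8) Hz.
#' @param cfcWindow coupling window; default c(0.5, 1.4) s (inside the
#'   trimmed axis of a 4 Hz, 5-cycle decomposition of a -1..2 s epoch).
#' @param nSurrogates default 200.
#' @return numeric vector of per-cohort correlations.
#' @export
effectCorrelationRecovery <- function(nCohorts = 100L, seed = 1L, rho = 0.9,
                                      nTrialsPerCondition = 40L,
                                      window = c(0.9, 1.1), band = c(4, 8),
                                      cfcWindow = c(0.5, 1.4),
                                      nSurrogates = 200L) {
  freqs <- c(4:8, 40:50)
  vapply(seq_len(nCohorts), function(b) {
    cfg <- .studyConfig(deriveSeed(seed, b), nTrialsPerCondition,
                        kappaSE = 1.5, kappaUE = 0,
                        participantEffectRho = rho)
    sets <- generateCohort(cfg)$epochSets
    pai <- mi <- numeric(length(sets))
    for (p in seq_along(sets)) {
      tf <- morletDecompose(sets[[p]], "RATN", freqs, nCycles = 5,
                            decim = 3L)
      pai[p] <- windowMeanPAI(paiFromTF(tf, "SE"), window, band)
      mi[p]  <- miZ(cfcFromTF(tf, "SE", phaseBand = c(7, 8),
                              ampBand = c(40, 50), window = cfcWindow,
                              nSurrogates = nSurrogates,
                              seed = deriveSeed(seed, b + 500000L + p)))
    }
    pearsonR(pai, mi)@r
  }, numeric(1))
}

#' Coupling z-score as a function of injected coupling depth
#'
#' Sweeps the generator's gamma modulation depth and measures the
#' surrogate-normalised modulation index of single-participant cohorts at each
#' level, to verify the estimator responds monotonically to the injected
#' effect.
#'
#' @param gains vector of modulation depths in [0, 1]; default 10 levels
#'   0 to 0.9.
#' @param nSeeds replicates per level; default 20.
#' @param seed master seed.
#' @param nTrialsPerCondition default 20.
#' @return matrix of miZ values, length(gains) x nSeeds, rownames the gains.
#' @export
couplingGainSweep <- function(gains = seq(0, 0.9, by = 0.1), nSeeds = 20L,
                              seed = 1L, nTrialsPerCondition = 20L) {
  freqs <- c(7, 8, 40:50)
  z <- matrix(NA_real_, length(gains), nSeeds,
              dimnames = list(gains, NULL))
  for (g in seq_along(gains)) {
    for (s in seq_len(nSeeds)) {
      cfg <- synthConfig(nParticipants = 1L,
                         nTrialsPerCondition = nTrialsPerCondition,
                         channelRoles = "RATN", samplingRate = 250,
                         kappaSE = 1.5, kappaUE = 1.5, kappaSpread = 0,
                         pacGainMean = gains[g], pacGainSD = 0,
                         participantEffectRho = 0,
                         seed = deriveSeed(seed, g * 1000L + s))
      es <- generateCohort(cfg)$epochSets[[1L]]
      tf <- morletDecompose(es, "RATN", freqs, nCycles = 5, decim = 2L)
      z[g, s] <- miZ(cfcFromTF(tf, "SE", window = c(0.5, 1.4),
                               seed = deriveSeed(seed, g * 1000L + s)))
    }
  }
  z
}
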