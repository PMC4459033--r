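#' Configure the synthetic cohort generator
#'
#' Builds a validated [SynthConfig-class]. The defaults describe the study
#' conditions the pipeline is designed around: 7 participants with 5 recording
#' sites (one frontal electrode, anterior and dorsomedial thalamic contacts
#' bilaterally), balanced successful (SE) / unsuccessful (UE) encoding trials,
#' a stimulus-locked theta phase reset near 1.0 s poststimulus whose von Mises
#' concentration differs by condition, an early broadband (4-20 Hz) reset of
#' equal concentration in both conditions, theta-phase-to-gamma-amplitude
#' coupling (7-8 Hz phase driving 40-50 Hz amplitude) whose depth covaries
#' across participants with reset strength, an ERP-like damped transient, and
#' 1/f background noise.
#'
#' @param nParticipants cohort size; default 7.
#' @param nTrialsPerCondition trials per condition per participant; default 40.
#' @param channelRoles ordered channel labels; default
#'   \code{c("frontal","LATN","RATN","LDMTN","RDMTN")}. A subset may be
#'   requested for reduced simulation studies.
#' @param samplingRate Hz; default 500. Must exceed twice the upper edge of
#'   \code{pacAmpBand}.
#' @param epochWindow seconds relative to stimulus onset at 0; default
#'   \code{c(-1, 2)} and must span at least 1.5 s with 0 interior.
#' @param noiseExponent 1/f spectral slope of the background; default 1.
#' @param noiseRMS background RMS in microvolts; default 10.
#' @param thetaBand Hz pair of the theta range of interest; default
#'   \code{c(4, 8)}.
#' @param resetLatency poststimulus centre of the condition-dependent theta
#'   burst, seconds; default 1.0.
#' @param resetWidth Gaussian SD of the theta burst envelope, seconds;
#'   default 0.3.
#' @param kappaSE,kappaUE von Mises concentration of the theta reset phase
#'   under successful / unsuccessful encoding; defaults 1.5 and 0 (UE phase
#'   uniform, i.e. no reset).
#' @param kappaSpread lognormal SD of the participant-level multiplier on
#'   kappa; default 0.3.
#' @param earlyResetBand Hz pair of the early broadband reset; default
#'   \code{c(4, 20)}.
#' @param earlyResetKappa concentration of the early reset phase, identical in
#'   both conditions; default 2.
#' @param earlyResetLatency,earlyResetWidth centre (s) and envelope SD (s) of
#'   the early burst; defaults 0.25 and 0.06 (short, hence spectrally broad).
#' @param thetaAmplitude,earlyAmplitude,gammaAmplitude component amplitudes in
#'   microvolts; defaults 8, 6 and 3.
#' @param pacPhaseBand,pacAmpBand Hz pairs of the coupling bands; defaults
#'   \code{c(7, 8)} and \code{c(40, 50)}. The theta burst carrier sits at the
#'   centre of \code{pacPhaseBand} so the reset oscillation is also the
#'   coupling phase.
#' @param pacGainMean,pacGainSD mean and SD of the participant-level gamma
#'   modulation depth (clipped to [0, 1] so the envelope stays nonnegative);
#'   defaults 0.5 and 0.15.
#' @param participantEffectRho target cross-participant correlation between
#'   reset strength and coupling gain, in [-1, 1]; default 0.9.
#' @param erpAmplitude peak of the ERP-like damped transient in microvolts;
#'   default 5.
#' @param seed integer master seed; the whole cohort is reproducible from it.
#' @return a [SynthConfig-class] object.
#' @seealso [generateCohort()], [synthesizeEpoch()]
#' @export
synthConfig <- function(nParticipants = 7L,
                        nTrialsPerCondition = 40L,
                        channelRoles = c("frontal", "LATN", "RATN",
                                         "LDMTN", "RDMTN"),
                        samplingRate = 500,
                        epochWindow = c(-1, 2),
                        noiseExponent = 1,
                        noiseRMS = 10,
                        thetaBand = c(4, 8),
                        resetLatency = 1.0,
                        resetWidth = 0.3,
                        kappaSE = 1.5,
                        kappaUE = 0,
                        kappaSpread = 0.3,
                        earlyResetBand = c(4, 20),
                        earlyResetKappa = 2,
                        earlyResetLatency = 0.25,
                        earlyResetWidth = 0.06,
                        thetaAmplitude = 8,
                        earlyAmplitude = 6,
                        gammaAmplitude = 3,
                        pacPhaseBand = c(7, 8),
                        pacAmpBand = c(40, 50),
                        pacGainMean = 0.5,
                        pacGainSD = 0.15,
                        participantEffectRho = 0.9,
                        erpAmplitude = 5,
                        seed = 20150520L) {
  new("SynthConfig",
      nParticipants        = as.integer(nParticipants),
      nTrialsPerCondition  = as.integer(nTrialsPerCondition),
      channelRoles         = channelRoles,
      samplingRate         = samplingRate,
      epochWindow          = epochWindow,
      noiseExponent        = noiseExponent,
      noiseRMS             = noiseRMS,
      thetaBand            = thetaBand,
      resetLatency         = resetLatency,
      resetWidth           = resetWidth,
      kappaSE              = kappaSE,
      kappaUE              = kappaUE,
      kappaSpread          = kappaSpread,
      earlyResetBand       = earlyResetBand,
      earlyResetKappa      = earlyResetKappa,
      earlyResetLatency    = earlyResetLatency,
      earlyResetWidth      = earlyResetWidth,
      thetaAmplitude       = thetaAmplitude,
      earlyAmplitude       = earlyAmplitude,
      gammaAmplitude       = gammaAmplitude,
      pacPhaseBand         = pacPhaseBand,
      pacAmpBand           = pacAmpBand,
      pacGainMean          = pacGainMean,
      pacGainSD            = pacGainSD,
      participantEffectRho = participantEffectRho,
      erpAmplitude         = erpAmplitude,
      seed                 = as.integer(seed))
}

# 1/f^exponent background noise by spectral shaping of white noise with a
# circular FFT (no reflection padding). Returns an n x m matrix, each column
# one independent series scaled to the requested RMS.
.pinkNoise <- function(n, m, fs, exponent, rms) {
  x <- matrix(stats::rnorm(n * m), n, m)
  if (exponent == 0) return(x * rms)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  g <- c(0, f[-1]^(-exponent / 2))      # kill DC
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
  sc <- sqrt(colMeans(y^2))
  sweep(y, 2, ifelse(sc > 0, rms / sc, 1), "*")
}

#' Synthesize a single epoch
#'
#' Draws one epoch (channels x samples, microvolts) for one participant and
#' condition: 1/f background + early broadband burst with a von Mises reset
#' phase (both conditions) + theta burst centred at \code{resetLatency} whose
#' phase there follows the condition's concentration + a gamma component whose
#' amplitude envelope is \code{1 + m * cos(theta phase)} with m the
#' participant's coupling gain + an ERP-like damped transient. Each channel
#' draws its reset phases independently (around a common mean direction, so
#' concentrated resets also create inter-channel synchrony).
#'
#' @param config a [SynthConfig-class].
#' @param params one row of the ground-truth parameter table produced by
#'   [generateCohort()] (fields \code{kappaSE}, \code{kappaUE},
#'   \code{pacGain}, \code{erpGain}).
#' @param condition "SE" or "UE".
#' @param trialSeed integer seed; the epoch is deterministic given it.
#' @return numeric matrix, channels x samples.
#' @export
synthesizeEpoch <- function(config, params, condition, trialSeed) {
  stopifnot(is(config, "SynthConfig"))
  if (!condition %in% .CONDITIONS)
    stop("condition must be 'SE' or 'UE'", call. = FALSE)
  withSeed(trialSeed, .synthEpochDraw(config, params, condition))
}

# One epoch from the current RNG stream.
.synthEpochDraw <- function(config, params, condition) {
  fs <- config@samplingRate
  t  <- seq(config@epochWindow[1L], config@epochWindow[2L], by = 1 / fs)
  ns <- length(t)
  nc <- length(config@channelRoles)
  kappa <- if (condition == "SE") params$kappaSE else params$kappaUE

  out <- t(.pinkNoise(ns, nc, fs, config@noiseExponent, config@noiseRMS))

  # early broadband burst: short Gaussian-windowed oscillation at the centre
  # of earlyResetBand, reset phase ~ vM(0, earlyResetKappa) per channel
  fE   <- mean(config@earlyResetBand)
  envE <- exp(-(t - config@earlyResetLatency)^2 /
                (2 * config@earlyResetWidth^2))
  phiE <- .rvonmises(nc, config@earlyResetKappa)
  # theta burst: carrier drawn per trial/channel within the PAC phase band
  # (trial-to-trial frequency variability dephases trials away from the reset
  # latency, so alignment peaks there); phase at resetLatency ~
  # vM(0, kappa_condition)
  fT   <- stats::runif(nc, config@pacPhaseBand[1L], config@pacPhaseBand[2L])
  envT <- exp(-(t - config@resetLatency)^2 / (2 * config@resetWidth^2))
  phiT <- .rvonmises(nc, kappa)
  # gamma carrier with theta-phase-modulated envelope
  fG   <- mean(config@pacAmpBand)
  m    <- params$pacGain
  phiG <- stats::runif(nc, -pi, pi)
  # ERP-like damped transient, fixed shape, participant gain
  erp  <- numeric(ns)
  post <- t >= 0
  erp[post] <- exp(-t[post] / 0.15) * sin(2 * pi * 4 * t[post])
  erp <- erp / max(abs(erp)) * config@erpAmplitude * params$erpGain

  for (ch in seq_len(nc)) {
    thPhase <- 2 * pi * fT[ch] * (t - config@resetLatency) + phiT[ch]
    gammaEnv <- pmax(1 + m * cos(thPhase), 0)
    out[ch, ] <- out[ch, ] +
      config@earlyAmplitude * envE *
        cos(2 * pi * fE * (t - config@earlyResetLatency) + phiE[ch]) +
      config@thetaAmplitude * envT * cos(thPhase) +
      config@gammaAmplitude * gammaEnv * cos(2 * pi * fG * t + phiG[ch]) +
      erp
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws one [EpochSet-class] per participant with
#' \code{nTrialsPerCondition} epochs per condition, plus the ground-truth
#' participant parameter table for recovery tests. Participant-level reset
#' strength and coupling gain are tied through a shared latent Gaussian factor
#' so their across-participant correlation targets
#' \code{participantEffectRho}: with latent iid z, u ~ N(0,1),
#' kappa_i = kappa * exp(s * z_i) (lognormal spread s = \code{kappaSpread},
#' the same multiplier for SE and UE) and
#' gain_i = clip(mean + sd * (rho * z_i + sqrt(1 - rho^2) * u_i), 0, 1).
#' Everything is reproducible from \code{config@seed}.
#'
#' @param config a [SynthConfig-class].
#' @return list with elements \code{epochSets} (list of [EpochSet-class]) and
#'   \code{params} (data.frame: participantID, kappaSE, kappaUE, pacGain,
#'   erpGain).
#' @examples
#' cfg <- synthConfig(nParticipants = 2, nTrialsPerCondition = 4,
#'                    channelRoles = "RATN", samplingRate = 250, seed = 7)
#' cohort <- generateCohort(cfg)
#' cohort$epochSets[[1]]
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  params <- drawParticipantParams(config)
  nTrial <- config@nTrialsPerCondition
  t      <- seq(config@epochWindow[1L], config@epochWindow[2L],
                by = 1 / config@samplingRate)
  sets <- vector("list", config@nParticipants)
  for (p in seq_len(config@nParticipants)) {
    dat  <- array(0, dim = c(2L * nTrial, length(config@channelRoles),
                             length(t)))
    cond <- rep(.CONDITIONS, each = nTrial)
    for (e in seq_len(2L * nTrial)) {
      dat[e, , ] <- synthesizeEpoch(
        config, params[p, ], cond[e],
        trialSeed = deriveSeed(config@seed, p * 100000L + e))
    }
    sets[[p]] <- new("EpochSet",
                     participantID = params$participantID[p],
                     channels      = config@channelRoles,
                     samplingRate  = config@samplingRate,
                     times         = t,
                     data          = dat,
                     condition     = cond)
  }
  list(epochSets = sets, params = params)
}

#' Ground-truth participant parameters
#'
#' Draws the participant-level effect sizes used by [generateCohort()];
#' exposed so the induced cross-participant correlation can be studied
#' directly.
#'
#' @param config a [SynthConfig-class].
#' @return data.frame with one row per participant.
#' @export
drawParticipantParams <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  withSeed(deriveSeed(config@seed, 0L), {
    nP  <- config@nParticipants
    z   <- stats::rnorm(nP)
    u   <- stats::rnorm(nP)
    rho <- config@participantEffectRho
    s   <- config@kappaSpread
    mult <- exp(s * z - s^2 / 2)   # unit-mean lognormal multiplier
    gain <- config@pacGainMean +
      config@pacGainSD * (rho * z + sqrt(1 - rho^2) * u)
    data.frame(
      participantID = sprintf("P%02d", seq_len(nP)),
      kappaSE = config@kappaSE * mult,
      kappaUE = config@kappaUE * mult,
      pacGain = pmin(pmax(gain, 0), 1),
      erpGain = exp(0.2 * stats::rnorm(nP) - 0.02),
      stringsAsFactors = FALSE)
  })
}

#' Write the ground-truth parameter table to TSV
#'
#' @param params data.frame from [generateCohort()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Field names match the arguments of [synthConfig()]; absent fields take the
#' defaults. Files ending in .json are parsed as JSON, anything else as YAML.
#'
#' @param path config file path.
#' @return a [SynthConfig-class].
#' @export
readSynthConfig <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  known <- names(formals(synthConfig))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(synthConfig, lst)
}
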