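#' @import methods
NULL

.CONDITIONS <- c("SE", "UE")

#' EpochSet: one participant's epoched multi-channel recording
#'
#' The pipeline's universal input: a stimulus-locked, epoched multi-channel
#' recording with a per-epoch condition label ("SE" = successfully encoded,
#' "UE" = unsuccessfully encoded). Time 0 is stimulus onset.
#'
#' @slot participantID single participant label.
#' @slot channels ordered channel role labels (e.g. "frontal", "RATN").
#' @slot samplingRate sampling rate in Hz.
#' @slot times sample times in seconds, a uniform grid with 0 at stimulus
#'   onset; spacing is \code{1/samplingRate}.
#' @slot data numeric array, epochs x channels x samples, in microvolts.
#' @slot condition character vector, one "SE"/"UE" label per epoch.
#'
#' @seealso [generateCohort()], [readEpochContainer()], [balanceTrials()]
#' @export
setClass("EpochSet",
  representation(
    participantID = "character",
    channels      = "character",
    samplingRate  = "numeric",
    times         = "numeric",
    data          = "array",
    condition     = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (epochs x channels x samples)")
  else {
    if (d[2L] != length(object@channels))
      msg <- c(msg, "dim(data)[2] must equal length(channels)")
    if (d[3L] != length(object@times))
      msg <- c(msg, "dim(data)[3] must equal length(times)")
    if (d[1L] != length(object@condition))
      msg <- c(msg, "dim(data)[1] must equal length(condition)")
  }
  if (length(object@participantID) != 1L)
    msg <- c(msg, "participantID must be a single label")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@times) >= 2L) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (max(abs(dt - 1 / object@samplingRate)) > 1e-6 / object@samplingRate)
      msg <- c(msg, "times must be uniform with spacing 1/samplingRate")
  }
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (!all(object@condition %in% .CONDITIONS))
    msg <- c(msg, "condition labels must be 'SE' or 'UE'")
  if (!all(.CONDITIONS %in% object@condition))
    msg <- c(msg, "at least one epoch per condition is required")
  if (length(msg)) msg else TRUE
})

#' TFAtlas: time-frequency phase and amplitude for one channel
#'
#' Per-epoch wavelet decomposition of one channel of an [EpochSet-class].
#' Edges contaminated by the wavelet are trimmed, so \code{times} is an
#' interior subset of the epoch's time axis.
#'
#' @slot participantID participant label carried from the source epochs.
#' @slot channel channel role label that was decomposed.
#' @slot condition per-epoch condition labels, aligned with the first array
#'   dimension.
#' @slot freqs ascending frequency grid in Hz.
#' @slot times retained times in seconds (uniform subset after edge trimming,
#'   possibly decimated).
#' @slot phase numeric array, epochs x freqs x times, radians in (-pi, pi].
#' @slot amplitude numeric array, epochs x freqs x times, microvolts, >= 0.
#'
#' @seealso [morletDecompose()], [bandComplexMean()], [paiFromTF()]
#' @export
setClass("TFAtlas",
  representation(
    participantID = "character",
    channel       = "character",
    condition     = "character",
    freqs         = "numeric",
    times         = "numeric",
    phase         = "array",
    amplitude     = "array"
  )
)

setValidity("TFAtlas", function(object) {
  msg <- character()
  dp <- dim(object@phase); da <- dim(object@amplitude)
  if (length(dp) != 3L || length(da) != 3L || !identical(dp, da))
    msg <- c(msg, "phase and amplitude must be 3-d arrays of identical shape")
  else {
    if (dp[2L] != length(object@freqs))
      msg <- c(msg, "dim[2] must equal length(freqs)")
    if (dp[3L] != length(object@times))
      msg <- c(msg, "dim[3] must equal length(times)")
    if (dp[1L] != length(object@condition))
      msg <- c(msg, "dim[1] must equal length(condition)")
  }
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly ascending")
  if (any(object@amplitude < 0))
    msg <- c(msg, "amplitude must be >= 0 everywhere")
  if (any(object@phase <= -pi - 1e-9 | object@phase > pi + 1e-9))
    msg <- c(msg, "phase must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' PAIMap: phase alignment index over a time-frequency grid
#'
#' The phase alignment index (phase-locking factor, inter-trial coherence) for
#' one participant/channel/condition: at each time-frequency point the modulus
#' of the across-epoch mean unit phase vector, so 0 means no phase alignment
#' and 1 complete phase alignment.
#'
#' @slot participantID participant label.
#' @slot channel channel role label.
#' @slot condition "SE" or "UE".
#' @slot freqs Hz grid. @slot times s grid.
#' @slot pai matrix freqs x times with values in [0, 1].
#' @slot nEpochs number of epochs K that entered the index.
#' @export
setClass("PAIMap",
  representation(
    participantID = "character",
    channel       = "character",
    condition     = "character",
    freqs         = "numeric",
    times         = "numeric",
    pai           = "matrix",
    nEpochs       = "integer"
  )
)

setValidity("PAIMap", function(object) {
  msg <- character()
  if (nrow(object@pai) != length(object@freqs) ||
      ncol(object@pai) != length(object@times))
    msg <- c(msg, "pai must be freqs x times")
  if (any(object@pai < -1e-12 | object@pai > 1 + 1e-12))
    msg <- c(msg, "pai values must lie in [0, 1]")
  if (length(object@condition) != 1L ||
      !object@condition %in% .CONDITIONS)
    msg <- c(msg, "condition must be a single 'SE' or 'UE'")
  if (object@nEpochs < 2L)
    msg <- c(msg, "nEpochs must be >= 2")
  if (length(msg)) msg else TRUE
})

#' CFCResult: theta-gamma phase-amplitude coupling for one participant
#'
#' Canolty-style modulation index, raw and surrogate-normalised, for one
#' participant/channel/condition over an analysis window.
#'
#' @slot participantID,channel,condition labels.
#' @slot phaseBand Hz pair of the phase-providing band (default 7-8 Hz).
#' @slot ampBand Hz pair of the amplitude-providing band (default 40-50 Hz).
#' @slot miRaw modulus of the time-mean composite vector, in microvolts.
#' @slot miZ surrogate z-score of miRaw (unitless).
#' @slot nSurrogates number of circular-shift surrogates used.
#' @slot window analysis window in seconds.
#' @export
setClass("CFCResult",
  representation(
    participantID = "character",
    channel       = "character",
    condition     = "character",
    phaseBand     = "numeric",
    ampBand       = "numeric",
    miRaw         = "numeric",
    miZ           = "numeric",
    nSurrogates   = "integer",
    window        = "numeric"
  )
)

setValidity("CFCResult", function(object) {
  msg <- character()
  if (object@miRaw < 0) msg <- c(msg, "miRaw must be >= 0")
  if (object@nSurrogates < 100L)
    msg <- c(msg, "nSurrogates must be >= 100")
  if (length(msg)) msg else TRUE
})

#' SynchronyMap: between-channel phase-locking value
#'
#' Across-epoch phase-locking value (PLV) between two channels at each
#' time-frequency point, per condition.
#'
#' @slot channelPair the two channel role labels.
#' @slot condition "SE" or "UE".
#' @slot freqs,times grids. @slot plv matrix freqs x times in [0, 1].
#' @slot nEpochs epochs used.
#' @export
setClass("SynchronyMap",
  representation(
    channelPair = "character",
    condition   = "character",
    freqs       = "numeric",
    times       = "numeric",
    plv         = "matrix",
    nEpochs     = "integer"
  )
)

setValidity("SynchronyMap", function(object) {
  msg <- character()
  if (any(object@plv < -1e-12 | object@plv > 1 + 1e-12))
    msg <- c(msg, "plv values must lie in [0, 1]")
  if (nrow(object@plv) != length(object@freqs) ||
      ncol(object@plv) != length(object@times))
    msg <- c(msg, "plv must be freqs x times")
  if (length(msg)) msg else TRUE
})

#' ERPWave: event-related potential for one participant/channel/condition
#'
#' Trial-averaged evoked waveform: every trial band-pass filtered (default
#' 1-8 Hz, zero phase), baseline-corrected by its prestimulus 200 ms mean,
#' then averaged over trials.
#'
#' @slot participantID,channel,condition labels.
#' @slot times s grid. @slot values microvolts.
#' @slot filterBand Hz pair used. @slot baselineWindow s pair used.
#' @export
setClass("ERPWave",
  representation(
    participantID  = "character",
    channel        = "character",
    condition      = "character",
    times          = "numeric",
    values         = "numeric",
    filterBand     = "numeric",
    baselineWindow = "numeric"
  )
)

setValidity("ERPWave", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  bl <- object@times >= object@baselineWindow[1L] &
        object@times <= object@baselineWindow[2L]
  if (any(bl)) {
    scale <- max(abs(object@values), 1)
    if (abs(mean(object@values[bl])) > 1e-8 * scale)
      msg <- c(msg, "baseline mean of values must be ~0")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterTestResult: cluster-size permutation contrast of two PAI map sets
#'
#' Pointwise paired t/p maps across participants plus the cluster-size
#' permutation assessment: connected components (4-adjacency, positive and
#' negative t clustered separately) of pointwise-significant points, a
#' permutation null of the largest cluster size per iteration, and a p-value
#' per observed cluster.
#'
#' @slot tMap,pMap matrices freqs x times.
#' @slot clusters list; each element has \code{points} (2-column matrix of
#'   freq/time grid indices), \code{size} (point count) and \code{sign}.
#' @slot nullMaxSizes integer vector, one max-cluster size per permutation.
#' @slot clusterP per-cluster permutation p-values in (0, 1].
#' @slot freqs,times axis grids. @slot alpha pointwise threshold.
#' @export
setClass("ClusterTestResult",
  representation(
    tMap         = "matrix",
    pMap         = "matrix",
    clusters     = "list",
    nullMaxSizes = "integer",
    clusterP     = "numeric",
    freqs        = "numeric",
    times        = "numeric",
    alpha        = "numeric"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  if (!identical(dim(object@tMap), dim(object@pMap)))
    msg <- c(msg, "tMap and pMap must have identical dimensions")
  if (length(object@clusterP) != length(object@clusters))
    msg <- c(msg, "one clusterP per cluster")
  if (length(object@clusterP) &&
      any(object@clusterP <= 0 | object@clusterP > 1))
    msg <- c(msg, "clusterP must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: a Pearson correlation with its test
#'
#' @slot r Pearson coefficient. @slot n number of pairs.
#' @slot tStat t statistic with n-2 df. @slot p two-sided p.
#' @slot pFDR BH-adjusted p (NA until a family is adjusted together).
#' @slot label free-text description of what was correlated.
#' @export
setClass("CorrelationResult",
  representation(
    r     = "numeric",
    n     = "integer",
    tStat = "numeric",
    p     = "numeric",
    pFDR  = "numeric",
    label = "character"
  )
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
  if (!is.na(object@pFDR) && object@pFDR < object@p - 1e-12)
    msg <- c(msg, "pFDR must be >= p")
  if (length(msg)) msg else TRUE
})

#' FisherComparison: Fisher z comparison of two correlations
#'
#' @slot z unit-normal statistic. @slot p two-sided p.
#' @slot r1,n1,r2,n2 the two correlations and their sample sizes.
#' @export
setClass("FisherComparison",
  representation(
    z  = "numeric", p = "numeric",
    r1 = "numeric", n1 = "integer",
    r2 = "numeric", n2 = "integer"
  )
)

#' SynthConfig: study-level parameters of the synthetic cohort generator
#'
#' Holds everything [generateCohort()] needs to draw a cohort of epoched
#' recordings with known phase-reset, coupling, and evoked structure.
#' See [synthConfig()] for field semantics and defaults.
#'
#' @seealso [synthConfig()], [generateCohort()]
#' @export
setClass("SynthConfig",
  representation(
    nParticipants        = "integer",
    nTrialsPerCondition  = "integer",
    channelRoles         = "character",
    samplingRate         = "numeric",
    epochWindow          = "numeric",
    noiseExponent        = "numeric",
    noiseRMS             = "numeric",
    thetaBand            = "numeric",
    resetLatency         = "numeric",
    resetWidth           = "numeric",
    kappaSE              = "numeric",
    kappaUE              = "numeric",
    kappaSpread          = "numeric",
    earlyResetBand       = "numeric",
    earlyResetKappa      = "numeric",
    earlyResetLatency    = "numeric",
    earlyResetWidth      = "numeric",
    thetaAmplitude       = "numeric",
    earlyAmplitude       = "numeric",
    gammaAmplitude       = "numeric",
    pacPhaseBand         = "numeric",
    pacAmpBand           = "numeric",
    pacGainMean          = "numeric",
    pacGainSD            = "numeric",
    participantEffectRho = "numeric",
    erpAmplitude         = "numeric",
    seed                 = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  w <- object@epochWindow
  if (length(w) != 2L || !(w[1L] < 0 && 0 < w[2L]))
    msg <- c(msg, "epochWindow must straddle the stimulus: start < 0 < end")
  else if (w[2L] - w[1L] < 1.5)
    msg <- c(msg, "epochWindow must span >= 1.5 s")
  for (nm in c("kappaSE", "kappaUE", "earlyResetKappa"))
    if (slot(object, nm) < 0) msg <- c(msg, paste(nm, "must be >= 0"))
  if (object@samplingRate <= 2 * max(object@pacAmpBand))
    msg <- c(msg, "samplingRate must exceed twice the PAC amplitude band")
  if (object@nTrialsPerCondition < 2L)
    msg <- c(msg, "nTrialsPerCondition must be >= 2")
  if (abs(object@participantEffectRho) > 1)
    msg <- c(msg, "|participantEffectRho| must be <= 1")
  if (object@nParticipants < 1L)
    msg <- c(msg, "nParticipants must be >= 1")
  if (length(object@channelRoles) < 1L)
    msg <- c(msg, "at least one channel role is required")
  if (length(msg)) msg else TRUE
})
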