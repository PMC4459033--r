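#' Phase alignment index (phase-locking factor) over epochs
#'
#' At each time-frequency point, the modulus of the across-epoch mean unit
#' phase vector: PAI = |sum_k exp(i phi_k)| / K. 0 means no phase alignment
#' across epochs, 1 complete alignment.
#'
#' @param phases numeric array, K epochs x freqs x times, radians.
#' @return numeric matrix freqs x times with values in [0, 1].
#' @examples
#' phaseAlignmentIndex(array(c(0, 0, pi/2), dim = c(3, 1, 1)))  # sqrt(5)/3
#' @export
phaseAlignmentIndex <- function(phases) {
  d <- dim(phases)
  if (length(d) != 3L)
    stop("phases must be a 3-d array (epochs x freqs x times)", call. = FALSE)
  if (d[1L] < 2L)
    stop("at least 2 epochs are required for a phase alignment index",
         call. = FALSE)
  z <- exp(1i * phases)
  m <- Mod(colMeans(z))               # collapses the epoch dimension
  matrix(pmin(m, 1), d[2L], d[3L])
}

#' Balance trial counts across conditions
#'
#' Randomly subsamples the larger condition without replacement down to the
#' smaller condition's count, preserving the original epoch order otherwise.
#' Condition-blind alignment comparisons require equal K because the
#' phase-locking factor is positively biased at small K.
#'
#' @param epochs an [EpochSet-class] with both conditions present.
#' @param seed integer seed; the subsample is deterministic given it.
#' @return a balanced [EpochSet-class] (unchanged if already balanced).
#' @export
balanceTrials <- function(epochs, seed = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  cond <- conditions(epochs)
  nSE <- sum(cond == "SE"); nUE <- sum(cond == "UE")
  if (nSE == 0L || nUE == 0L)
    stop("both conditions must have at least one epoch", call. = FALSE)
  if (nSE == nUE) return(epochs)
  k    <- min(nSE, nUE)
  big  <- if (nSE > nUE) "SE" else "UE"
  idxB <- which(cond == big)
  keep <- sort(c(which(cond != big),
                 withSeed(seed, sample(idxB, k))))
  initialize(epochs,
             data      = epochs@data[keep, , , drop = FALSE],
             condition = cond[keep])
}

#' Build a PAIMap from a time-frequency decomposition
#'
#' Computes the phase alignment index from the phases of one condition's
#' epochs in a [TFAtlas-class].
#'
#' @param tf a [TFAtlas-class] (decompose a balanced [EpochSet-class] if the
#'   two conditions are to be compared).
#' @param condition "SE" or "UE".
#' @return a [PAIMap-class].
#' @export
paiFromTF <- function(tf, condition) {
  stopifnot(is(tf, "TFAtlas"))
  if (!condition %in% .CONDITIONS)
    stop("condition must be 'SE' or 'UE'", call. = FALSE)
  sel <- conditions(tf) == condition
  if (sum(sel) < 2L)
    stop("fewer than 2 epochs in condition ", condition, call. = FALSE)
  new("PAIMap",
      participantID = participantID(tf),
      channel       = tf@channel,
      condition     = condition,
      freqs         = tfFreqs(tf),
      times         = tfTimes(tf),
      pai           = phaseAlignmentIndex(tf@phase[sel, , , drop = FALSE]),
      nEpochs       = sum(sel))
}

#' Mean phase alignment over a time window and frequency band
#'
#' Arithmetic mean of the PAI over all grid points whose time lies in the
#' closed window and frequency in the closed band. This is the per-participant
#' scalar entering the across-participant correlation battery (e.g. late
#' 0.9-1.1 s x 4-8 Hz theta alignment).
#'
#' @param map a [PAIMap-class].
#' @param timeWindow s pair. @param freqBand Hz pair.
#' @return scalar in [0, 1].
#' @export
windowMeanPAI <- function(map, timeWindow, freqBand) {
  stopifnot(is(map, "PAIMap"))
  fi <- closedIndices(tfFreqs(map), freqBand, "frequency band")
  ti <- closedIndices(tfTimes(map), timeWindow, "time window")
  mean(map@pai[fi, ti])
}
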