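#' Canolty-style modulation index
#'
#' Raw phase-amplitude coupling strength between a slow rhythm's phase and a
#' fast rhythm's amplitude: the modulus of the time-mean composite vector,
#' MI = |mean_t amp(t) * exp(i phase(t))|. If amplitude is independent of
#' phase the composite vectors cancel; if amplitude is systematically larger
#' at some phase the mean vector points there.
#'
#' @param phaseSeries radians over samples (e.g. 7-8 Hz theta phase).
#' @param ampSeries microvolts over samples (e.g. 40-50 Hz gamma amplitude),
#'   equal length, >= 2 samples.
#' @return nonnegative scalar in the units of \code{ampSeries}.
#' @examples
#' phi <- seq(0, 20 * pi, length.out = 4001)[-1]
#' modulationIndex(phi, 1 + cos(phi))  # 0.5 analytically
#' @export
modulationIndex <- function(phaseSeries, ampSeries) {
  if (length(phaseSeries) != length(ampSeries))
    stop("phaseSeries and ampSeries must have equal length", call. = FALSE)
  if (length(phaseSeries) < 2L)
    stop("at least 2 samples are required", call. = FALSE)
  Mod(mean(ampSeries * exp(1i * phaseSeries)))
}

#' Surrogate-normalised modulation index
#'
#' Normalises [modulationIndex()] against a null of circularly time-shifted
#' amplitude: the amplitude series is rotated by random offsets of at least
#' \code{minShift} seconds (preserving both marginal distributions while
#' destroying the phase-amplitude relation) and the raw MI is z-scored against
#' the \code{nSurrogates} surrogate values. The z-score is invariant to a
#' global amplitude gain.
#'
#' Inputs may be single series (numeric vectors) or multi-epoch matrices
#' (epochs x samples). In matrix form the raw MI is computed over all epochs
#' pooled, and every surrogate rotates each epoch's amplitude by an
#' independent offset within that epoch. Independent per-epoch rotations are
#' essential when both phase and amplitude are time-locked to a stimulus: a
#' common shift then lands amplitude on similarly-locked stretches of signal
#' and the surrogate distribution retains genuine coupling, but rotations that
#' differ across epochs average the retained coupling to zero.
#'
#' @param phaseSeries radians; numeric vector or epochs x samples matrix.
#' @param ampSeries amplitudes, same shape as \code{phaseSeries}.
#' @param nSurrogates number of surrogates, >= 100; default 200.
#' @param minShift minimum shift in seconds; must be < duration/2 (of one
#'   epoch, in matrix form). Default 0.5.
#' @param samplingRate Hz of the series.
#' @param seed integer seed for the surrogate offsets.
#' @return list with \code{miRaw}, \code{miZ}, \code{surrogates}.
#' @export
surrogateMIZscore <- function(phaseSeries, ampSeries, nSurrogates = 200L,
                              minShift = 0.5, samplingRate, seed = 1L) {
  if (is.matrix(phaseSeries) != is.matrix(ampSeries) ||
      !identical(dim(phaseSeries), dim(ampSeries)) ||
      length(ampSeries) != length(phaseSeries))
    stop("phaseSeries and ampSeries must have identical shapes",
         call. = FALSE)
  if (nSurrogates < 100L)
    stop("nSurrogates must be >= 100", call. = FALSE)
  ph <- if (is.matrix(phaseSeries)) phaseSeries else
    matrix(phaseSeries, nrow = 1L)
  am <- if (is.matrix(ampSeries)) ampSeries else matrix(ampSeries, nrow = 1L)
  K <- nrow(ph); n <- ncol(ph)
  if (n < 2L)
    stop("at least 2 samples per epoch are required", call. = FALSE)
  minSamp <- ceiling(minShift * samplingRate)
  if (minSamp >= n / 2)
    stop("series too short: minShift must be < duration/2", call. = FALSE)
  # circular cross-correlation of each epoch's amplitude against its phase
  # vector at every lag: cc[k, s+1] = sum_t am[k, (t+s-1) %% n + 1] *
  # exp(1i ph[k, t]); lag 0 recovers the observed composite sum
  cc <- matrix(0i, K, n)
  for (k in seq_len(K)) {
    fa <- stats::fft(am[k, ])
    fe <- stats::fft(exp(1i * ph[k, ]), inverse = TRUE)
    cc[k, ] <- stats::fft(fa * fe, inverse = TRUE) / n
  }
  miRaw <- Mod(sum(cc[, 1L])) / (K * n)
  shifts <- withSeed(seed,
                     matrix(sample.int(n - 2L * minSamp, nSurrogates * K,
                                       replace = TRUE) + minSamp,
                            nSurrogates, K))
  pick <- cbind(rep(seq_len(K), each = nSurrogates),
                as.vector(shifts) + 1L)
  surr <- Mod(rowSums(matrix(cc[pick], nSurrogates, K))) / (K * n)
  s <- stats::sd(surr)
  if (!is.finite(s) ||
      s <= 1e-9 * max(miRaw, mean(surr), .Machine$double.xmin))
    stop("degenerate surrogate distribution (zero spread)", call. = FALSE)
  list(miRaw = miRaw, miZ = (miRaw - mean(surr)) / s,
       surrogates = as.numeric(surr))
}

#' Theta-gamma coupling for one participant/channel/condition
#'
#' Convenience wrapper producing a [CFCResult-class] from a decomposed
#' channel: band phase (complex mean over \code{phaseBand}) and band amplitude
#' (over \code{ampBand}) are extracted in the analysis window for every epoch
#' of the condition and pooled by [surrogateMIZscore()] (per-epoch surrogate
#' rotations) into one per-participant scalar. Each epoch's mean amplitude is
#' removed first: a stimulus-locked (evoked) amplitude level paired with
#' stimulus-locked phase would otherwise register as coupling even when the
#' amplitude does not track phase within epochs.
#'
#' @param tf a [TFAtlas-class].
#' @param condition "SE" or "UE".
#' @param phaseBand,ampBand Hz pairs; defaults 7-8 and 40-50.
#' @param window analysis window in s; default c(0.5, 1.5).
#' @param nSurrogates,minShift,seed passed to [surrogateMIZscore()];
#'   \code{minShift} defaults to 0.1 s (shifts are within-epoch, so it must be
#'   under half the window length).
#' @return a [CFCResult-class].
#' @export
cfcFromTF <- function(tf, condition, phaseBand = c(7, 8),
                      ampBand = c(40, 50), window = c(0.5, 1.5),
                      nSurrogates = 200L, minShift = 0.1, seed = 1L) {
  stopifnot(is(tf, "TFAtlas"))
  sel <- conditions(tf) == condition
  if (!any(sel))
    stop("no epochs in condition ", condition, call. = FALSE)
  ti  <- closedIndices(tfTimes(tf), window, "analysis window")
  fsEff <- 1 / mean(diff(tfTimes(tf)))       # effective rate after decimation
  zP <- bandComplexMean(tf, phaseBand)[sel, ti, drop = FALSE]
  zA <- bandComplexMean(tf, ampBand)[sel, ti, drop = FALSE]
  ph <- Arg(zP)
  am <- Mod(zA)
  am <- am - rowMeans(am)                    # remove evoked amplitude level
  res <- surrogateMIZscore(ph, am, nSurrogates, minShift, fsEff, seed)
  new("CFCResult",
      participantID = participantID(tf), channel = tf@channel,
      condition = condition, phaseBand = phaseBand, ampBand = ampBand,
      miRaw = res$miRaw, miZ = res$miZ,
      nSurrogates = as.integer(nSurrogates), window = window)
}

#' Between-channel phase-locking value
#'
#' Across-epoch synchrony between two channels at each time-frequency point:
#' PLV = |mean_k exp(i (phiA_k - phiB_k))|. 1 means a constant phase lag
#' across epochs, 0 no consistent relation.
#'
#' @param phasesA,phasesB numeric arrays, K epochs x freqs x times, identical
#'   shapes, K >= 2.
#' @return numeric matrix freqs x times in [0, 1].
#' @export
phaseLockingValue <- function(phasesA, phasesB) {
  if (!identical(dim(phasesA), dim(phasesB)))
    stop("phasesA and phasesB must have identical shapes", call. = FALSE)
  d <- dim(phasesA)
  if (length(d) != 3L || d[1L] < 2L)
    stop("inputs must be K x freqs x times arrays with K >= 2",
         call. = FALSE)
  m <- Mod(colMeans(exp(1i * (phasesA - phasesB))))
  matrix(pmin(m, 1), d[2L], d[3L])
}

#' SynchronyMap between two decomposed channels
#'
#' @param tfA,tfB [TFAtlas-class] objects for two channels of the same
#'   (balanced) epochs, identical axes.
#' @param condition "SE" or "UE".
#' @return a [SynchronyMap-class].
#' @export
plvFromTF <- function(tfA, tfB, condition) {
  stopifnot(is(tfA, "TFAtlas"), is(tfB, "TFAtlas"))
  if (!isTRUE(all.equal(tfFreqs(tfA), tfFreqs(tfB))) ||
      !isTRUE(all.equal(tfTimes(tfA), tfTimes(tfB))))
    stop("the two decompositions must share axes", call. = FALSE)
  sel <- conditions(tfA) == condition
  if (sum(sel) < 2L)
    stop("fewer than 2 epochs in condition ", condition, call. = FALSE)
  new("SynchronyMap",
      channelPair = c(tfA@channel, tfB@channel),
      condition   = condition,
      freqs       = tfFreqs(tfA),
      times       = tfTimes(tfA),
      plv         = phaseLockingValue(tfA@phase[sel, , , drop = FALSE],
                                      tfB@phase[sel, , , drop = FALSE]),
      nEpochs     = sum(sel))
}
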