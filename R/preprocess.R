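#' Bipolar re-referencing of depth-electrode contacts
#'
#' Re-references a thalamic contact by subtracting its deeper neighbour,
#' yielding a bipolar derivation that suppresses far-field activity common to
#' both contacts.
#'
#' @param deepSignal numeric series from the contact of interest, microvolts.
#' @param deeperNeighbor numeric series from the next deeper contact, equal
#'   length.
#' @return the elementwise difference \code{deepSignal - deeperNeighbor}.
#' @export
bipolarRereference <- function(deepSignal, deeperNeighbor) {
  if (length(deepSignal) != length(deeperNeighbor))
    stop("deepSignal and deeperNeighbor must have equal length",
         call. = FALSE)
  deepSignal - deeperNeighbor
}

#' Morlet wavelet decomposition of one channel
#'
#' Convolves every epoch of one channel with complex Morlet wavelets
#' (Gaussian-windowed complex exponentials with a fixed number of cycles, so
#' temporal resolution scales with frequency) and returns phase (argument) and
#' amplitude (modulus) per epoch, frequency and time. Wavelets are normalised
#' so a unit-amplitude sinusoid at a grid frequency yields unit amplitude.
#' Samples within half the longest wavelet (3 Gaussian SDs at the lowest
#' frequency) of either epoch edge are trimmed to exclude edge artifacts.
#'
#' @param epochs an [EpochSet-class].
#' @param channel channel role label to decompose.
#' @param freqs ascending Hz grid; all below Nyquist.
#' @param nCycles wavelet cycles (Gaussian SD = nCycles / (2 pi f)); >= 3.
#'   Default 5.
#' @param decim keep every decim-th retained sample (time-axis decimation for
#'   large simulation studies); default 1.
#' @return a [TFAtlas-class].
#' @export
morletDecompose <- function(epochs, channel, freqs, nCycles = 5, decim = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- samplingRate(epochs)
  if (max(freqs) >= fs / 2)
    stop("all frequencies must be below the Nyquist frequency ", fs / 2,
         call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly ascending", call. = FALSE)
  if (nCycles < 3)
    stop("nCycles must be >= 3", call. = FALSE)
  ich <- match(channel, channelRoles(epochs))
  if (is.na(ich))
    stop("channel '", channel, "' not present", call. = FALSE)

  x  <- t(epochs@data[, ich, , drop = TRUE])        # samples x epochs
  if (is.null(dim(x))) x <- matrix(x, ncol = nEpochs(epochs))
  ns <- nrow(x); ne <- ncol(x)
  sigma <- nCycles / (2 * pi * freqs)
  halfLen <- ceiling(3 * sigma * fs)                # 3 SD support half-length
  Lmax <- max(halfLen)
  if (2L * Lmax >= ns)
    stop("epoch too short for the lowest frequency's wavelet", call. = FALSE)
  N  <- stats::nextn(ns + 2L * Lmax, 2)
  X  <- stats::mvfft(rbind(x, matrix(0, N - ns, ne)))

  keep <- seq.int(Lmax + 1L, ns - Lmax, by = as.integer(decim))
  nt   <- length(keep)
  ph   <- array(0, dim = c(ne, length(freqs), nt))
  am   <- array(0, dim = c(ne, length(freqs), nt))
  tw   <- seq_len(N) - 1L                            # wavelet sample index
  for (j in seq_along(freqs)) {
    L   <- halfLen[j]
    # wavelet centred at index 0, wrapped circularly; support +/- L samples
    idx <- c(0:L, (N - L):(N - 1L)) + 1L
    tt  <- c(0:L, -(L:1)) / fs
    w   <- complex(modulus = 0, argument = 0, length.out = N)
    env <- exp(-tt^2 / (2 * sigma[j]^2))
    # normalise by the discrete envelope sum so a unit cosine at the centre
    # frequency yields unit amplitude despite the 3-sigma truncation
    w[idx] <- exp(2i * pi * freqs[j] * tt) * env * (2 / sum(env))
    Wf  <- stats::fft(w)
    cv  <- stats::mvfft(X * Wf, inverse = TRUE)[keep, , drop = FALSE] / N
    ph[, j, ] <- t(Arg(cv))
    am[, j, ] <- t(Mod(cv))
  }
  new("TFAtlas",
      participantID = participantID(epochs),
      channel       = channel,
      condition     = conditions(epochs),
      freqs         = as.numeric(freqs),
      times         = epochTimes(epochs)[keep],
      phase         = ph,
      amplitude     = am)
}

#' Complex mean over a frequency band
#'
#' Collapses a [TFAtlas-class] onto one band by arithmetically averaging the
#' complex spectra amplitude * exp(i phase) over all grid frequencies inside
#' the closed band. The band phase is the argument and the band amplitude the
#' modulus of that mean, so low-amplitude bins contribute proportionally.
#'
#' @param tf a [TFAtlas-class].
#' @param band Hz pair; must intersect \code{tfFreqs(tf)}.
#' @return complex matrix, epochs x times; \code{Arg()} gives band phase,
#'   \code{Mod()} band amplitude.
#' @export
bandComplexMean <- function(tf, band) {
  stopifnot(is(tf, "TFAtlas"))
  idx <- closedIndices(tfFreqs(tf), band, "frequency band")
  z <- tf@amplitude[, idx, , drop = FALSE] *
    exp(1i * tf@phase[, idx, , drop = FALSE])
  cm <- apply(z, c(1L, 3L), mean)
  if (is.null(dim(cm)))
    cm <- matrix(cm, nrow = dim(tf@phase)[1L])
  cm
}
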