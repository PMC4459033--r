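#' Event-related potential for one channel and condition
#'
#' Each trial is band-pass filtered (zero-phase: 4th-order Butterworth applied
#' forward and backward), its prestimulus baseline mean subtracted, and the
#' trials averaged.
#'
#' @param epochs an [EpochSet-class].
#' @param channel channel role label.
#' @param condition "SE" or "UE".
#' @param filterBand Hz pair; default c(1, 8).
#' @param baselineWindow s pair; default c(-0.2, 0) (the 200 ms before
#'   stimulus onset).
#' @return an [ERPWave-class].
#' @export
computeERP <- function(epochs, channel, condition,
                       filterBand = c(1, 8), baselineWindow = c(-0.2, 0)) {
  stopifnot(is(epochs, "EpochSet"))
  t <- epochTimes(epochs)
  if (baselineWindow[1L] < min(t) || baselineWindow[2L] > max(t))
    stop("baseline window must lie inside the epoch", call. = FALSE)
  sel <- conditions(epochs) == condition
  if (!any(sel))
    stop("no epochs in condition ", condition, call. = FALSE)
  ich <- match(channel, channelRoles(epochs))
  if (is.na(ich))
    stop("channel '", channel, "' not present", call. = FALSE)

  fs  <- samplingRate(epochs)
  bf  <- signal::butter(4, filterBand / (fs / 2), type = "pass")
  bl  <- closedIndices(t, baselineWindow, "baseline window")
  x   <- epochs@data[sel, ich, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  filt <- t(apply(x, 1L, function(tr) signal::filtfilt(bf, tr)))
  filt <- filt - rowMeans(filt[, bl, drop = FALSE])
  vals <- colMeans(filt)
  vals <- vals - mean(vals[bl])       # remove residual rounding of the mean
  new("ERPWave",
      participantID = participantID(epochs), channel = channel,
      condition = condition, times = t, values = vals,
      filterBand = filterBand, baselineWindow = baselineWindow)
}

#' ERP peak extraction
#'
#' The sample of maximum absolute amplitude within the closed window; ties are
#' broken by the earliest latency.
#'
#' @param erp an [ERPWave-class].
#' @param window s pair intersecting the ERP's time axis.
#' @return list with \code{amplitude} (signed, microvolts) and \code{latency}
#'   (s).
#' @export
erpPeak <- function(erp, window) {
  stopifnot(is(erp, "ERPWave"))
  ti <- closedIndices(epochTimes(erp), window, "peak window")
  v  <- erpValues(erp)[ti]
  k  <- which.max(abs(v))            # which.max returns the first maximum
  list(amplitude = v[k], latency = epochTimes(erp)[ti][k])
}

#' Correlation between ERP magnitude and phase alignment
#'
#' Pearson correlation between the ERP time course (absolute value) and the
#' band-mean phase alignment time course over the grid times in the window,
#' pooled across the participants of one condition. Both series are evaluated
#' on the (possibly decimated) PAI time grid.
#'
#' @param erps an [ERPWave-class] or list of them (one per participant, same
#'   condition).
#' @param pais a [PAIMap-class] or list of them, matching \code{erps}.
#' @param window s pair; default c(0, 0.5), the early poststimulus period.
#' @param band Hz pair over which PAI is averaged.
#' @return a [CorrelationResult-class].
#' @export
erpAlignmentCorrelation <- function(erps, pais, window = c(0, 0.5), band) {
  if (is(erps, "ERPWave")) erps <- list(erps)
  if (is(pais, "PAIMap"))  pais <- list(pais)
  if (length(erps) != length(pais))
    stop("need one PAIMap per ERPWave", call. = FALSE)
  xs <- ys <- numeric(0)
  for (i in seq_along(erps)) {
    erp <- erps[[i]]; pai <- pais[[i]]
    ti  <- closedIndices(tfTimes(pai), window, "correlation window")
    tPai <- tfTimes(pai)[ti]
    ei  <- vapply(tPai, function(tt) which.min(abs(epochTimes(erp) - tt)),
                  integer(1))
    fi  <- closedIndices(tfFreqs(pai), band, "frequency band")
    xs  <- c(xs, abs(erpValues(erp)[ei]))
    ys  <- c(ys, colMeans(paiValues(pai)[fi, ti, drop = FALSE]))
  }
  if (length(xs) < 3L)
    stop("fewer than 3 paired points in the window", call. = FALSE)
  pearsonR(xs, ys, label = "ERP magnitude vs band-mean PAI")
}
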