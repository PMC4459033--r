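#' Configure a full pipeline run
#'
#' Bundles every band, window, scale and seed the end-to-end analysis needs,
#' so a run is fully reproducible from its configuration. Defaults follow the
#' analysis the package is built around: theta 4-8 Hz, theta/alpha 7-12 Hz,
#' broadband 4-20 Hz, coupling bands 7-8 Hz (phase) and 40-50 Hz (amplitude),
#' early window 0-0.5 s, late window 0.9-1.1 s, 1000 permutations at a 0.05
#' pointwise threshold.
#'
#' @param synth a [SynthConfig-class] used when \code{containerPath} is NULL.
#' @param containerPath optional HDF5 epoch container to analyse instead of
#'   synthesizing a cohort.
#' @param thetaBand,thetaAlphaBand,broadBand Hz pairs for the alignment
#'   windows of interest.
#' @param cfcPhaseBand,cfcAmpBand Hz pairs for theta-gamma coupling.
#' @param earlyWindow,lateWindow s pairs for the early and late alignment
#'   summaries.
#' @param cfcWindow s pair over which coupling is computed; default
#'   c(0.5, 1.5) around the late reset.
#' @param paiFreqs Hz grid for the alignment decomposition; default 4-30 Hz
#'   in 1 Hz steps. The 4 Hz floor keeps the late analysis window interior to
#'   the epoch after the longest wavelet's edge margins are trimmed.
#' @param nCycles Morlet cycles; default 5.
#' @param decim time-axis decimation of the decomposition; default 1.
#' @param cfcChannel channel carrying the coupling analysis; default "RATN".
#' @param frontalChannel the frontal channel; default "frontal".
#' @param nPermutations,alpha cluster permutation settings (1000, 0.05).
#' @param fdrQ FDR level for the correlation family; default 0.05.
#' @param nSurrogates,minShift surrogate settings for the coupling z-score.
#' @param seeds named integer list with entries \code{balancing},
#'   \code{permutation}, \code{surrogates}.
#' @param outputDir if non-NULL, TSV tables, a JSON summary and a plain-text
#'   log are written there.
#' @return a validated run configuration (list of class "plfRunConfig").
#' @seealso [runFullAnalysis()]
#' @export
runConfig <- function(synth = synthConfig(),
                      containerPath = NULL,
                      thetaBand = c(4, 8),
                      thetaAlphaBand = c(7, 12),
                      broadBand = c(4, 20),
                      cfcPhaseBand = c(7, 8),
                      cfcAmpBand = c(40, 50),
                      earlyWindow = c(0, 0.5),
                      lateWindow = c(0.9, 1.1),
                      cfcWindow = c(0.5, 1.5),
                      paiFreqs = 4:30,
                      nCycles = 5,
                      decim = 1L,
                      cfcChannel = "RATN",
                      frontalChannel = "frontal",
                      nPermutations = 1000L,
                      alpha = 0.05,
                      fdrQ = 0.05,
                      nSurrogates = 200L,
                      minShift = 0.1,
                      seeds = list(balancing = 11L, permutation = 12L,
                                   surrogates = 13L),
                      outputDir = NULL) {
  cfg <- list(synth = synth, containerPath = containerPath,
              thetaBand = thetaBand, thetaAlphaBand = thetaAlphaBand,
              broadBand = broadBand, cfcPhaseBand = cfcPhaseBand,
              cfcAmpBand = cfcAmpBand, earlyWindow = earlyWindow,
              lateWindow = lateWindow, cfcWindow = cfcWindow,
              paiFreqs = paiFreqs, nCycles = nCycles,
              decim = as.integer(decim),
              cfcChannel = cfcChannel, frontalChannel = frontalChannel,
              nPermutations = as.integer(nPermutations), alpha = alpha,
              fdrQ = fdrQ, nSurrogates = as.integer(nSurrogates),
              minShift = minShift, seeds = seeds, outputDir = outputDir)
  need <- c("balancing", "permutation", "surrogates")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(containerPath)) {
    stopifnot(is(synth, "SynthConfig"))
    nyq <- synth@samplingRate / 2
    for (b in list(thetaBand, thetaAlphaBand, broadBand, cfcPhaseBand,
                   cfcAmpBand, range(paiFreqs)))
      if (max(b) >= nyq)
        stop("band above Nyquist: ", paste(b, collapse = "-"),
             call. = FALSE)
    for (w in list(earlyWindow, lateWindow, cfcWindow))
      if (w[1L] < synth@epochWindow[1L] || w[2L] > synth@epochWindow[2L])
        stop("analysis window outside the epoch window", call. = FALSE)
  }
  class(cfg) <- "plfRunConfig"
  cfg
}

#' Run the full alignment / coupling / statistics pipeline
#'
#' Orchestrates the end-to-end analysis on a synthetic or stored cohort:
#' trial balancing, Morlet decomposition, phase-alignment maps per
#' participant/channel/condition, an SE-vs-UE cluster-size permutation test
#' per channel, per-participant window alignment summaries (early frontal
#' 7-12 Hz, early RATN 4-20 Hz, late frontal and late RATN 4-8 Hz),
#' surrogate-normalised theta-gamma coupling, frontal-RATN synchrony
#' summaries, the eight alignment-coupling correlations (four windows x two
#' conditions) with BH-FDR and SE-vs-UE Fisher comparisons, the
#' alignment-synchrony correlations, and ERPs with peaks and
#' ERP-alignment correlations. Fully reproducible from the configuration.
#'
#' @param config from [runConfig()].
#' @return a report bundle (list) with elements \code{paiMaps},
#'   \code{clusterTests}, \code{windowPAI}, \code{cfc}, \code{synchrony},
#'   \code{correlations}, \code{fisher}, \code{erps}, \code{erpPeaks},
#'   \code{erpCorrelations}, \code{params} (ground truth when synthetic) and
#'   \code{summary} (the JSON-ready summary). Written to
#'   \code{config$outputDir} when set.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "plfRunConfig"))
  t0 <- proc.time()[["elapsed"]]
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...))
    log <<- c(log, line)
    message(line)
  }

  if (is.null(config$containerPath)) {
    say("generating synthetic cohort (seed %d)", config$synth@seed)
    cohort <- generateCohort(config$synth)
    sets <- cohort$epochSets
    truth <- cohort$params
  } else {
    say("reading cohort from %s", config$containerPath)
    sets <- readEpochContainer(config$containerPath)
    truth <- NULL
  }
  nP <- length(sets)

  # validate before any computation
  for (es in sets) {
    chans <- channelRoles(es)
    for (need in unique(c(config$frontalChannel, config$cfcChannel)))
      if (!need %in% chans)
        stop("participant ", participantID(es), " lacks required channel '",
             need, "'", call. = FALSE)
  }
  chans <- channelRoles(sets[[1L]])
  seeds <- config$seeds

  paiMaps <- list()   # [[channel]][[condition]] -> list over participants
  cfcs    <- list()   # [[condition]] -> list of CFCResult
  plvLate <- plvEarly <- list(SE = numeric(nP), UE = numeric(nP))
  erps    <- list()
  erpChannels <- unique(c(config$frontalChannel, config$cfcChannel))

  cfcFreqs <- sort(unique(c(
    seq(config$cfcPhaseBand[1L], config$cfcPhaseBand[2L], by = 1),
    seq(config$cfcAmpBand[1L], config$cfcAmpBand[2L], by = 1))))

  for (p in seq_len(nP)) {
    es  <- sets[[p]]
    bal <- balanceTrials(es, seed = deriveSeed(seeds$balancing, p))
    tfs <- list()
    for (ch in chans) {
      tfs[[ch]] <- morletDecompose(bal, ch, config$paiFreqs,
                                   config$nCycles, config$decim)
      for (cond in .CONDITIONS)
        paiMaps[[ch]][[cond]][[p]] <- paiFromTF(tfs[[ch]], cond)
    }
    tfC <- morletDecompose(bal, config$cfcChannel, cfcFreqs, config$nCycles)
    for (cond in .CONDITIONS) {
      cfcs[[cond]][[p]] <- cfcFromTF(
        tfC, cond, config$cfcPhaseBand, config$cfcAmpBand, config$cfcWindow,
        config$nSurrogates, config$minShift,
        seed = deriveSeed(seeds$surrogates, p))
      sm <- plvFromTF(tfs[[config$frontalChannel]], tfs[[config$cfcChannel]],
                      cond)
      fiT <- closedIndices(tfFreqs(sm), config$thetaBand, "band")
      fiA <- closedIndices(tfFreqs(sm), config$thetaAlphaBand, "band")
      tiL <- closedIndices(tfTimes(sm), config$lateWindow, "window")
      tiE <- closedIndices(tfTimes(sm), config$earlyWindow, "window")
      plvLate[[cond]][p]  <- mean(plvValues(sm)[fiT, tiL])
      plvEarly[[cond]][p] <- mean(plvValues(sm)[fiA, tiE])
    }
    for (ch in erpChannels)
      for (cond in .CONDITIONS)
        erps[[ch]][[cond]][[p]] <- computeERP(bal, ch, cond)
    say("participant %s: decomposition, PAI, CFC, PLV, ERP done",
        participantID(es))
  }

  # SE-vs-UE cluster-size permutation test per channel
  freqsTF <- tfFreqs(paiMaps[[1L]][["SE"]][[1L]])
  timesTF <- tfTimes(paiMaps[[1L]][["SE"]][[1L]])
  stack <- function(ch, cond) {
    arr <- array(0, dim = c(nP, length(freqsTF), length(timesTF)))
    for (p in seq_len(nP)) arr[p, , ] <- paiValues(paiMaps[[ch]][[cond]][[p]])
    arr
  }
  clusterTests <- list()
  for (k in seq_along(chans)) {
    ch <- chans[k]
    clusterTests[[ch]] <- clusterSizePermutation(
      stack(ch, "SE"), stack(ch, "UE"),
      nPermutations = config$nPermutations, alpha = config$alpha,
      seed = deriveSeed(seeds$permutation, k),
      freqs = freqsTF, times = timesTF)
    say("cluster test %s: %d cluster(s)%s", ch,
        length(clusters(clusterTests[[ch]])),
        if (length(clusterP(clusterTests[[ch]])))
          sprintf(", min p = %.4g", min(clusterP(clusterTests[[ch]])))
        else "")
  }

  # per-participant window alignment summaries
  winDefs <- list(
    earlyFrontal = list(ch = config$frontalChannel,
                        band = config$thetaAlphaBand, win = config$earlyWindow),
    earlyRATN    = list(ch = config$cfcChannel,
                        band = config$broadBand, win = config$earlyWindow),
    lateFrontal  = list(ch = config$frontalChannel,
                        band = config$thetaBand, win = config$lateWindow),
    lateRATN     = list(ch = config$cfcChannel,
                        band = config$thetaBand, win = config$lateWindow))
  windowPAI <- list()
  for (w in names(winDefs)) {
    def <- winDefs[[w]]
    for (cond in .CONDITIONS)
      windowPAI[[w]][[cond]] <- vapply(
        seq_len(nP),
        function(p) windowMeanPAI(paiMaps[[def$ch]][[cond]][[p]],
                                  def$win, def$band),
        numeric(1))
  }
  miZbyCond <- lapply(.CONDITIONS, function(cond)
    vapply(cfcs[[cond]], miZ, numeric(1)))
  names(miZbyCond) <- .CONDITIONS

  # correlation battery: four alignment windows x two conditions vs coupling
  corrs <- list()
  for (w in names(winDefs)) {
    for (cond in .CONDITIONS) {
      corrs[[paste(w, cond, sep = ".")]] <- pearsonR(
        windowPAI[[w]][[cond]], miZbyCond[[cond]],
        label = sprintf("%s PAI vs %s CFC miZ (%s)", w, config$cfcChannel,
                        cond))
    }
  }
  # alignment vs frontal-RATN synchrony
  corrs[["latePLV.frontal.SE"]] <- pearsonR(
    plvLate$SE, windowPAI$lateFrontal$SE,
    label = "late frontal-RATN theta PLV vs late frontal PAI (SE)")
  corrs[["latePLV.RATN.SE"]] <- pearsonR(
    plvLate$SE, windowPAI$lateRATN$SE,
    label = "late frontal-RATN theta PLV vs late RATN PAI (SE)")
  corrs[["earlyPLV.frontal.pooled"]] <- pearsonR(
    c(plvEarly$SE, plvEarly$UE),
    c(windowPAI$earlyFrontal$SE, windowPAI$earlyFrontal$UE),
    label = "early frontal-RATN PLV vs early frontal PAI (pooled)")
  corrs[["earlyPLV.RATN.pooled"]] <- pearsonR(
    c(plvEarly$SE, plvEarly$UE),
    c(windowPAI$earlyRATN$SE, windowPAI$earlyRATN$UE),
    label = "early frontal-RATN PLV vs early RATN PAI (pooled)")
  # ERP magnitude vs early RATN alignment, pooled over time points
  erpCorrs <- list()
  for (cond in .CONDITIONS) {
    erpCorrs[[cond]] <- erpAlignmentCorrelation(
      erps[[config$cfcChannel]][[cond]],
      paiMaps[[config$cfcChannel]][[cond]],
      window = config$earlyWindow, band = config$broadBand)
    erpCorrs[[cond]]@label <- sprintf("%s ERP vs early %s PAI (%s)",
                                      config$cfcChannel, config$cfcChannel,
                                      cond)
  }
  family <- c(corrs, erpCorrs)
  family <- adjustCorrelationFamily(family, q = config$fdrQ)
  corrs <- family[seq_along(corrs)]
  erpCorrs <- family[length(corrs) + seq_along(erpCorrs)]
  say("correlation battery: %d correlations, BH-FDR at q = %g",
      length(family), config$fdrQ)

  # SE-vs-UE Fisher comparison per alignment-coupling window
  fisher <- list()
  for (w in names(winDefs)) {
    se <- corrs[[paste(w, "SE", sep = ".")]]
    ue <- corrs[[paste(w, "UE", sep = ".")]]
    fisher[[w]] <- fisherZCompare(se@r, se@n, ue@r, ue@n)
  }

  erpPeaks <- list()
  for (ch in erpChannels)
    for (cond in .CONDITIONS)
      erpPeaks[[ch]][[cond]] <- lapply(erps[[ch]][[cond]], erpPeak,
                                       window = config$earlyWindow)

  summary <- .pipelineSummary(config, chans, clusterTests, windowPAI,
                              miZbyCond, corrs, erpCorrs, fisher, nP)
  bundle <- list(paiMaps = paiMaps, clusterTests = clusterTests,
                 windowPAI = windowPAI, cfc = cfcs,
                 synchrony = list(late = plvLate, early = plvEarly),
                 correlations = corrs, fisher = fisher,
                 erps = erps, erpPeaks = erpPeaks,
                 erpCorrelations = erpCorrs,
                 params = truth, summary = summary, log = log)
  if (!is.null(config$outputDir)) {
    .writeBundle(bundle, config)
    say("outputs written to %s", config$outputDir)
    bundle$log <- log
  }
  invisible(bundle)
}

# machine-readable run summary; every statistic carries its window, band, n
# and seed provenance
.pipelineSummary <- function(config, chans, clusterTests, windowPAI,
                             miZbyCond, corrs, erpCorrs, fisher, nP) {
  winDefsOut <- list(
    earlyFrontal = list(band = config$thetaAlphaBand,
                        window = config$earlyWindow),
    earlyRATN    = list(band = config$broadBand, window = config$earlyWindow),
    lateFrontal  = list(band = config$thetaBand, window = config$lateWindow),
    lateRATN     = list(band = config$thetaBand, window = config$lateWindow))
  list(
    nParticipants = nP,
    seeds = config$seeds,
    generatorSeed = if (is.null(config$containerPath))
      config$synth@seed else NA,
    nPermutations = config$nPermutations,
    alpha = config$alpha,
    fdrQ = config$fdrQ,
    clusterTests = sapply(chans, simplify = FALSE, FUN = function(ch) {
      ct <- clusterTests[[ch]]
      list(channel = ch,
           nClusters = length(clusters(ct)),
           clusterSizes = vapply(clusters(ct), `[[`, integer(1), "size"),
           clusterSigns = vapply(clusters(ct), `[[`, numeric(1), "sign"),
           clusterP = clusterP(ct),
           maxAbsT = max(abs(tMap(ct))))
    }),
    windowPAI = lapply(names(windowPAI), function(w)
      c(list(name = w), winDefsOut[[w]],
        list(SE = windowPAI[[w]]$SE, UE = windowPAI[[w]]$UE))),
    cfc = list(phaseBand = config$cfcPhaseBand, ampBand = config$cfcAmpBand,
               window = config$cfcWindow, nSurrogates = config$nSurrogates,
               miZ = miZbyCond),
    correlations = lapply(c(corrs, erpCorrs), function(cr)
      list(label = cr@label, r = cr@r, n = cr@n, t = cr@tStat, p = cr@p,
           pFDR = cr@pFDR)),
    fisher = lapply(names(fisher), function(w) {
      fz <- fisher[[w]]
      list(name = w, z = fz@z, p = fz@p,
           rSE = fz@r1, rUE = fz@r2, n = fz@n1)
    })
  )
}

.writeBundle <- function(bundle, config) {
  dir <- config$outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paiToTSV(unlist(lapply(bundle$paiMaps,
                         function(byCond) unlist(byCond, recursive = FALSE)),
                  recursive = FALSE),
           file.path(dir, "pai_maps.tsv"))
  cfcToTSV(unlist(bundle$cfc, recursive = FALSE),
           file.path(dir, "cfc.tsv"))
  erpToTSV(unlist(lapply(bundle$erps,
                         function(byCond) unlist(byCond, recursive = FALSE)),
                  recursive = FALSE),
           file.path(dir, "erp.tsv"))
  utils::write.table(
    correlationTable(c(bundle$correlations, bundle$erpCorrelations)),
    file.path(dir, "correlations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$params))
    writeGroundTruth(bundle$params, file.path(dir, "ground_truth.tsv"))
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
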