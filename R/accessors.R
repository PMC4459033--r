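# Accessor and show methods. Slot access outside the package should go
# through these.

#' @rdname EpochSet-class
#' @export
setMethod("participantID", "EpochSet", function(x) x@participantID)
#' @rdname EpochSet-class
#' @export
setMethod("channelRoles", "EpochSet", function(x) x@channels)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname EpochSet-class
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname EpochSet-class
#' @export
setMethod("conditions", "EpochSet", function(x) x@condition)
#' @rdname EpochSet-class
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1L])
#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname TFAtlas-class
#' @export
setMethod("participantID", "TFAtlas", function(x) x@participantID)
#' @rdname TFAtlas-class
#' @export
setMethod("conditions", "TFAtlas", function(x) x@condition)
#' @rdname TFAtlas-class
#' @export
setMethod("tfFreqs", "TFAtlas", function(x) x@freqs)
#' @rdname TFAtlas-class
#' @export
setMethod("tfTimes", "TFAtlas", function(x) x@times)
#' @rdname TFAtlas-class
#' @export
setMethod("tfPhase", "TFAtlas", function(x) x@phase)
#' @rdname TFAtlas-class
#' @export
setMethod("tfAmplitude", "TFAtlas", function(x) x@amplitude)

#' @rdname PAIMap-class
#' @export
setMethod("participantID", "PAIMap", function(x) x@participantID)
#' @rdname PAIMap-class
#' @export
setMethod("conditions", "PAIMap", function(x) x@condition)
#' @rdname PAIMap-class
#' @export
setMethod("paiValues", "PAIMap", function(x) x@pai)
#' @rdname PAIMap-class
#' @export
setMethod("tfFreqs", "PAIMap", function(x) x@freqs)
#' @rdname PAIMap-class
#' @export
setMethod("tfTimes", "PAIMap", function(x) x@times)
#' @rdname PAIMap-class
#' @export
setMethod("nEpochs", "PAIMap", function(x) x@nEpochs)

#' @rdname SynchronyMap-class
#' @export
setMethod("plvValues", "SynchronyMap", function(x) x@plv)
#' @rdname SynchronyMap-class
#' @export
setMethod("tfFreqs", "SynchronyMap", function(x) x@freqs)
#' @rdname SynchronyMap-class
#' @export
setMethod("tfTimes", "SynchronyMap", function(x) x@times)

#' @rdname ERPWave-class
#' @export
setMethod("erpValues", "ERPWave", function(x) x@values)
#' @rdname ERPWave-class
#' @export
setMethod("epochTimes", "ERPWave", function(x) x@times)
#' @rdname ERPWave-class
#' @export
setMethod("participantID", "ERPWave", function(x) x@participantID)
#' @rdname ERPWave-class
#' @export
setMethod("conditions", "ERPWave", function(x) x@condition)

#' @rdname ClusterTestResult-class
#' @export
setMethod("clusters", "ClusterTestResult", function(x) x@clusters)
#' @rdname ClusterTestResult-class
#' @export
setMethod("clusterP", "ClusterTestResult", function(x) x@clusterP)
#' @rdname ClusterTestResult-class
#' @export
setMethod("nullMaxSizes", "ClusterTestResult", function(x) x@nullMaxSizes)
#' @rdname ClusterTestResult-class
#' @export
setMethod("tMap", "ClusterTestResult", function(x) x@tMap)
#' @rdname ClusterTestResult-class
#' @export
setMethod("pMap", "ClusterTestResult", function(x) x@pMap)
#' @rdname ClusterTestResult-class
#' @export
setMethod("tfFreqs", "ClusterTestResult", function(x) x@freqs)
#' @rdname ClusterTestResult-class
#' @export
setMethod("tfTimes", "ClusterTestResult", function(x) x@times)

#' @rdname CFCResult-class
#' @export
setMethod("miRaw", "CFCResult", function(x) x@miRaw)
#' @rdname CFCResult-class
#' @export
setMethod("miZ", "CFCResult", function(x) x@miZ)
#' @rdname CFCResult-class
#' @export
setMethod("participantID", "CFCResult", function(x) x@participantID)
#' @rdname CFCResult-class
#' @export
setMethod("conditions", "CFCResult", function(x) x@condition)

setMethod("show", "EpochSet", function(object) {
  tab <- table(object@condition)
  cat(sprintf(
    "EpochSet '%s': %d epochs (%s) x %d channels x %d samples @ %g Hz\n",
    object@participantID, dim(object@data)[1L],
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    length(object@channels), length(object@times), object@samplingRate))
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat(sprintf("  time: %.3f .. %.3f s (stimulus at 0)\n",
              min(object@times), max(object@times)))
})

setMethod("show", "TFAtlas", function(object) {
  cat(sprintf(
    "TFAtlas '%s' channel %s: %d epochs x %d freqs (%g-%g Hz) x %d times (%.3f..%.3f s)\n",
    object@participantID, object@channel, dim(object@phase)[1L],
    length(object@freqs), min(object@freqs), max(object@freqs),
    length(object@times), min(object@times), max(object@times)))
})

setMethod("show", "PAIMap", function(object) {
  cat(sprintf(
    "PAIMap '%s' %s/%s: %d freqs x %d times, K=%d epochs, range [%.3f, %.3f]\n",
    object@participantID, object@channel, object@condition,
    length(object@freqs), length(object@times), object@nEpochs,
    min(object@pai), max(object@pai)))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult: %d x %d map, alpha=%g, %d permutations, %d cluster(s)\n",
    nrow(object@tMap), ncol(object@tMap), object@alpha,
    length(object@nullMaxSizes), length(object@clusters)))
  if (length(object@clusters)) {
    for (i in seq_along(object@clusters)) {
      cl <- object@clusters[[i]]
      cat(sprintf("  cluster %d: size %d, sign %+d, p = %.4g\n",
                  i, cl$size, cl$sign, object@clusterP[i]))
    }
  }
})

setMethod("show", "CFCResult", function(object) {
  cat(sprintf(
    "CFCResult '%s' %s/%s: MI=%.4g uV, z=%.3f (%d surrogates, %g-%g Hz phase, %g-%g Hz amp, %.2f-%.2f s)\n",
    object@participantID, object@channel, object@condition,
    object@miRaw, object@miZ, object@nSurrogates,
    object@phaseBand[1L], object@phaseBand[2L],
    object@ampBand[1L], object@ampBand[2L],
    object@window[1L], object@window[2L]))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult%s: r = %.3f, n = %d, t = %.3f, p = %.4g%s\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              object@r, object@n, object@tStat, object@p,
              if (!is.na(object@pFDR)) sprintf(", p.FDR = %.4g", object@pFDR)
              else ""))
})

setMethod("show", "FisherComparison", function(object) {
  cat(sprintf(
    "FisherComparison: z = %.3f, p = %.4g (r1=%.3f n1=%d vs r2=%.3f n2=%d)\n",
    object@z, object@p, object@r1, object@n1, object@r2, object@n2))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d participants x %d trials/condition, %d channels @ %g Hz, window %.2f..%.2f s\n",
    object@nParticipants, object@nTrialsPerCondition,
    length(object@channelRoles), object@samplingRate,
    object@epochWindow[1L], object@epochWindow[2L]))
  cat(sprintf("  reset: kappa SE=%g UE=%g at %.2f s; early kappa=%g; PAC gain %g+/-%g, rho=%g; seed=%d\n",
              object@kappaSE, object@kappaUE, object@resetLatency,
              object@earlyResetKappa, object@pacGainMean, object@pacGainSD,
              object@participantEffectRho, object@seed))
})
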