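#' @rdname EpochSet-class
#' @param object,x an object.
#' @export
setGeneric("participantID", function(x) standardGeneric("participantID"))

#' @rdname EpochSet-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname EpochSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname EpochSet-class
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname EpochSet-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname TFAtlas-class
#' @export
setGeneric("tfFreqs", function(x) standardGeneric("tfFreqs"))

#' @rdname TFAtlas-class
#' @export
setGeneric("tfTimes", function(x) standardGeneric("tfTimes"))

#' @rdname TFAtlas-class
#' @export
setGeneric("tfPhase", function(x) standardGeneric("tfPhase"))

#' @rdname TFAtlas-class
#' @export
setGeneric("tfAmplitude", function(x) standardGeneric("tfAmplitude"))

#' @rdname PAIMap-class
#' @export
setGeneric("paiValues", function(x) standardGeneric("paiValues"))

#' @rdname SynchronyMap-class
#' @export
setGeneric("plvValues", function(x) standardGeneric("plvValues"))

#' @rdname ERPWave-class
#' @export
setGeneric("erpValues", function(x) standardGeneric("erpValues"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("clusterP", function(x) standardGeneric("clusterP"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("nullMaxSizes", function(x) standardGeneric("nullMaxSizes"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("pMap", function(x) standardGeneric("pMap"))

#' @rdname CFCResult-class
#' @export
setGeneric("miRaw", function(x) standardGeneric("miRaw"))

#' @rdname CFCResult-class
#' @export
setGeneric("miZ", function(x) standardGeneric("miZ"))
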