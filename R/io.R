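#' Write epoched recordings to an HDF5 container
#'
#' Layout: one group per participant holding dataset \code{data}
#' (epochs x channels x samples, 32-bit float, microvolts), dataset
#' \code{times} (s), dataset \code{condition} (per-epoch "SE"/"UE" strings),
#' and group attributes \code{sampling_rate} and \code{channels} (role
#' labels). Round-trips are lossless at the stored (float32) precision.
#'
#' @param epochSets an [EpochSet-class] or list of them.
#' @param path output .h5 file; overwritten if present.
#' @return invisibly, the path.
#' @export
writeEpochContainer <- function(epochSets, path) {
  if (is(epochSets, "EpochSet")) epochSets <- list(epochSets)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (es in epochSets) {
    stopifnot(is(es, "EpochSet"))
    g <- participantID(es)
    rhdf5::h5createGroup(path, g)
    d <- dim(es@data)
    rhdf5::h5createDataset(path, paste0(g, "/data"), dims = d,
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(es@data, path, paste0(g, "/data"))
    rhdf5::h5write(epochTimes(es), path, paste0(g, "/times"))
    rhdf5::h5write(conditions(es), path, paste0(g, "/condition"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(samplingRate(es), gid, "sampling_rate")
    rhdf5::h5writeAttribute(channelRoles(es), gid, "channels")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read epoched recordings from an HDF5 container
#'
#' Inverse of [writeEpochContainer()]. Unknown extra attributes or datasets
#' are ignored; a missing required member raises a format error naming it.
#'
#' @param path .h5 file written by [writeEpochContainer()] (or any container
#'   with the same layout).
#' @return list of [EpochSet-class], one per participant group, in file
#'   order.
#' @export
readEpochContainer <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  if (!length(groups))
    stop("container format error: no participant groups found",
         call. = FALSE)
  lapply(groups, function(g) {
    members <- ls$name[ls$group == paste0("/", g)]
    for (need in c("data", "times", "condition"))
      if (!need %in% members)
        stop("container format error: group '", g,
             "' is missing dataset '", need, "'", call. = FALSE)
    at <- rhdf5::h5readAttributes(path, g)
    for (need in c("sampling_rate", "channels"))
      if (!need %in% names(at))
        stop("container format error: group '", g,
             "' is missing attribute '", need, "'", call. = FALSE)
    dat <- rhdf5::h5read(path, paste0(g, "/data"))
    new("EpochSet",
        participantID = g,
        channels      = as.character(at$channels),
        samplingRate  = as.numeric(at$sampling_rate),
        times         = as.numeric(rhdf5::h5read(path, paste0(g, "/times"))),
        data          = array(as.numeric(dat), dim = dim(dat)),
        condition     = as.character(rhdf5::h5read(path,
                                                   paste0(g, "/condition"))))
  })
}

#' Long-format TSV export of PAI maps
#'
#' @param maps list of [PAIMap-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
paiToTSV <- function(maps, path) {
  if (is(maps, "PAIMap")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    grid <- expand.grid(freq = tfFreqs(m), time = tfTimes(m))
    data.frame(participant = participantID(m), channel = m@channel,
               condition = conditions(m), freq = grid$freq,
               time = grid$time, pai = as.numeric(paiValues(m)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' TSV export of CFC results
#'
#' @param cfcs list of [CFCResult-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
cfcToTSV <- function(cfcs, path) {
  if (is(cfcs, "CFCResult")) cfcs <- list(cfcs)
  df <- do.call(rbind, lapply(cfcs, function(x) data.frame(
    participant = participantID(x), channel = x@channel,
    condition = conditions(x),
    phase_lo = x@phaseBand[1L], phase_hi = x@phaseBand[2L],
    amp_lo = x@ampBand[1L], amp_hi = x@ampBand[2L],
    window_lo = x@window[1L], window_hi = x@window[2L],
    mi_raw = miRaw(x), mi_z = miZ(x), n_surrogates = x@nSurrogates)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSV export of ERPs
#'
#' @param erps list of [ERPWave-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
erpToTSV <- function(erps, path) {
  if (is(erps, "ERPWave")) erps <- list(erps)
  df <- do.call(rbind, lapply(erps, function(e) data.frame(
    participant = participantID(e), channel = e@channel,
    condition = conditions(e), time = epochTimes(e), uV = erpValues(e))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# data.frame view of a list of CorrelationResult (internal, used by the
# pipeline's TSV/JSON writers)
correlationTable <- function(corrs) {
  do.call(rbind, lapply(corrs, function(cr) data.frame(
    label = cr@label, r = cr@r, n = cr@n, t = cr@tStat, p = cr@p,
    p_fdr = cr@pFDR)))
}
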