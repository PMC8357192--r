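#' Write a scan (and optional ground truth) to a container directory
#'
#' Persists a [RawScan-class] as a simple hierarchical container: a
#' directory holding one JSON metadata file plus one raw little-endian
#' float64 binary file per named array. Layout:
#'
#' \preformatted{
#' scan/
#'   meta.json            acquisition config, preset name, array registry
#'   waveforms.bin        rows x cols x samples
#'   irf.bin              channel window samples
#'   truth_*.bin          optional ground-truth arrays
#' }
#'
#' Arrays round-trip bit-identically; `meta.json` records each array's
#' dimensions in column-major order.
#'
#' @param scan A [RawScan-class].
#' @param path Directory to create/overwrite.
#' @param truth Optional [PhantomTruth-class].
#' @param presetName Optional preset label stored in the metadata.
#' @return `path`, invisibly.
#' @seealso [readScan()]
#' @export
writeScan <- function(scan, path, truth = NULL, presetName = NULL) {
  validObject(scan)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- scan@config
  arrays <- list(waveforms = scan@waveforms, irf = scan@irf)
  if (!is.null(truth)) {
    arrays$truth_surfaceRow <- truth@surfaceRow
    arrays$truth_trueLt <- truth@trueLt
    arrays$truth_trueRatios <- truth@trueRatios
    arrays$truth_depletedMask <- truth@depletedMask + 0
    arrays$truth_depletedThicknessPerColumn <- truth@depletedThicknessPerColumn
    arrays$truth_tissueMask <- truth@tissueMask + 0
  }
  registry <- lapply(arrays, function(a) {
    d <- dim(a); if (is.null(d)) d <- length(a)
    list(dim = as.integer(d))
  })
  meta <- list(
    format = "flimcart-scan-v1",
    config = list(
      dt = cfg@dt, nSamples = cfg@nSamples,
      channelDelays = cfg@channelDelays, channelWindow = cfg@channelWindow,
      irfFwhm = cfg@irfFwhm, irfPeakOffset = cfg@irfPeakOffset,
      pixelPitch = cfg@pixelPitch, nRows = cfg@nRows, nCols = cfg@nCols,
      peakSnrDb = cfg@peakSnrDb, channelGains = cfg@channelGains,
      seed = cfg@seed, baselineFrac = cfg@baselineFrac
    ),
    preset = presetName,
    hasTruth = !is.null(truth),
    arrays = registry
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(arrays)) {
    con <- file(file.path(path, paste0(nm, ".bin")), "wb")
    writeBin(as.numeric(arrays[[nm]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a scan container directory
#'
#' @param path Directory written by [writeScan()].
#' @return A list with `scan` ([RawScan-class]), `truth`
#'   ([PhantomTruth-class] or `NULL`) and `presetName`.
#' @export
readScan <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "flimcart-scan-v1"))
    stop("not a flimcart scan container: ", path)
  cf <- meta$config
  config <- acquisitionConfig(
    dt = cf$dt, channelDelays = cf$channelDelays,
    channelWindow = cf$channelWindow, nSamples = cf$nSamples,
    irfFwhm = cf$irfFwhm, irfPeakOffset = cf$irfPeakOffset,
    pixelPitch = cf$pixelPitch, nRows = cf$nRows, nCols = cf$nCols,
    peakSnrDb = cf$peakSnrDb, channelGains = cf$channelGains,
    seed = cf$seed, baselineFrac = cf$baselineFrac
  )
  readArr <- function(nm) {
    d <- meta$arrays[[nm]]$dim
    con <- file(file.path(path, paste0(nm, ".bin")), "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
    if (length(d) > 1) array(v, dim = d) else v
  }
  scan <- new("RawScan", waveforms = readArr("waveforms"),
              irf = readArr("irf"), config = config)
  truth <- NULL
  if (isTRUE(meta$hasTruth)) {
    truth <- new("PhantomTruth",
      surfaceRow = readArr("truth_surfaceRow"),
      trueLt = readArr("truth_trueLt"),
      trueRatios = readArr("truth_trueRatios"),
      depletedMask = matrix(readArr("truth_depletedMask") > 0.5,
                            config@nRows, config@nCols),
      depletedThicknessPerColumn = readArr("truth_depletedThicknessPerColumn"),
      tissueMask = matrix(readArr("truth_tissueMask") > 0.5,
                          config@nRows, config@nCols))
  }
  list(scan = scan, truth = truth, presetName = meta$preset)
}
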