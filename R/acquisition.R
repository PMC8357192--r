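#' Construct an acquisition configuration
#'
#' Defaults describe a desk-scale emulation of a fiber-based FLIm system:
#' a 600-ps excitation pulse, three spectral channels temporally
#' multiplexed at 0/50/100 ns delays into one digitized record, 45-ns
#' analysis windows, and a 50 x 50 grid at 0.2 mm pixel pitch covering a
#' 10 mm x 10 mm cross-sectional field.
#'
#' @param dt Sampling interval (ns).
#' @param channelDelays Start offsets (ns) of the three channel windows.
#' @param channelWindow Per-channel analysis window length (ns).
#' @param nSamples Samples per record; default just covers the last window.
#' @param irfFwhm Instrument-response FWHM (ns).
#' @param irfPeakOffset Instrument-response peak position within a channel
#'   window (ns). The region before the pulse onset is used for baseline
#'   estimation.
#' @param pixelPitch Pixel size (mm); 0.2 or 0.4 in the emulated system,
#'   smaller values give fine-pitch depth profiling.
#' @param nRows,nCols Grid size.
#' @param peakSnrDb Peak signal-to-noise ratio (dB) for phantom noise.
#' @param channelGains Relative detection gains of the three channels (the
#'   ND-filter equalization of the instrument). `NA` (default) lets the
#'   phantom generator choose gains that equalize detected channel
#'   energies; measured intensities are divided by the gains before
#'   intensity ratios are formed.
#' @param seed Integer random seed for phantom generation.
#' @param baselineFrac Fraction of the record used for baseline estimation.
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' cfg <- acquisitionConfig()
#' cfg
#' @export
acquisitionConfig <- function(dt = 0.08,
                              channelDelays = c(0, 50, 100),
                              channelWindow = 45,
                              nSamples = NULL,
                              irfFwhm = 0.6,
                              irfPeakOffset = 2.0,
                              pixelPitch = 0.2,
                              nRows = 50L, nCols = 50L,
                              peakSnrDb = 40,
                              channelGains = rep(NA_real_, 3),
                              seed = 1L,
                              baselineFrac = 0.05) {
  if (is.null(nSamples))
    nSamples <- as.integer(ceiling((max(channelDelays) + channelWindow) / dt))
  new("AcquisitionConfig",
      dt = dt, nSamples = as.integer(nSamples),
      channelDelays = as.numeric(channelDelays),
      channelWindow = channelWindow, irfFwhm = irfFwhm,
      irfPeakOffset = irfPeakOffset, pixelPitch = pixelPitch,
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      peakSnrDb = peakSnrDb, channelGains = as.numeric(channelGains),
      seed = as.integer(seed), baselineFrac = baselineFrac)
}

# internal: per-channel start indices (1-based) of the windows in a record
.channelStarts <- function(config) {
  as.integer(round(config@channelDelays / config@dt)) + 1L
}

# internal: number of quiet baseline samples at the head of the record.
# Capped to the region before the first channel's pulse onset (peak offset
# minus 4 sigma of the Gaussian iRF) so signal never leaks into the
# baseline estimate.
.baselineSamples <- function(config) {
  sigma <- config@irfFwhm / (2 * sqrt(2 * log(2)))
  onset <- config@channelDelays[1] + config@irfPeakOffset - 4 * sigma
  n <- floor(min(config@baselineFrac * config@nSamples, onset / config@dt))
  max(2L, as.integer(n))
}
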