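#' @import methods
NULL

#' Acquisition configuration for a multiplexed FLIm scan
#'
#' Describes the digitizer and scan geometry of a fiber-based FLIm
#' acquisition in which three spectral channels are temporally multiplexed
#' into a single record per pixel via delay fibers.
#'
#' @slot dt Sampling interval (ns).
#' @slot nSamples Samples per full multiplexed record.
#' @slot channelDelays Offsets (ns) at which each spectral channel's pulse
#'   starts within the record.
#' @slot channelWindow Per-channel analysis window length (ns).
#' @slot irfFwhm Instrument response FWHM (ns); dominated by the excitation
#'   pulse width.
#' @slot irfPeakOffset Position (ns) of the instrument-response peak within
#'   each channel window; leaves a quiet pre-pulse region used for baseline
#'   estimation.
#' @slot pixelPitch Lateral/axial pixel size (mm).
#' @slot nRows,nCols Image grid size (rows index depth, columns lateral
#'   position).
#' @slot peakSnrDb Peak signal-to-noise ratio (dB) used by the phantom
#'   generator.
#' @slot channelGains Relative detection gains of the three channels
#'   (emulating the neutral-density filters that equalize channel
#'   intensities at the detector). Measured intensities are divided by
#'   these before ratio computation. `NA` lets the phantom generator pick
#'   energy-equalizing gains.
#' @slot seed Random seed for reproducible phantom generation.
#' @slot baselineFrac Fraction of the record used for baseline estimation
#'   (capped to the quiet region before signal onset).
#' @seealso [acquisitionConfig()]
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    dt = "numeric", nSamples = "integer", channelDelays = "numeric",
    channelWindow = "numeric", irfFwhm = "numeric", irfPeakOffset = "numeric",
    pixelPitch = "numeric", nRows = "integer", nCols = "integer",
    peakSnrDb = "numeric", channelGains = "numeric", seed = "integer",
    baselineFrac = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character(0)
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
  if (length(object@channelDelays) != 3L)
    msg <- c(msg, "channelDelays must have length 3")
  d <- sort(object@channelDelays)
  if (any(diff(d) < object@channelWindow - 1e-9))
    msg <- c(msg, "channel windows overlap: delays closer than channelWindow")
  if (max(object@channelDelays) + object@channelWindow >
      object@nSamples * object@dt + 1e-9)
    msg <- c(msg, "channel windows do not fit inside the record")
  if (object@nRows * object@pixelPitch > 10 + 1e-9 ||
      object@nCols * object@pixelPitch > 10 + 1e-9)
    msg <- c(msg, "grid exceeds the 10 mm x 10 mm scan area")
  if (object@irfPeakOffset < 0 ||
      object@irfPeakOffset >= object@channelWindow)
    msg <- c(msg, "irfPeakOffset must lie inside the channel window")
  if (length(object@channelGains) != 3L)
    msg <- c(msg, "channelGains must have length 3")
  else if (!all(is.na(object@channelGains)) &&
           any(object@channelGains <= 0, na.rm = TRUE))
    msg <- c(msg, "channelGains must be positive")
  if (length(msg)) msg else TRUE
})

#' Tissue preset: generator ground truth for one treatment condition
#'
#' Holds the per-condition optical truth used by the phantom generator:
#' channel lifetimes (with a superficial-to-deep channel-1 ramp), spectral
#' intensity-ratio triples for healthy and GAG-depleted cartilage, and the
#' thickness of the depleted superficial layer.
#'
#' @slot name One of `"control"`, `"low"`, `"high"` (chondroitinase ABC
#'   treatment intensity).
#' @slot ltCh1Surface,ltCh1Deep Channel-1 average lifetime (ns) at the
#'   articular surface and in the middle/deep zones.
#' @slot ltRampDepth Depth (mm) over which the channel-1 lifetime ramps
#'   linearly from the surface to the deep value.
#' @slot ltCh2,ltCh3 Healthy channel-2/3 average lifetimes (ns).
#' @slot ltCh2Depleted,ltCh3Depleted Channel-2/3 lifetimes (ns) inside the
#'   GAG-depleted layer.
#' @slot ratiosHealthy,ratiosDepleted Intensity-ratio triples (3-simplex).
#' @slot depletedThickness Mean thickness (mm) of the depleted layer.
#' @slot surfaceFn Function mapping lateral position (mm) to cartilage
#'   surface depth from the image top (mm); allows tilt/curvature.
#' @seealso [tissuePreset()]
#' @exportClass TissuePreset
setClass("TissuePreset",
  representation(
    name = "character",
    ltCh1Surface = "numeric", ltCh1Deep = "numeric", ltRampDepth = "numeric",
    ltCh2 = "numeric", ltCh3 = "numeric",
    ltCh2Depleted = "numeric", ltCh3Depleted = "numeric",
    ratiosHealthy = "numeric", ratiosDepleted = "numeric",
    depletedThickness = "numeric", surfaceFn = "function"
  )
)

setValidity("TissuePreset", function(object) {
  msg <- character(0)
  for (nm in c("ratiosHealthy", "ratiosDepleted")) {
    r <- slot(object, nm)
    if (length(r) != 3L) msg <- c(msg, paste(nm, "must have length 3"))
    else {
      if (abs(sum(r) - 1) > 1e-12) msg <- c(msg, paste(nm, "must sum to 1 within 1e-12"))
      if (any(r <= 0 | r >= 1)) msg <- c(msg, paste(nm, "components must lie in (0,1)"))
    }
  }
  if (object@depletedThickness < 0) msg <- c(msg, "depletedThickness must be >= 0")
  if (identical(object@name, "control") && object@depletedThickness != 0)
    msg <- c(msg, "control preset must have depletedThickness = 0")
  if (length(msg)) msg else TRUE
})

#' Raw multiplexed FLIm scan
#'
#' The pipeline's sole measured input: one digitized record per pixel
#' containing the three time-shifted spectral-channel decays, plus the
#' measured instrument response and acquisition metadata.
#'
#' @slot waveforms Numeric array `nRows x nCols x nSamples` (arbitrary
#'   intensity units). May contain small negative values after noise.
#' @slot irf Instrument-response trace, one channel window long, unit area.
#' @slot config The [AcquisitionConfig-class] the scan was acquired with.
#' @seealso [makePhantom()], [readScan()], [buildMaps()]
#' @exportClass RawScan
setClass("RawScan",
  representation(waveforms = "array", irf = "numeric",
                 config = "AcquisitionConfig")
)

setValidity("RawScan", function(object) {
  d <- dim(object@waveforms)
  cfg <- object@config
  if (length(d) != 3L) return("waveforms must be a 3-d array (rows x cols x samples)")
  if (d[1] != cfg@nRows || d[2] != cfg@nCols || d[3] != cfg@nSamples)
    return("waveforms dimensions disagree with config")
  nw <- .windowSamples(cfg)
  if (length(object@irf) != nw)
    return("irf length must equal the channel window in samples")
  TRUE
})

#' Phantom ground truth
#'
#' Per-pixel truth emitted alongside a synthetic scan; stands in for the
#' histology ground truth of a real experiment.
#'
#' @slot surfaceRow Per-column cartilage surface position as a fractional
#'   row coordinate (row centers at integers, boundary between rows r and
#'   r+1 at r + 0.5).
#' @slot trueLt `nRows x nCols x 3` true average lifetimes (ns), `NA`
#'   outside tissue.
#' @slot trueRatios `nRows x nCols x 3` true intensity-ratio triples.
#' @slot depletedMask Logical matrix marking GAG-depleted tissue pixels.
#' @slot depletedThicknessPerColumn Depleted-layer thickness per column (mm),
#'   equal to the per-column depleted pixel count times the pixel pitch.
#' @slot tissueMask Logical matrix marking tissue (vs. PBS background).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    surfaceRow = "numeric", trueLt = "array", trueRatios = "array",
    depletedMask = "matrix", depletedThicknessPerColumn = "numeric",
    tissueMask = "matrix"
  )
)

setValidity("PhantomTruth", function(object) {
  if (any(object@depletedMask & !object@tissueMask))
    return("depletedMask must be a subset of tissueMask")
  if (any(object@depletedThicknessPerColumn < 0))
    return("depleted thickness must be >= 0")
  TRUE
})

#' A single demultiplexed channel decay
#'
#' Background-subtracted, windowed single-channel time trace for one pixel,
#' ready for deconvolution. Negative noise excursions are preserved.
#'
#' @slot samples Trace values (arbitrary units), one channel window long.
#' @slot dt Sampling interval (ns).
#' @slot channelIndex Spectral channel, 1..3.
#' @slot pixelCoord Integer `(row, col)` of the source pixel.
#' @seealso [demultiplex()]
#' @exportClass ChannelDecay
setClass("ChannelDecay",
  representation(samples = "numeric", dt = "numeric",
                 channelIndex = "integer", pixelCoord = "integer")
)

#' Discrete-time Laguerre basis
#'
#' Orthonormal basis of exponentially decaying discrete Laguerre functions
#' used to expand the fluorescence impulse response. Columns are generated
#' by the standard recurrence and re-orthonormalized on the finite window,
#' so `crossprod(B)` is the identity to near machine precision.
#'
#' @slot alpha Scale parameter in (0,1); larger alpha stretches the basis
#'   to longer times.
#' @slot order Number of basis functions.
#' @slot length Number of samples per basis function.
#' @slot B `length x order` basis matrix with orthonormal columns.
#' @seealso [laguerreBasis()], [deconvolve()]
#' @exportClass LaguerreBasis
setClass("LaguerreBasis",
  representation(alpha = "numeric", order = "integer", length = "integer",
                 B = "matrix")
)

setValidity("LaguerreBasis", function(object) {
  if (!all(dim(object@B) == c(object@length, object@order)))
    return("B dimensions disagree with length/order")
  g <- crossprod(object@B)
  if (max(abs(g - diag(object@order))) > 1e-8)
    return("basis columns are not orthonormal")
  TRUE
})

#' Result of constrained Laguerre deconvolution for one decay
#'
#' @slot coeffs Laguerre expansion coefficients.
#' @slot h Reconstructed fluorescence impulse response (non-negative up to
#'   a -1e-12 numerical tolerance).
#' @slot avgLifetime Average lifetime (ns): first moment of `h` normalized
#'   by its area.
#' @slot intensity Integrated area of the refitted observation
#'   (irf convolved with `h`, times dt).
#' @slot residualRms Root-mean-square residual as a fraction of the signal
#'   RMS.
#' @slot converged Whether the active-set solver converged.
#' @slot dt Sampling interval (ns).
#' @seealso [deconvolve()]
#' @exportClass DeconvResult
setClass("DeconvResult",
  representation(coeffs = "numeric", h = "numeric", avgLifetime = "numeric",
                 intensity = "numeric", residualRms = "numeric",
                 converged = "logical", dt = "numeric")
)

#' Per-pixel FLIm image stack
#'
#' Assembled per-pixel results: average-lifetime, integrated-intensity and
#' intensity-ratio images for the three spectral channels plus a validity
#' mask. Invalid pixels (background or non-converged) carry `NA` in all
#' layers. Row 1 is the top of the image (above the cartilage surface);
#' row index increases with depth.
#'
#' @slot lt `nRows x nCols x 3` average lifetime (ns).
#' @slot intensity `nRows x nCols x 3` integrated intensity (a.u.).
#' @slot ratio `nRows x nCols x 3` intensity ratios; sums to 1 at valid
#'   pixels.
#' @slot valid Logical matrix of valid pixels.
#' @slot pixelPitch Pixel size (mm).
#' @seealso [buildMaps()], [exportMaps()]
#' @exportClass FLImMaps
setClass("FLImMaps",
  representation(lt = "array", intensity = "array", ratio = "array",
                 valid = "matrix", pixelPitch = "numeric")
)

setValidity("FLImMaps", function(object) {
  d <- dim(object@lt)
  if (length(d) != 3L || d[3] != 3L) return("lt must be rows x cols x 3")
  if (!all(dim(object@intensity) == d) || !all(dim(object@ratio) == d))
    return("lt, intensity and ratio must share dimensions")
  if (!all(dim(object@valid) == d[1:2])) return("valid mask dimension mismatch")
  if (any(object@valid)) {
    s <- apply(object@ratio, c(1, 2), sum)
    if (max(abs(s[object@valid] - 1)) > 1e-9)
      return("ratios at valid pixels must sum to 1 within 1e-9")
  }
  if (any(!is.na(object@lt[!.expandMask(object@valid)])))
    return("invalid pixels must carry NA in all layers")
  TRUE
})

#' Detected cartilage surface
#'
#' Per-column surface location found at the maximum depth gradient of total
#' fluorescence intensity, with sub-pixel parabolic refinement.
#'
#' @slot surfaceRow Fractional row coordinate of the surface per column
#'   (`NA` where no surface was found).
#' @slot confidence Peak gradient magnitude per column.
#' @slot valid Logical: columns with a detected surface.
#' @seealso [detectSurface()], [distanceMap()]
#' @exportClass SurfaceMap
setClass("SurfaceMap",
  representation(surfaceRow = "numeric", confidence = "numeric",
                 valid = "logical")
)

#' Depth-resolved lifetime profile
#'
#' Distribution summaries of average lifetime binned by distance from the
#' cartilage surface, per spectral channel.
#'
#' @slot table Data frame with columns `bin_lo`, `bin_hi`, `channel`, `n`,
#'   `mean`, `sd`, `min`, `q1`, `median`, `q3`, `max`.
#' @slot binWidth Bin width (mm).
#' @seealso [depthProfile()]
#' @exportClass DepthProfile
setClass("DepthProfile",
  representation(table = "data.frame", binWidth = "numeric")
)

#' Threshold segmentation of the GAG-depleted layer
#'
#' @slot depletedMask Logical matrix of pixels classified as depleted.
#' @slot thicknessPerColumn Depleted thickness per column (mm).
#' @slot meanThickness Mean thickness over tissue columns (mm).
#' @slot threshold Channel-1 intensity-ratio threshold used.
#' @seealso [segmentDepletion()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(depletedMask = "matrix", thicknessPerColumn = "numeric",
                 meanThickness = "numeric", threshold = "numeric")
)

setValidity("SegmentationResult", function(object) {
  if (any(object@thicknessPerColumn < 0, na.rm = TRUE))
    return("thickness must be >= 0")
  TRUE
})

#' ROC analysis for threshold selection
#'
#' @slot thresholds Candidate thresholds (midpoints between sorted unique
#'   values, plus outer sentinels).
#' @slot tpr,fpr True/false positive rates at each threshold.
#' @slot auc Area under the ROC curve (trapezoid rule).
#' @slot chosenThreshold Threshold maximizing Youden's J.
#' @seealso [rocThreshold()]
#' @exportClass ROCResult
setClass("ROCResult",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric", chosenThreshold = "numeric")
)

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr and fpr must be non-decreasing along sorted thresholds")
  TRUE
})

#' Group comparison: one-way ANOVA with Tukey HSD
#'
#' @slot groupStats Data frame of per-group n, mean and SD.
#' @slot fStatistic One-way ANOVA F statistic (`NA` if degenerate).
#' @slot pValue ANOVA p-value.
#' @slot pairwise Data frame of pairwise mean differences and Tukey-adjusted
#'   p-values.
#' @slot degenerate TRUE when within-group variance is zero and F is
#'   undefined.
#' @seealso [compareGroups()]
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(groupStats = "data.frame", fStatistic = "numeric",
                 pValue = "numeric", pairwise = "data.frame",
                 degenerate = "logical")
)

# internal: expand a rows x cols logical mask across 3 channels
.expandMask <- function(m) array(rep(m, 3L), dim = c(dim(m), 3L))

# internal: channel window length in samples
.windowSamples <- function(config) as.integer(round(config@channelWindow / config@dt))
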