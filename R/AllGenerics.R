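#' Accessors for flimcart objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object A flimcart S4 object.
#' @param channel Spectral channel index (1..3); `NULL` returns all three.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lifetimeMap", function(object, channel = NULL) standardGeneric("lifetimeMap"))

#' @rdname accessors
#' @export
setGeneric("intensityMap", function(object, channel = NULL) standardGeneric("intensityMap"))

#' @rdname accessors
#' @export
setGeneric("ratioMap", function(object, channel = NULL) standardGeneric("ratioMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("surfaceRow", function(object) standardGeneric("surfaceRow"))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setGeneric("avgLifetime", function(object) standardGeneric("avgLifetime"))

#' @rdname accessors
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))

#' @rdname accessors
#' @export
setGeneric("meanThickness", function(object) standardGeneric("meanThickness"))

#' @rdname accessors
#' @export
setGeneric("depletedMask", function(object) standardGeneric("depletedMask"))

#' @rdname accessors
#' @export
setGeneric("chosenThreshold", function(object) standardGeneric("chosenThreshold"))

#' @rdname accessors
#' @export
setGeneric("rocAuc", function(object) standardGeneric("rocAuc"))

setMethod("lifetimeMap", "FLImMaps", function(object, channel = NULL) {
  if (is.null(channel)) object@lt else object@lt[, , channel]
})
setMethod("intensityMap", "FLImMaps", function(object, channel = NULL) {
  if (is.null(channel)) object@intensity else object@intensity[, , channel]
})
setMethod("ratioMap", "FLImMaps", function(object, channel = NULL) {
  if (is.null(channel)) object@ratio else object@ratio[, , channel]
})
setMethod("validMask", "FLImMaps", function(object) object@valid)
setMethod("pixelPitch", "FLImMaps", function(object) object@pixelPitch)
setMethod("surfaceRow", "SurfaceMap", function(object) object@surfaceRow)
setMethod("surfaceRow", "PhantomTruth", function(object) object@surfaceRow)
setMethod("basisMatrix", "LaguerreBasis", function(object) object@B)
setMethod("avgLifetime", "DeconvResult", function(object) object@avgLifetime)
setMethod("profileTable", "DepthProfile", function(object) object@table)
setMethod("meanThickness", "SegmentationResult", function(object) object@meanThickness)
setMethod("depletedMask", "SegmentationResult", function(object) object@depletedMask)
setMethod("depletedMask", "PhantomTruth", function(object) object@depletedMask)
setMethod("chosenThreshold", "ROCResult", function(object) object@chosenThreshold)
setMethod("rocAuc", "ROCResult", function(object) object@auc)

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:", object@nRows, "x", object@nCols, "pixels @",
      object@pixelPitch, "mm\n")
  cat("  dt:", object@dt, "ns |", object@nSamples, "samples | window:",
      object@channelWindow, "ns\n")
  cat("  channel delays (ns):", paste(object@channelDelays, collapse = ", "),
      "| iRF FWHM:", object@irfFwhm, "ns\n")
})

setMethod("show", "TissuePreset", function(object) {
  cat("TissuePreset <", object@name, ">\n", sep = "")
  cat("  ch1 LT:", object@ltCh1Surface, "->", object@ltCh1Deep, "ns over",
      object@ltRampDepth, "mm\n")
  cat("  ch2/ch3 LT (healthy):", object@ltCh2, "/", object@ltCh3, "ns",
      "(depleted:", object@ltCh2Depleted, "/", object@ltCh3Depleted, "ns)\n")
  cat("  ratios healthy:", paste(round(object@ratiosHealthy, 4), collapse = ", "), "\n")
  cat("  ratios depleted:", paste(round(object@ratiosDepleted, 4), collapse = ", "), "\n")
  cat("  depleted thickness:", object@depletedThickness, "mm\n")
})

setMethod("show", "RawScan", function(object) {
  d <- dim(object@waveforms)
  cat("RawScan:", d[1], "x", d[2], "pixels,", d[3], "samples/record\n")
  show(object@config)
})

setMethod("show", "FLImMaps", function(object) {
  d <- dim(object@lt)
  cat("FLImMaps:", d[1], "x", d[2], "pixels, 3 channels @",
      object@pixelPitch, "mm\n")
  cat("  valid pixels:", sum(object@valid), "/", prod(d[1:2]), "\n")
  for (k in 1:3) {
    v <- object@lt[, , k][object@valid]
    if (length(v)) cat(sprintf("  ch%d LT: %.2f - %.2f ns (median %.2f)\n",
                               k, min(v), max(v), stats::median(v)))
  }
})

setMethod("show", "LaguerreBasis", function(object) {
  cat("LaguerreBasis: alpha =", object@alpha, ", order =", object@order,
      ", length =", object@length, "samples\n")
})

setMethod("show", "DeconvResult", function(object) {
  cat(sprintf("DeconvResult: avg lifetime %.3f ns, intensity %.4g, residual %.3g%s\n",
              object@avgLifetime, object@intensity, object@residualRms,
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "SurfaceMap", function(object) {
  cat("SurfaceMap:", sum(object@valid), "/", length(object@valid),
      "columns with detected surface\n")
  if (any(object@valid))
    cat(sprintf("  surface row: %.2f - %.2f\n",
                min(object@surfaceRow[object@valid]),
                max(object@surfaceRow[object@valid])))
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile:", length(unique(object@table$bin_lo)), "bins of",
      object@binWidth, "mm x 3 channels\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: mean depleted thickness %.3f mm (threshold %.3g)\n",
              object@meanThickness, object@threshold))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC %.4f, chosen threshold %.4f (Youden)\n",
              object@auc, object@chosenThreshold))
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison (one-way ANOVA + Tukey HSD)\n")
  print(object@groupStats)
  if (object@degenerate) cat("  F undefined: zero within-group variance\n")
  else cat(sprintf("  F = %.4g, p = %.4g\n", object@fStatistic, object@pValue))
  print(object@pairwise)
})
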