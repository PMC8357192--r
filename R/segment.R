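#' ROC analysis for the depletion threshold
#'
#' Sweeps all midpoints between sorted unique values of the channel-1
#' intensity ratio, treating `value < threshold` as a positive
#' (GAG-depleted) call, and selects the threshold maximizing Youden's
#' J = TPR - FPR. Ties are broken toward the threshold nearest the
#' midpoint of the two class means. AUC is computed by the trapezoid rule.
#'
#' @param values Per-pixel channel-1 intensity ratios.
#' @param labels Logical (or 0/1) per-pixel truth: `TRUE` = depleted.
#' @return A [ROCResult-class].
#' @examples
#' roc <- rocThreshold(c(0.1, 0.15, 0.3, 0.35), c(TRUE, TRUE, FALSE, FALSE))
#' rocAuc(roc)
#' @export
rocThreshold <- function(values, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  u <- sort(unique(values))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  thr <- c(u[1] - 1, mids, u[length(u)] + 1)
  nPos <- sum(labels); nNeg <- sum(!labels)
  tpr <- vapply(thr, function(s) sum(values < s & labels) / nPos, numeric(1))
  fpr <- vapply(thr, function(s) sum(values < s & !labels) / nNeg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    anchor <- (mean(values[labels]) + mean(values[!labels])) / 2
    best <- best[which.min(abs(thr[best] - anchor))]
  }
  new("ROCResult", thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
      chosenThreshold = thr[best])
}

#' Segment the GAG-depleted superficial layer
#'
#' Per column, labels as depleted the contiguous run of valid tissue
#' pixels starting at the detected surface whose channel-1 intensity ratio
#' falls below the threshold (0.25 by default, the ROC operating point).
#' Isolated deep below-threshold pixels are not counted: GAG depletion
#' proceeds from the surface inward. Thickness is the run length times
#' the pixel pitch; the mean is over columns with tissue.
#'
#' @param maps A [FLImMaps-class].
#' @param surface A [SurfaceMap-class].
#' @param threshold Channel-1 intensity-ratio threshold.
#' @return A [SegmentationResult-class].
#' @export
segmentDepletion <- function(maps, surface, threshold = 0.25) {
  nr <- nrow(maps@valid); nc <- ncol(maps@valid)
  r1 <- maps@ratio[, , 1]
  mask <- matrix(FALSE, nr, nc)
  thick <- rep(NA_real_, nc)
  for (cc in seq_len(nc)) {
    if (!surface@valid[cc] || is.na(surface@surfaceRow[cc])) next
    rStart <- floor(surface@surfaceRow[cc]) + 1L
    if (rStart > nr) next
    run <- 0L
    for (rr in rStart:nr) {
      if (!maps@valid[rr, cc] || is.na(r1[rr, cc]) ||
          r1[rr, cc] >= threshold) break
      mask[rr, cc] <- TRUE
      run <- run + 1L
    }
    thick[cc] <- run * maps@pixelPitch
  }
  if (all(is.na(thick))) stop("no tissue columns to segment")
  new("SegmentationResult", depletedMask = mask,
      thicknessPerColumn = thick,
      meanThickness = mean(thick, na.rm = TRUE), threshold = threshold)
}

#' Summarize lifetimes and ratios over a region of interest
#'
#' Arithmetic means over the valid pixels of a region of interest, per
#' channel. In the phantom workflow the ROI comes from generator truth
#' masks, replacing the manual histology-guided ROIs of a real
#' experiment.
#'
#' @param maps A [FLImMaps-class].
#' @param roiMask Logical matrix selecting the ROI.
#' @return A list with `meanLt`, `meanRatio`, `meanIntensity` (each length
#'   3) and `n`, the number of contributing pixels.
#' @export
roiSummary <- function(maps, roiMask) {
  sel <- roiMask & maps@valid
  if (!any(sel)) stop("ROI does not intersect any valid pixel")
  list(
    meanLt = vapply(1:3, function(k) mean(maps@lt[, , k][sel]), numeric(1)),
    meanRatio = vapply(1:3, function(k) mean(maps@ratio[, , k][sel]), numeric(1)),
    meanIntensity = vapply(1:3, function(k) mean(maps@intensity[, , k][sel]), numeric(1)),
    n = sum(sel)
  )
}
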