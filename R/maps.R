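#' Build per-pixel FLIm maps from a raw scan
#'
#' Runs the full per-pixel chain: demultiplex each record into three
#' channel decays, deconvolve each decay against the instrument response
#' on a Laguerre basis, and assemble average-lifetime, intensity and
#' intensity-ratio images. Background pixels (record peak below
#' `minPeakFrac` of the scan maximum) and non-converged pixels are masked
#' with `NA`. Intensities are corrected for the configured channel
#' detection gains before ratios are formed, and each pixel is processed
#' independently, so the result does not depend on processing order.
#'
#' @param scan A [RawScan-class].
#' @param order Laguerre basis order.
#' @param alpha Laguerre scale: a single value, one per channel, or
#'   `"auto"` to calibrate per channel by residual grid search
#'   ([calibrateAlpha()]).
#' @param minPeakFrac Background threshold as a fraction of the scan's
#'   maximum peak amplitude.
#' @param maxIter Active-set iteration cap per decay.
#' @return A [FLImMaps-class].
#' @examples
#' ph <- makePhantom(acquisitionConfig(nRows = 10L, nCols = 6L),
#'                   tissuePreset("control"), noise = FALSE)
#' m <- buildMaps(ph$scan, alpha = 0.95)
#' @export
buildMaps <- function(scan, order = 12L, alpha = "auto",
                      minPeakFrac = 0.05, maxIter = 200L) {
  validObject(scan)
  cfg <- scan@config
  nr <- cfg@nRows; nc <- cfg@nCols
  nw <- .windowSamples(cfg)
  fg <- foregroundMask(scan, minPeakFrac)
  gains <- cfg@channelGains
  if (all(is.na(gains))) gains <- c(1, 1, 1)

  # demultiplex every pixel once against the pooled scan-level baseline;
  # decays[[k]] is samples x pixels
  base <- scanBaseline(scan)
  decays <- lapply(1:3, function(k) matrix(0, nw, nr * nc))
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    m <- .demuxMatrix(scan@waveforms[rr, cc, ], cfg, baseline = base)
    j <- (cc - 1L) * nr + rr
    for (k in 1:3) decays[[k]][, j] <- m[, k]
  }
  fgIdx <- which(as.vector(fg))

  if (identical(alpha, "auto")) {
    alpha <- vapply(1:3, function(k)
      calibrateAlpha(decays[[k]][, fgIdx, drop = FALSE], scan@irf, cfg@dt,
                     order = order), numeric(1))
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, 3L)

  lt <- array(NA_real_, c(nr, nc, 3))
  intensity <- array(NA_real_, c(nr, nc, 3))
  ratio <- array(NA_real_, c(nr, nc, 3))
  conv <- matrix(TRUE, nr, nc)

  designs <- lapply(1:3, function(k)
    .laguerreDesign(laguerreBasis(alpha[k], order, nw), scan@irf, cfg@dt))

  for (j in fgIdx) {
    rr <- (j - 1L) %% nr + 1L
    cc <- (j - 1L) %/% nr + 1L
    ok <- TRUE
    vals <- matrix(NA_real_, 3, 2)
    for (k in 1:3) {
      r <- .deconvolveDesign(decays[[k]][, j], designs[[k]], maxIter)
      if (!r@converged || r@intensity <= 0) { ok <- FALSE; break }
      vals[k, ] <- c(r@avgLifetime, r@intensity)
    }
    if (!ok) { conv[rr, cc] <- FALSE; next }
    lt[rr, cc, ] <- vals[, 1]
    intensity[rr, cc, ] <- vals[, 2]
    ratio[rr, cc, ] <- intensityRatio(vals[, 2] / gains)
  }

  nBad <- sum(!conv[fg])
  if (nBad > 0.2 * length(fgIdx))
    warning(nBad, " of ", length(fgIdx),
            " foreground pixels failed to converge")
  valid <- fg & conv
  lt[!.expandMask(valid)] <- NA_real_
  intensity[!.expandMask(valid)] <- NA_real_
  ratio[!.expandMask(valid)] <- NA_real_
  new("FLImMaps", lt = lt, intensity = intensity, ratio = ratio,
      valid = valid, pixelPitch = cfg@pixelPitch)
}
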