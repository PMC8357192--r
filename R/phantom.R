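#' Generate a synthetic cross-sectional cartilage FLIm scan
#'
#' Builds a raw multiplexed scan with known ground truth emulating a
#' cross-sectional FLIm acquisition of a cartilage explant in PBS. For
#' every tissue pixel three channel decays are synthesized
#' ([synthDecay()]; channel-1 lifetime ramps linearly with depth from the
#' superficial to the deep value, channel-2/3 lifetimes and the
#' intensity-ratio triple switch to depleted values inside the GAG-depleted
#' layer), convolved with the instrument response, scaled so the in-window
#' channel energies match the preset's ratio triple, and placed at the
#' channel delays in one record, after applying the configured per-channel
#' detection gains (the instrument's ND-filter equalization, which keeps
#' all three channels at comparable signal level at the detector). Pixels
#' above the cartilage surface (PBS) carry no signal. Noise is additive Gaussian scaled to the configured
#' peak SNR with a Poisson-like signal-dependent variance term,
#' reproducible from `config@seed`.
#'
#' The per-column depleted pixel count is dithered (Bresenham-style) so the
#' column-mean depleted thickness equals the preset thickness exactly even
#' when it is not a multiple of the pixel pitch.
#'
#' @param config An [AcquisitionConfig-class].
#' @param preset A [TissuePreset-class].
#' @param noise Set `FALSE` for a noiseless scan (model development and
#'   exactness tests).
#' @return A list with elements `scan` ([RawScan-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- makePhantom(acquisitionConfig(nRows = 12L, nCols = 8L),
#'                   tissuePreset("control"), noise = FALSE)
#' dim(ph$scan@waveforms)
#' @export
makePhantom <- function(config, preset, noise = TRUE) {
  validObject(config); validObject(preset)
  if (all(is.na(config@channelGains))) {
    # emulate the ND-filter equalization: attenuate so detected channel
    # energies match, keeping the strongest channel's gain at 1
    config@channelGains <- min(preset@ratiosHealthy) / preset@ratiosHealthy
  }
  gains <- config@channelGains
  nr <- config@nRows; nc <- config@nCols
  p <- config@pixelPitch
  dt <- config@dt
  nw <- .windowSamples(config)
  irf <- makeIrf(config)
  starts <- .channelStarts(config)

  xLat <- (seq_len(nc) - 0.5) * p           # lateral center of each column
  surfMm <- preset@surfaceFn(xLat)
  # first tissue row: smallest row whose center lies at or below the surface
  firstRow <- pmax(1L, as.integer(ceiling(surfMm / p + 0.5)))
  if (any(firstRow > nr))
    stop("surface lies below the image for some columns")
  # boundary in fractional row coordinates (centers at integers)
  surfaceRowCoord <- surfMm / p + 0.5

  ndeep <- nr - firstRow + 1L               # tissue rows per column
  ndTarget <- preset@depletedThickness / p  # depleted pixels per column (real)
  ndCol <- diff(c(0L, as.integer(floor(seq_len(nc) * ndTarget + 1e-9))))
  if (any(ndCol > ndeep))
    stop("depleted thickness ", preset@depletedThickness,
         " mm exceeds the tissue depth of the image")

  trueLt <- array(NA_real_, c(nr, nc, 3))
  trueRatios <- array(NA_real_, c(nr, nc, 3))
  tissueMask <- matrix(FALSE, nr, nc)
  depMask <- matrix(FALSE, nr, nc)

  waveforms <- array(0, c(nr, nc, config@nSamples))
  decayCache <- new.env(parent = emptyenv())
  winIdx <- lapply(starts, function(s) s:(s + nw - 1L))

  for (cc in seq_len(nc)) {
    for (rr in firstRow[cc]:nr) {
      tissueMask[rr, cc] <- TRUE
      depth <- (rr - 0.5) * p - surfMm[cc]     # pixel-center depth (mm)
      depleted <- rr < firstRow[cc] + ndCol[cc]
      depMask[rr, cc] <- depleted
      lt1 <- preset@ltCh1Surface +
        (preset@ltCh1Deep - preset@ltCh1Surface) *
        min(max(depth, 0) / preset@ltRampDepth, 1)
      lts <- c(lt1,
               if (depleted) preset@ltCh2Depleted else preset@ltCh2,
               if (depleted) preset@ltCh3Depleted else preset@ltCh3)
      ratios <- if (depleted) preset@ratiosDepleted else preset@ratiosHealthy
      trueLt[rr, cc, ] <- lts
      trueRatios[rr, cc, ] <- ratios
      rec <- numeric(config@nSamples)
      for (k in 1:3) {
        key <- sprintf("%.9f", lts[k])
        y <- decayCache[[key]]
        if (is.null(y)) {
          h <- synthDecay(lts[k], window = config@channelWindow, dt = dt,
                          shape = "bi")
          y <- .causalConv(irf, h)
          y <- y / (sum(y) * dt)               # unit in-window energy
          decayCache[[key]] <- y
        }
        rec[winIdx[[k]]] <- y * ratios[k] * gains[k]
      }
      waveforms[rr, cc, ] <- rec
    }
  }

  if (noise) {
    peak <- max(waveforms)
    sAdd <- peak / 10^(config@peakSnrDb / 20)
    rng <- .preserveSeed(config@seed)
    on.exit(rng(), add = TRUE)
    nz <- stats::rnorm(length(waveforms))
    waveforms <- waveforms +
      sAdd * sqrt(1 + pmax(waveforms, 0) / peak) *
        array(nz, dim = dim(waveforms))
  }

  scan <- new("RawScan", waveforms = waveforms, irf = irf, config = config)
  truth <- new("PhantomTruth",
               surfaceRow = surfaceRowCoord,
               trueLt = trueLt, trueRatios = trueRatios,
               depletedMask = depMask,
               depletedThicknessPerColumn = ndCol * p,
               tissueMask = tissueMask)
  list(scan = scan, truth = truth)
}

# internal: set the RNG seed, returning a restorer for the previous state
.preserveSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
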