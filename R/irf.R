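#' Instrument response function
#'
#' Builds the discrete instrument-response trace: a unit-area Gaussian of
#' the configured FWHM (600 ps by default, the excitation pulse width),
#' peaked at `irfPeakOffset` within a trace one channel window long.
#'
#' @param config An [AcquisitionConfig-class].
#' @return Numeric vector of length `channelWindow / dt`, non-negative,
#'   summing to 1.
#' @examples
#' irf <- makeIrf(acquisitionConfig())
#' sum(irf)                      # 1
#' @export
makeIrf <- function(config) {
  if (config@irfFwhm <= 2 * config@dt)
    stop("iRF FWHM (", config@irfFwhm, " ns) is not resolvable at dt = ",
         config@dt, " ns: the pulse is under-sampled")
  n <- .windowSamples(config)
  t <- (seq_len(n) - 1L) * config@dt
  sigma <- config@irfFwhm / (2 * sqrt(2 * log(2)))
  irf <- exp(-0.5 * ((t - config@irfPeakOffset) / sigma)^2)
  irf / sum(irf)
}

# internal: causal discrete convolution of irf with x, truncated to
# length(x). FFT-based; both inputs share the same grid.
.causalConv <- function(irf, x) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(n)), rev(c(irf, numeric(n))),
                         type = "open")[seq_len(n)]
  out
}
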