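# shared fixtures, built once per test run and cached
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]]))
    assign(key, expr, envir = .fixtureCache)
  .fixtureCache[[key]]
}

# small desk-scale grid for unit tests (full 50x50 runs live in the
# acceptance suite)
smallConfig <- function(seed = 1L, ...) {
  acquisitionConfig(nRows = 24L, nCols = 16L, seed = seed, ...)
}

smallPhantom <- function(preset, noise = FALSE, seed = 1L, ...) {
  key <- paste0("ph_", preset, "_", noise, "_", seed)
  cached(key, makePhantom(smallConfig(seed = seed, ...),
                          tissuePreset(preset), noise = noise))
}

smallMaps <- function(preset, noise = FALSE, seed = 1L, alpha = 0.95) {
  key <- paste0("maps_", preset, "_", noise, "_", seed, "_", alpha)
  cached(key, buildMaps(smallPhantom(preset, noise, seed)$scan,
                        alpha = alpha))
}

# full-size study phantoms used by the acceptance suite
studyPhantom <- function(preset, seed, pitch = 0.2) {
  key <- paste0("study_", preset, "_", seed, "_", pitch)
  cached(key, makePhantom(acquisitionConfig(pixelPitch = pitch, seed = seed),
                          tissuePreset(preset)))
}

studyMaps <- function(preset, seed, pitch = 0.2) {
  key <- paste0("studymaps_", preset, "_", seed, "_", pitch)
  cached(key, buildMaps(studyPhantom(preset, seed, pitch)$scan))
}

# truth-mask ROI of tissue deeper than the channel-1 ramp (0.5 mm)
deepTissueROI <- function(ph, config) {
  nr <- config@nRows; nc <- config@nCols; p <- config@pixelPitch
  depth <- outer((seq_len(nr) - 0.5) * p, rep(1, nc)) -
    matrix((ph$truth@surfaceRow - 0.5) * p, nr, nc, byrow = TRUE)
  ph$truth@tissueMask & depth > 0.5
}
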