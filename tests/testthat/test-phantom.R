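test_that("iRF is unit-area, non-negative, with the configured FWHM", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  expect_equal(sum(irf), 1, tolerance = 1e-12)
  expect_true(all(irf >= 0))
  expect_length(irf, round(cfg@channelWindow / cfg@dt))
  # width at half max: 0.6 ns / 0.08 ns = 7.5 samples
  half <- max(irf) / 2
  above <- which(irf >= half)
  width <- max(above) - min(above) + 1L
  expect_lt(abs(width - 7.5), 1)
  # under-sampled pulse is rejected
  expect_error(makeIrf(acquisitionConfig(irfFwhm = 0.1)), "under-sampled")
})

test_that("synthDecay hits the discrete average lifetime exactly", {
  h <- synthDecay(4, window = 45, dt = 0.01, shape = "mono")
  expect_lt(abs(averageLifetime(h, 0.01) - 4), 1e-6)
  for (lt in c(6.34, 5.22)) {
    h <- synthDecay(lt, window = 45, dt = 0.08, shape = "bi")
    expect_lt(abs(averageLifetime(h, 0.08) - lt), 1e-6)
    expect_true(all(h >= 0))
    expect_true(all(diff(h) <= 1e-12))      # non-increasing
  }
  expect_error(synthDecay(20, window = 45, dt = 0.08), "window/3")
  expect_error(synthDecay(0, window = 45, dt = 0.08), "window/3")
})

test_that("phantom truth is self-consistent and ratio-closed", {
  ph <- smallPhantom("high", noise = FALSE)
  tr <- ph$truth
  # ratio closure at every tissue pixel
  s <- apply(tr@trueRatios, c(1, 2), sum)
  expect_lt(max(abs(s[tr@tissueMask] - 1)), 1e-12)
  expect_true(all(tr@trueRatios[!is.na(tr@trueRatios)] > 0 &
                  tr@trueRatios[!is.na(tr@trueRatios)] < 1))
  # depleted mask within tissue; thickness = count * pitch
  expect_true(all(tr@tissueMask[tr@depletedMask]))
  counts <- colSums(tr@depletedMask)
  expect_equal(tr@depletedThicknessPerColumn, counts * 0.2)
  expect_equal(mean(tr@depletedThicknessPerColumn), 0.7, tolerance = 1e-12)
  # regenerating the truth decay reproduces the stored lifetime
  idx <- which(tr@tissueMask, arr.ind = TRUE)[c(1, 20, 100), ]
  for (i in seq_len(nrow(idx))) for (k in 1:3) {
    lt <- tr@trueLt[idx[i, 1], idx[i, 2], k]
    h <- synthDecay(lt, window = 45, dt = 0.08, shape = "bi")
    expect_lt(abs(averageLifetime(h, 0.08) - lt), 1e-6)
  }
})

test_that("control preset carries the healthy lifetimes and no depletion", {
  ph <- smallPhantom("control", noise = FALSE)
  tr <- ph$truth
  expect_false(any(tr@depletedMask))
  expect_true(all(tr@trueLt[, , 2][tr@tissueMask] == 6.34))
  expect_true(all(tr@trueLt[, , 3][tr@tissueMask] == 5.22))
  # channel-1 ramp: surface value at the shallowest pixel, deep value at
  # the bottom
  firstRow <- floor(tr@surfaceRow[1]) + 1L
  lt1 <- tr@trueLt[, 1, 1]
  expect_lt(lt1[firstRow], 5.8)
  expect_equal(lt1[24], 6.1)
  expect_true(all(diff(lt1[!is.na(lt1)]) >= 0))
})

test_that("noiseless records confine each channel to its window", {
  ph <- smallPhantom("control", noise = FALSE)
  cfg <- ph$scan@config
  nw <- round(cfg@channelWindow / cfg@dt)
  starts <- round(cfg@channelDelays / cfg@dt) + 1
  rec <- ph$scan@waveforms[12, 4, ]
  expect_true(all(rec >= 0))
  inWin <- unlist(lapply(starts, function(s) s:(s + nw - 1)))
  expect_equal(sum(rec[-inWin]), 0)
  for (s in starts) expect_gt(sum(rec[s:(s + nw - 1)]), 0)
})

test_that("phantom generation is deterministic given the seed", {
  cfg <- acquisitionConfig(nRows = 10L, nCols = 6L, seed = 99L)
  a <- makePhantom(cfg, tissuePreset("low"))
  b <- makePhantom(cfg, tissuePreset("low"))
  expect_identical(a$scan@waveforms, b$scan@waveforms)
  c <- makePhantom(acquisitionConfig(nRows = 10L, nCols = 6L, seed = 100L),
                   tissuePreset("low"))
  expect_false(identical(a$scan@waveforms, c$scan@waveforms))
})

test_that("impossible depletion geometry is rejected", {
  cfg <- acquisitionConfig(nRows = 8L, nCols = 6L)   # 0.6 mm of tissue
  expect_error(makePhantom(cfg, tissuePreset("high")), "exceeds")
})

test_that("preset ratio triples satisfy closure and the threshold geometry", {
  pre <- tissuePreset("high")
  expect_equal(sum(pre@ratiosHealthy), 1, tolerance = 1e-15)
  expect_equal(sum(pre@ratiosDepleted), 1, tolerance = 1e-15)
  # relative changes under depletion: -37%, -31%, +23%
  rel <- pre@ratiosDepleted / pre@ratiosHealthy - 1
  expect_equal(rel, c(-0.37, -0.31, 0.23), tolerance = 1e-10)
  # channel-1 ratio brackets the 0.25 segmentation threshold
  expect_gt(pre@ratiosHealthy[1], 0.25)
  expect_lt(pre@ratiosDepleted[1], 0.25)
})

test_that("scan containers round-trip bit-identically", {
  ph <- smallPhantom("low", noise = TRUE, seed = 7L)
  dir <- withr::local_tempdir()
  writeScan(ph$scan, dir, truth = ph$truth, presetName = "low")
  back <- readScan(dir)
  expect_identical(back$scan@waveforms, ph$scan@waveforms)
  expect_identical(back$scan@irf, ph$scan@irf)
  expect_identical(back$truth@depletedMask, ph$truth@depletedMask)
  expect_identical(back$truth@trueLt, ph$truth@trueLt)
  expect_identical(back$presetName, "low")
  expect_equal(back$scan@config@channelGains, ph$scan@config@channelGains)
})
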