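test_that("basis columns are orthonormal across the usable alpha grid", {
  for (a in c(0.90, 0.92, 0.94, 0.96, 0.98)) {
    b <- laguerreBasis(a, 12, 562)
    G <- crossprod(basisMatrix(b))
    expect_lt(max(abs(G - diag(12))), 1e-8)
  }
})

test_that("basis degenerates gracefully at the limits", {
  # alpha -> 0: first function approaches a unit impulse at n = 0
  b <- laguerreBasis(1e-6, 1, 100)
  B <- basisMatrix(b)
  expect_gt(B[1, 1], 0.999)
  expect_lt(sum(B[-1, 1]^2), 1e-5)
  # alpha too large for the window is rejected with advice
  expect_error(laguerreBasis(0.999, 12, 562), "smaller alpha")
  expect_error(laguerreBasis(1.2, 12, 562), "alpha")
  expect_error(laguerreBasis(0.95, 40, 562), "order")
})

test_that("averageLifetime matches closed forms", {
  # impulse at t = 3.2 ns
  h <- numeric(600); h[41] <- 1
  expect_equal(averageLifetime(h, 0.08), 3.2)
  # truncated exponential: geometric-series closed form as oracle
  dt <- 0.01; tau <- 4; N <- 4500
  t <- (0:(N - 1)) * dt
  h <- exp(-t / tau)
  q <- exp(-dt / tau)
  S0 <- (1 - q^N) / (1 - q)
  S1 <- q * (1 - N * q^(N - 1) + (N - 1) * q^N) / (1 - q)^2
  oracle <- dt * S1 / S0
  expect_equal(averageLifetime(h, dt), oracle, tolerance = 1e-12)
  # the discrete moment sits dt/2 below the continuous truncated-window
  # expectation tau - T exp(-T/tau) / (1 - exp(-T/tau))
  cont <- tau - N * dt * exp(-N * dt / tau) / (1 - exp(-N * dt / tau))
  expect_equal(oracle, cont - dt / 2, tolerance = 1e-5)
  # uniform trace: mid-window by symmetry
  u <- rep(1, 450)
  expect_equal(averageLifetime(u, 0.1), (450 - 1) * 0.1 / 2)
  expect_error(averageLifetime(numeric(10), 0.1), "non-positive")
})

test_that("intensityRatio lies on the simplex and sums to 1 exactly", {
  expect_equal(intensityRatio(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(intensityRatio(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  set.seed(2)
  for (i in 1:20) {
    r <- intensityRatio(stats::runif(3, 0.01, 5))
    expect_lt(abs(sum(r) - 1), 1e-15)
  }
  expect_error(intensityRatio(c(0, 0, 0)), "zero")
  expect_error(intensityRatio(c(-1, 1, 1)), ">= 0")
})

test_that("noiseless deconvolution recovers lifetimes in the basis span", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  nw <- length(irf)
  basis <- laguerreBasis(0.95, 12, nw)
  for (lt in c(3, 5.22, 6.34)) {
    h <- synthDecay(lt, 45, cfg@dt, shape = "bi")
    y <- flimcart:::.causalConv(irf, h)
    r <- deconvolve(y, irf, basis, dt = cfg@dt)
    expect_true(r@converged)
    expect_lt(abs(avgLifetime(r) - lt), 0.02)
    expect_gt(min(r@h), -1e-12)
  }
})

test_that("deconvolution agrees with a brute-force exponential grid fit", {
  # oracle: scan a dense tau grid, fit amplitude linearly, keep the
  # windowed moment of the best mono-exponential
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  nw <- length(irf)
  dt <- cfg@dt
  t <- (0:(nw - 1)) * dt
  basis <- laguerreBasis(0.95, 12, nw)
  for (tau in c(3.5, 6)) {
    hTrue <- exp(-t / tau)
    y <- flimcart:::.causalConv(irf, hTrue)
    taus <- seq(tau - 0.5, tau + 0.5, by = 0.002)
    sse <- vapply(taus, function(tg) {
      m <- flimcart:::.causalConv(irf, exp(-t / tg))
      a <- sum(m * y) / sum(m * m)
      sum((y - a * m)^2)
    }, numeric(1))
    tauHat <- taus[which.min(sse)]
    oracleLt <- averageLifetime(exp(-t / tauHat), dt)
    r <- deconvolve(y, irf, basis, dt = dt)
    expect_lt(abs(avgLifetime(r) - oracleLt), 0.02)
  }
})

test_that("deconvolution is scale-equivariant", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  basis <- laguerreBasis(0.95, 12, length(irf))
  h <- synthDecay(5, 45, cfg@dt)
  y <- flimcart:::.causalConv(irf, h)
  r1 <- deconvolve(y, irf, basis, dt = cfg@dt)
  r2 <- deconvolve(7.3 * y, irf, basis, dt = cfg@dt)
  expect_equal(avgLifetime(r2), avgLifetime(r1), tolerance = 1e-9)
  expect_equal(r2@intensity, 7.3 * r1@intensity, tolerance = 1e-9)
})

test_that("recovered lifetime increases monotonically with true lifetime", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  basis <- laguerreBasis(0.95, 12, length(irf))
  rec <- vapply(2:8, function(lt) {
    y <- flimcart:::.causalConv(irf, synthDecay(lt, 45, cfg@dt))
    avgLifetime(deconvolve(y, irf, basis, dt = cfg@dt))
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("recovered lifetime is insensitive to alpha on clean input", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  y <- flimcart:::.causalConv(irf, synthDecay(5, 45, cfg@dt))
  rec <- vapply(c(0.94, 0.95, 0.96, 0.97, 0.98), function(a) {
    basis <- laguerreBasis(a, 12, length(irf))
    avgLifetime(deconvolve(y, irf, basis, dt = cfg@dt))
  }, numeric(1))
  expect_lt(max(rec) - min(rec), 0.05)
})

test_that("noisy replicates stay precise and unbiased at default SNR", {
  cfg <- acquisitionConfig()
  irf <- makeIrf(cfg)
  nw <- length(irf)
  basis <- laguerreBasis(0.95, 12, nw)
  design <- flimcart:::.laguerreDesign(basis, irf, cfg@dt)
  ltTrue <- 5
  y0 <- flimcart:::.causalConv(irf, synthDecay(ltTrue, 45, cfg@dt))
  peak <- max(y0)
  sAdd <- peak / 10^(cfg@peakSnrDb / 20)
  rec <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    y <- y0 + stats::rnorm(nw, 0, sAdd * sqrt(1 + pmax(y0, 0) / peak))
    avgLifetime(flimcart:::.deconvolveDesign(y, design))
  }, numeric(1))
  expect_lt(stats::sd(rec), 0.1)
  expect_lt(abs(mean(rec) - ltTrue), 0.05)
})

test_that("alpha calibration picks a feasible grid value deterministically", {
  ph <- smallPhantom("control", noise = TRUE, seed = 5L)
  cfg <- ph$scan@config
  nw <- round(cfg@channelWindow / cfg@dt)
  idx <- which(ph$truth@tissueMask)[1:20]
  dec <- vapply(idx, function(j) {
    rr <- (j - 1) %% cfg@nRows + 1; cc <- (j - 1) %/% cfg@nRows + 1
    flimcart:::.demuxMatrix(ph$scan@waveforms[rr, cc, ], cfg)[, 2]
  }, numeric(nw))
  a1 <- calibrateAlpha(dec, ph$scan@irf, cfg@dt)
  a2 <- calibrateAlpha(dec, ph$scan@irf, cfg@dt)
  expect_identical(a1, a2)
  expect_true(a1 %in% c(seq(0.90, 0.98, by = 0.02), 0.99))
})
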