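test_that("ROC on separated classes is perfect and sits between them", {
  values <- c(0.10, 0.15, 0.18, 0.30, 0.33, 0.40)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- rocThreshold(values, labels)
  expect_equal(rocAuc(roc), 1)
  expect_gt(chosenThreshold(roc), 0.18)
  expect_lt(chosenThreshold(roc), 0.30)
  expect_error(rocThreshold(values, rep(TRUE, 6)), "both classes")
})

test_that("ROC curves are monotone and match an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  values <- c(stats::rnorm(300, 0.20, 0.03), stats::rnorm(300, 0.30, 0.03))
  labels <- rep(c(TRUE, FALSE), each = 300)
  roc <- rocThreshold(values, labels)
  expect_true(all(diff(roc@tpr) >= 0))
  expect_true(all(diff(roc@fpr) >= 0))
  ref <- pROC::roc(response = labels, predictor = values,
                   direction = ">", quiet = TRUE)
  expect_equal(rocAuc(roc), as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(17)
  values <- c(stats::rnorm(1250, 0.20, 0.02), stats::rnorm(1250, 0.32, 0.02))
  labels <- sample(rep(c(TRUE, FALSE), 1250))   # independent of values
  roc <- rocThreshold(values, labels)
  expect_lt(abs(rocAuc(roc) - 0.5), 0.05)
})

test_that("phantom pair re-derives a threshold near the 0.25 operating point", {
  mC <- smallMaps("control", noise = TRUE, seed = 1L)
  mH <- smallMaps("high", noise = TRUE, seed = 2L)
  phC <- smallPhantom("control", noise = TRUE, seed = 1L)
  phH <- smallPhantom("high", noise = TRUE, seed = 2L)
  values <- c(ratioMap(mC, 1)[phC$truth@tissueMask],
              ratioMap(mH, 1)[phH$truth@tissueMask])
  labels <- c(phC$truth@depletedMask[phC$truth@tissueMask],
              phH$truth@depletedMask[phH$truth@tissueMask])
  roc <- rocThreshold(values, labels)
  expect_gt(rocAuc(roc), 0.99)
  expect_gte(chosenThreshold(roc), 0.21)
  expect_lte(chosenThreshold(roc), 0.29)
})

test_that("noiseless segmentation is exact and recovers preset thickness", {
  for (preset in c("low", "high")) {
    ph <- smallPhantom(preset, noise = FALSE)
    m <- smallMaps(preset, noise = FALSE)
    s <- detectSurface(m)
    for (thr in c(0.22, 0.25, 0.30)) {
      seg <- segmentDepletion(m, s, threshold = thr)
      expect_identical(depletedMask(seg), ph$truth@depletedMask)
    }
    seg <- segmentDepletion(m, s)
    truthMean <- mean(ph$truth@depletedThicknessPerColumn)
    expect_lt(abs(meanThickness(seg) - truthMean), 0.1)    # pitch / 2
  }
  # control: nothing to segment
  mC <- smallMaps("control", noise = FALSE)
  segC <- segmentDepletion(mC, detectSurface(mC))
  expect_lte(meanThickness(segC), 0.2)
  # degenerate threshold removes everything
  seg0 <- segmentDepletion(mC, detectSurface(mC), threshold = 0)
  expect_identical(meanThickness(seg0), 0)
})

test_that("mean thickness is monotone in the threshold", {
  m <- smallMaps("high", noise = TRUE, seed = 2L)
  s <- detectSurface(m)
  th <- vapply(seq(0.05, 0.40, by = 0.05), function(thr)
    meanThickness(segmentDepletion(m, s, threshold = thr)), numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("noiseless low and high phantoms order correctly", {
  mL <- smallMaps("low", noise = FALSE)
  mH <- smallMaps("high", noise = FALSE)
  tL <- meanThickness(segmentDepletion(mL, detectSurface(mL)))
  tH <- meanThickness(segmentDepletion(mH, detectSurface(mH)))
  expect_lt(tL, tH)
  expect_lt(abs(tL - 0.3), 0.1)
  expect_lt(abs(tH - 0.7), 0.1)
})

test_that("roiSummary reduces to single pixels and uniform regions", {
  m <- smallMaps("control", noise = FALSE)
  ph <- smallPhantom("control", noise = FALSE)
  px <- which(ph$truth@tissueMask, arr.ind = TRUE)[40, ]
  roi <- matrix(FALSE, nrow(m@valid), ncol(m@valid))
  roi[px[1], px[2]] <- TRUE
  r <- roiSummary(m, roi)
  expect_identical(r$n, 1L)
  expect_equal(r$meanLt, lifetimeMap(m)[px[1], px[2], ])
  # uniform region: deep tissue has constant truth, ROI mean equals it
  deep <- deepTissueROI(ph, ph$scan@config)
  rd <- roiSummary(m, deep)
  expect_lt(abs(rd$meanLt[2] - 6.34), 0.02)
  expect_error(roiSummary(m, matrix(FALSE, nrow(m@valid), ncol(m@valid))),
               "ROI")
})

test_that("depleted-ROI lifetime recovery on the noisy high phantom", {
  ph <- studyPhantom("high", seed = 2L)
  m <- studyMaps("high", seed = 2L)
  r <- roiSummary(m, ph$truth@depletedMask)
  pre <- tissuePreset("high")
  expect_gt(r$n, 150)
  expect_lt(abs(r$meanLt[2] - pre@ltCh2Depleted), 0.1)
  expect_lt(abs(r$meanLt[3] - pre@ltCh3Depleted), 0.1)
})

test_that("group comparison matches aov and orders p-values sensibly", {
  # identical group means: F ~ 0, p ~ 1
  g <- compareGroups(list(a = c(1, 2, 3), b = c(2, 1, 3)))
  expect_lt(g@fStatistic, 1e-10)
  expect_gt(g@pValue, 0.99)
  # hand-checkable fixture: SSB = 150 (df 1), MSW = 1 (df 4)
  g2 <- compareGroups(list(lo = c(1, 2, 3), hi = c(11, 12, 13)))
  expect_equal(g2@fStatistic, 150, tolerance = 1e-9)
  expect_lt(g2@pValue, 0.01)
  expect_equal(g2@pairwise$diff[1], 10)
  # cross-check against aov run independently
  d <- data.frame(v = c(1, 2, 3, 11, 12, 13),
                  g = factor(rep(c("lo", "hi"), each = 3)))
  ref <- summary(stats::aov(v ~ g, d))[[1]][["F value"]][1]
  expect_equal(g2@fStatistic, ref, tolerance = 1e-9)
  # Tukey adjustment never undercuts the unadjusted pairwise t-test
  set.seed(5)
  groups <- list(a = stats::rnorm(6, 0), b = stats::rnorm(6, 0.5),
                 c = stats::rnorm(6, 1.5))
  g3 <- compareGroups(groups)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    pu <- stats::t.test(groups[[pair[1]]], groups[[pair[2]]],
                        var.equal = TRUE)$p.value
    comp <- g3@pairwise$pAdj[grepl(pair[1], g3@pairwise$comparison) &
                             grepl(pair[2], g3@pairwise$comparison)]
    expect_gte(comp + 1e-12, pu)
  }
  # degenerate variance is flagged rather than fabricated
  gd <- compareGroups(list(a = c(2, 2), b = c(2, 2)))
  expect_true(gd@degenerate)
  expect_true(is.na(gd@fStatistic))
  expect_error(compareGroups(list(a = 1:3)), "2 groups")
  expect_error(compareGroups(list(a = 1:3, b = 2)), "2 samples")
})
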