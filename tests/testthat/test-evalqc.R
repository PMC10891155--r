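# Evaluation metrics, stain unmixing, nuclei quantification, t-test, and
# the FOV artifact-screening workflow.

test_that("whole-image SSIM matches the closed-form statistic", {
  set.seed(1)
  a <- matrix(runif(64), 8, 8)
  expect_equal(ssimGlobal(a, a), 1)
  # constant 0 vs constant 1: hand evaluation with zero variances
  c1 <- 1e-4; c2 <- 9e-4
  expect_equal(ssimGlobal(matrix(0, 8, 8), matrix(1, 8, 8)),
               c1 * c2 / ((1 + c1) * c2), tolerance = 1e-12)
  # direct formula oracle on random pairs
  for (i in 1:10) {
    a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
    muA <- mean(a); muB <- mean(b)
    vA <- mean((a - muA)^2); vB <- mean((b - muB)^2)
    cab <- mean((a - muA) * (b - muB))
    ref <- (2 * muA * muB + c1) * (2 * cab + c2) /
      ((muA^2 + muB^2 + c1) * (vA + vB + c2))
    expect_equal(ssimGlobal(a, b), ref, tolerance = 1e-10)
  }
  # symmetry and range on non-negative images
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  expect_equal(ssimGlobal(a, b), ssimGlobal(b, a))
  expect_gt(ssimGlobal(a, b), 0)
  expect_lte(ssimGlobal(a, b), 1)
})

test_that("PSNR uses the reference peak and the pixel-mean MSE", {
  expect_equal(psnrPeak(matrix(0.9, 4, 4), matrix(1, 4, 4)), 20)  # MSE 0.01
  expect_equal(psnrPeak(matrix(1, 3, 3), matrix(1, 3, 3)), Inf)
  set.seed(2)
  for (i in 1:5) {
    a <- array(runif(48), c(4, 4, 3)); b <- array(runif(48), c(4, 4, 3))
    mse <- mean((a - b)^2)   # loop-free oracle equals definition
    expect_equal(psnrPeak(a, b), 10 * log10(max(b)^2 / mse), tolerance = 1e-9)
  }
  # strictly decreasing in MSE for a fixed reference
  b <- matrix(0.8, 6, 6)
  p <- sapply(c(0.01, 0.05, 0.1, 0.2), function(e) psnrPeak(b + e, b))
  expect_true(all(diff(p) < 0))
})

test_that("stain unmixing recovers rendered concentrations", {
  un <- stainUnmix(array(255, c(2, 2, 3)))
  expect_equal(un$hema, matrix(0, 2, 2))      # white pixel: zero OD
  expect_equal(un$eosin, matrix(0, 2, 2))
  od <- array(c(0.8, 0), c(1, 1, 2))
  un <- stainUnmix(renderHE(od))
  expect_lt(abs(un$hema[1, 1] - 0.8), 1e-2)
  expect_lt(abs(un$eosin[1, 1]), 1e-2)
  od <- array(c(0.5, 0.5), c(1, 1, 2))
  un <- stainUnmix(renderHE(od))
  expect_lt(abs(un$hema[1, 1] - 0.5), 1e-2)
  expect_lt(abs(un$eosin[1, 1] - 0.5), 1e-2)
  bad <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(stainUnmix(array(128, c(2, 2, 3)), bad), "degenerate")
})

test_that("unmix-render roundtrip is accurate over the concentration grid", {
  cs <- seq(0, 2, length.out = 10)
  errs <- c()
  for (ch in cs) for (ce in cs) {
    un <- stainUnmix(renderHE(array(c(ch, ce), c(1, 1, 2))))
    errs <- c(errs, abs(un$hema - ch), abs(un$eosin - ce))
  }
  expect_lt(mean(errs), 1e-2)
})

test_that("nuclei segmentation recovers disjoint disks", {
  # 5 disjoint disks of radius 6 on a near-zero background
  H <- 80
  od <- matrix(0.02, H, H)
  centers <- cbind(c(15, 15, 40, 65, 65), c(15, 65, 40, 15, 65))
  gt <- matrix(0, H, H)
  for (i in 1:5) {
    for (r in 1:H) for (cc in 1:H)
      if ((r - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= 36) {
        od[r, cc] <- 0.9; gt[r, cc] <- 1
      }
  }
  mask <- segmentNuclei(od)
  expect_equal(nucleiStats(mask)$count, 5L)
  iou <- sum(mask & gt) / sum(mask | gt)
  expect_gt(iou, 0.8)
  expect_equal(segmentNuclei(matrix(0, 8, 8)), matrix(0, 8, 8))
  expect_error(segmentNuclei(matrix(-1, 4, 4)), "non-negative")
})

test_that("nuclei statistics use 8-connected components", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal touch: one 8-connected blob
  expect_equal(nucleiStats(m)$count, 1L)
  m2 <- matrix(0, 8, 8)
  m2[1:2, 1:2] <- 1                    # area 4
  m2[6:8, 6:7] <- 1                    # area 6
  st <- nucleiStats(m2)
  expect_equal(st$count, 2L)
  expect_equal(st$meanArea, 5)
  expect_equal(nucleiStats(matrix(0, 4, 4)), list(count = 0L,
                                                  meanArea = NA_real_))
  expect_error(nucleiStats(matrix(2, 3, 3)), "binary")
  # random blob masks agree with the independent flood-fill oracle
  set.seed(3)
  for (i in 1:5) {
    mk <- matrix(rbinom(400, 1, 0.25), 20, 20)
    expect_equal(nucleiStats(mk)$count, max(floodLabel(mk)))
  }
})

test_that("paired t-test matches the closed form", {
  expect_equal(pairedTTest(1:5, 1:5), list(t = 0, p = 1, df = 4))
  out <- pairedTTest(c(2, 3, 4), c(1, 1, 1))   # d = (1, 2, 3)
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-abs(out$t), df = 2), tolerance = 1e-9)
  expect_equal(out$p, 0.0742, tolerance = 1e-3)
  # sign symmetry
  rev <- pairedTTest(c(1, 1, 1), c(2, 3, 4))
  expect_equal(rev$t, -out$t)
  expect_equal(rev$p, out$p)
  expect_error(pairedTTest(1, 1), "at least 2")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("FOV metrics respond to staining artifacts as designed", {
  s <- smallPhantom(seed = 30, n = 25)
  qcc <- qcConfig(fov = 96)
  m <- fovQualityMetrics(heIdeal(s), qcc)
  # ground-truth nuclei coverage within tissue is tracked by metric 1
  gtFrac <- sum(nucleiMask(s)) / sum(registain:::.lum(heIdeal(s)) < 235)
  expect_equal(m$nucleiAreaFraction, gtFrac, tolerance = 0.02)
  expect_equal(fovQualityMetrics(degradeStaining(s, artifactSpec(hemaFade = 1)),
                                 qcc)$nucleiAreaFraction, 0)
  expect_lt(fovQualityMetrics(degradeStaining(s, artifactSpec(eosinFade = 1)),
                              qcc)$eosinMeanIntensity, 0.02)
  # all-white FOV has no tissue
  expect_null(fovQualityMetrics(array(255, c(32, 32, 3)), qcc))
})

test_that("FOV classification applies strict threshold exceedance", {
  # decision rule on synthetic metric values via a minimal wrapper slide:
  # construct FOVs whose measured metrics fall on either side of the
  # thresholds and check the labels
  s <- smallPhantom(seed = 31, n = 25)
  qcc <- qcConfig(fov = 96)
  well <- fovTable(classifyFOVs(heIdeal(s), qcc))
  expect_equal(well$classification, "well")
  poor <- fovTable(classifyFOVs(degradeStaining(s, artifactSpec(hemaFade = 1)),
                                qcc))
  expect_equal(poor$classification, "poor")
  # exact threshold equality classifies as poor (strict exceedance)
  tb <- well
  expect_true(tb$nucleiAreaFraction > qcc$nucleiAreaThreshold)
  cfgEq <- qcConfig(fov = 96,
                    nucleiAreaThreshold = tb$nucleiAreaFraction,
                    eosinIntensityThreshold = 0.0001)
  eq <- fovTable(classifyFOVs(heIdeal(s), cfgEq))
  expect_equal(eq$classification, "poor")
})

test_that("slide evaluation bundles metrics and nuclei tests", {
  ph <- lapply(1:4, function(i) smallPhantom(seed = 40 + i, n = 15, H = 64))
  vs <- lapply(ph, heIdeal)
  hs <- lapply(ph, function(s)
    registain:::.clamp(heIdeal(s) + array(rnorm(64 * 64 * 3, 0, 4),
                                          c(64, 64, 3)), 0, 255))
  res <- evaluateStaining(vs, hs)
  expect_length(res$ssim, 4)
  expect_true(all(res$ssim > 0.5))
  expect_true(all(is.finite(res$psnr)))
  expect_true(!is.null(res$countTest))
  expect_true(res$countTest$p > 0.05)  # same nuclei on both sides
})
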