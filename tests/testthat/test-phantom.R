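# Synthetic phantom generator: determinism, ground-truth consistency,
# rendering, artifacts, misalignment fields.

test_that("phantom generation is deterministic and honours the nuclei count", {
  a <- smallPhantom(seed = 3, n = 20)
  b <- smallPhantom(seed = 3, n = 20)
  expect_identical(afImage(a), afImage(b))
  expect_identical(heIdeal(a), heIdeal(b))
  expect_identical(nucleiMask(a), nucleiMask(b))
  expect_equal(nucleiCount(a), 20L)
  # independent labeling of the emitted mask agrees with the count
  expect_equal(max(floodLabel(nucleiMask(a))), 20)
  # empty case
  e <- generatePhantom(phantomSpec(height = 32, width = 32, nNuclei = 0))
  expect_equal(sum(nucleiMask(e)), 0)
  expect_equal(nucleiCount(e), 0L)
})

test_that("phantom specification validates its invariants", {
  expect_error(phantomSpec(height = 0), "positive")
  expect_error(phantomSpec(nNuclei = -1), "nNuclei")
  expect_error(phantomSpec(backgroundFraction = 1.5), "backgroundFraction")
  expect_error(phantomSpec(nucleusRadiusRange = c(0, 3)), "radii")
  # infeasible dense packing errors out naming the constraint
  expect_error(generatePhantom(phantomSpec(height = 24, width = 24,
                                           nNuclei = 200,
                                           nucleusRadiusRange = c(3, 4))),
               "overlap")
})

test_that("rendering follows Beer-Lambert composition and unmixing inverts it", {
  od0 <- array(0, c(4, 4, 2))
  expect_true(all(renderHE(od0) == 255))           # zero absorbance -> white
  V <- heStainVectors()
  od1 <- array(0, c(1, 1, 2)); od1[1, 1, 1] <- 1
  px <- renderHE(od1)[1, 1, ]
  expect_equal(px, round(256 * exp(-V[1, ]) - 1), tolerance = 0)
  expect_error(renderHE(array(-0.1, c(2, 2, 2))), "non-negative")
  # roundtrip before quantization: continuous inverse is exact
  set.seed(1)
  od <- array(runif(32, 0, 2), c(4, 4, 2))
  rgbCont <- array(0, c(4, 4, 3))
  for (ch in 1:3)
    rgbCont[, , ch] <- 256 * exp(-(od[, , 1] * V[1, ch] + od[, , 2] * V[2, ch])) - 1
  un <- stainUnmix(rgbCont)
  expect_lt(max(abs(un$hema - od[, , 1])), 1e-6)
  expect_lt(max(abs(un$eosin - od[, , 2])), 1e-6)
})

test_that("under-staining artifacts scale the optical density as specified", {
  s <- smallPhantom(seed = 5)
  expect_identical(degradeStaining(s, artifactSpec(0, 0)), heIdeal(s))
  qcc <- qcConfig(fov = 96)
  m <- fovQualityMetrics(degradeStaining(s, artifactSpec(hemaFade = 1)), qcc)
  expect_equal(m$nucleiAreaFraction, 0)
  # nuclei-area metric is non-increasing in the hematoxylin fade
  m1 <- sapply(seq(0, 1, 0.25), function(f)
    fovQualityMetrics(degradeStaining(s, artifactSpec(hemaFade = f)),
                      qcc)$nucleiAreaFraction)
  expect_true(all(diff(m1) <= 1e-9))
  # region mask shape mismatch
  expect_error(degradeStaining(s, artifactSpec(0.5, 0, matrix(1, 3, 3))),
               "mask")
})

test_that("misalignment fields obey their mode contracts", {
  z <- generateMisalignment(misalignmentSpec("smooth_random", amplitude = 0),
                            32, 32)
  expect_true(all(dvfX(z) == 0) && all(dvfY(z) == 0))
  tr <- generateMisalignment(misalignmentSpec("translation",
                                              amplitude = c(4, 0)), 16, 16)
  expect_equal(dvfX(tr), matrix(4, 16, 16))
  expect_equal(dvfY(tr), matrix(0, 16, 16))
  sm <- generateMisalignment(misalignmentSpec("smooth_random", amplitude = 6,
                                              smoothnessScale = 8, seed = 2),
                             64, 64)
  nrm <- sqrt(dvfX(sm)^2 + dvfY(sm)^2)
  expect_equal(max(nrm), 6, tolerance = 1e-6)
  # smoothness: finite-difference gradient magnitude bounded well below the
  # amplitude over one correlation length
  gx <- diff(dvfX(sm))
  expect_lt(max(abs(gx)), 6 / 8 * 3)
  sm2 <- generateMisalignment(misalignmentSpec("smooth_random", amplitude = 6,
                                               smoothnessScale = 8, seed = 2),
                              64, 64)
  expect_identical(dvfX(sm), dvfX(sm2))
})

test_that("undegraded phantoms clear both slide-QC screening thresholds", {
  s <- smallPhantom(seed = 7, n = 25)
  expect_gt(sum(nucleiMask(s)) / length(nucleiMask(s)), 0.01)
  tb <- fovTable(classifyFOVs(heIdeal(s), qcConfig(fov = 96)))
  expect_equal(tb$classification, "well")
  expect_gt(tb$nucleiAreaFraction, 0.01)
  expect_gt(tb$eosinMeanIntensity, 0.07)
})

test_that("phantom raw target encodes the stored true displacement field", {
  set.seed(8)
  s <- generatePhantom(phantomSpec(height = 64, width = 64, nNuclei = 10,
                                   seed = 21),
                       misalignment = misalignmentSpec("smooth_random",
                                                       amplitude = 4,
                                                       seed = 4))
  realigned <- alignTarget(heRaw(s), trueDVF(s), postprocess = FALSE)
  # away from the border, warping the raw target by the true field recovers
  # the aligned rendering within interpolation error
  err <- abs(realigned - heIdeal(s))[10:54, 10:54, ]
  expect_lt(mean(err), 6)
})
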