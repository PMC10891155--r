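# Training-loop mechanics: schedule, normalization, augmentation, counters,
# tiled inference. (The long end-to-end runs live in test-acceptance.R.)

test_that("update ratio follows the decaying schedule with floor 3", {
  expect_equal(updateRatio(0), 12)
  expect_equal(updateRatio(4000), 11)
  expect_equal(updateRatio(48000), 3)
  tds <- seq(0, 1e5, by = 997)
  vals <- updateRatio(tds)
  expect_true(all(vals >= 3))
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals, pmax(3, floor(12 - tds / 4000)))
  expect_error(updateRatio(-1), "non-negative")
})

test_that("patch normalization standardizes per channel", {
  p <- rbind(c(0, 0), c(2, 2))
  expect_equal(normalizePatch(p), rbind(c(-1, -1), c(1, 1)))
  expect_equal(normalizePatch(matrix(7, 5, 5)), matrix(0, 5, 5))
  set.seed(1)
  x <- array(runif(16 * 16 * 2, 3, 9), c(16, 16, 2))
  nx <- normalizePatch(x)
  for (c in 1:2) {
    expect_lt(abs(mean(nx[, , c])), 1e-6)
    expect_lt(abs(sqrt(mean((nx[, , c] - mean(nx[, , c]))^2)) - 1), 1e-6)
  }
})

test_that("augmentation keeps pairs aligned with calibrated frequencies", {
  set.seed(2)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  out <- augmentPair(x, x)
  expect_identical(out$input, out$target)
  # seeded reproducibility
  set.seed(99); a <- augmentPair(x, x)
  set.seed(99); b <- augmentPair(x, x)
  expect_identical(a$input, b$input)
  # empirical frequencies of flips and rotations
  set.seed(3)
  n <- 4000
  marks <- matrix(0, n, 2)
  rots <- integer(n)
  probe <- matrix(0, 4, 4); probe[1, 2] <- 1   # asymmetric marker
  for (i in seq_len(n)) {
    r <- augmentPair(probe, probe)$input
    pos <- which(r == 1, arr.ind = TRUE)
    marks[i, ] <- pos
    rots[i] <- (pos[1] - 1) + (pos[2] - 1) * 4  # location encodes transform
  }
  # each of the 8 distinct dihedral placements of the marker appears;
  # with flips at 1/2 and rotations at 1/4 each placement has frequency 1/8
  tab <- table(rots) / n
  expect_equal(length(tab), 8L)
  expect_true(all(abs(tab - 1 / 8) < 0.03))
})

test_that("a short run maintains schedule conservation and counters", {
  ds <- toyDataset(6, 40, mis = c(2, 4))
  cfg <- toyTrainConfig(5, useR = TRUE, cycles = 3)
  m <- trainRegiStain(ds, cfg)
  st <- trainState(m)
  expect_equal(st$tD, 3L)
  expect_equal(st$itersR, 3L)
  expect_equal(st$itersG, sum(st$lossHistory$ratio))
  # ratio follows the schedule exactly: 12 at t_D = 0, then floor(12 - t_D/4000)
  expect_equal(st$lossHistory$ratio, updateRatio(0:2))
  # best checkpoint bookkeeping matches the recorded minimum
  vals <- c(st$initialValLG, st$lossHistory$valLG)
  expect_equal(st$bestLG, min(vals, na.rm = TRUE))
})

test_that("ablation without the registration network records zero R iterations", {
  ds <- toyDataset(5, 60)
  m <- trainRegiStain(ds, toyTrainConfig(6, useR = FALSE, cycles = 2))
  expect_null(registrationNet(m))
  expect_equal(trainState(m)$itersR, 0L)
  expect_equal(trainState(m)$tD, 2L)
})

test_that("training is reproducible given the seed", {
  ds <- toyDataset(5, 80, mis = c(2, 4))
  m1 <- trainRegiStain(ds, toyTrainConfig(7, cycles = 2))
  m2 <- trainRegiStain(ds, toyTrainConfig(7, cycles = 2))
  expect_identical(netParameters(generatorNet(m1)),
                   netParameters(generatorNet(m2)))
  expect_equal(trainState(m1)$lossHistory$LG, trainState(m2)$lossHistory$LG)
})

test_that("tiled inference is deterministic and matches the direct pass", {
  ds <- toyDataset(4, 120)
  m <- trainRegiStain(ds, toyTrainConfig(8, useR = FALSE, cycles = 2))
  af <- afImage(ds[[1]])
  # single tile: identical to one forward pass
  v1 <- inferVirtualStain(m, af, tile = 64)
  g <- generatorNet(m)
  direct <- netForward(g, normalizePatch(af))
  expect_equal(v1, round(direct * 255))
  expect_identical(v1, inferVirtualStain(m, af, tile = 64))
  # tiled pass with overlap stays close to the untiled pass
  af2 <- afImage(ds[[2]])
  full <- inferVirtualStain(m, af2, tile = 64)
  tiled <- inferVirtualStain(m, af2, tile = 48, overlap = 16)
  expect_lt(mean(abs(tiled - full)) / 255, 1 / 255)
  expect_error(inferVirtualStain(m, array(0, c(64, 64, 3))), "2 channels")
})

test_that("warm start and generator freezing behave as documented", {
  ds <- toyDataset(5, 160)
  base <- trainRegiStain(ds, toyTrainConfig(11, useR = FALSE, cycles = 2))
  p0 <- netParameters(generatorNet(base))
  frozen <- trainRegiStain(ds, toyTrainConfig(12, useR = TRUE, cycles = 2,
                                              freezeG = TRUE), init = base)
  # frozen generator: zero generator iterations, parameters unchanged
  expect_equal(trainState(frozen)$itersG, 0L)
  expect_equal(netParameters(generatorNet(frozen)), p0)
  # registration and discriminator still update
  expect_equal(trainState(frozen)$itersR, 2L)
  expect_equal(trainState(frozen)$tD, 2L)
})

test_that("divergent losses abort with a diagnostic error", {
  ds <- lapply(toyDataset(4, 140), function(s)
    list(af = afImage(s), he = heRaw(s)))
  ds[[1]]$af[1, 1, 1] <- NaN  # poisoned input propagates to a NaN loss
  cfg <- toyTrainConfig(9, useR = FALSE, cycles = 2)
  expect_error(trainRegiStain(ds, cfg), "divergent")
})
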