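# Loss functions against hand evaluations and independent naive oracles.

test_that("BerHu matches hand-evaluated branches and is continuous at delta", {
  expect_equal(berhuLoss(matrix(1), matrix(1), 1), 0)
  expect_equal(berhuLoss(matrix(0.5), matrix(0), 1), 0.5)       # L1 branch
  expect_equal(berhuLoss(matrix(3), matrix(0), 1), 5)           # (9 + 1) / 2
  # continuity and slope continuity across |d| = delta
  d <- 1
  lo <- berhuLoss(matrix(d - 1e-6), matrix(0), d)
  hi <- berhuLoss(matrix(d + 1e-6), matrix(0), d)
  expect_lt(abs(hi - lo), 1e-5)
  g_lo <- (berhuLoss(matrix(d - 1e-6), matrix(0), d) -
           berhuLoss(matrix(d - 2e-6), matrix(0), d)) / 1e-6
  g_hi <- (berhuLoss(matrix(d + 2e-6), matrix(0), d) -
           berhuLoss(matrix(d + 1e-6), matrix(0), d)) / 1e-6
  expect_lt(abs(g_hi - g_lo), 1e-3)
  expect_error(berhuLoss(matrix(1), matrix(0), 0), "delta")
  expect_error(berhuLoss(matrix(1, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("BerHu is non-negative and zero iff equal", {
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
    expect_gte(berhuLoss(a, b, 0.5), 0)
    expect_equal(berhuLoss(a, a, 0.5), 0)
    if (any(a != b)) expect_gt(berhuLoss(a, b, 0.5), 0)
  }
})

test_that("total variation matches interior-difference oracles", {
  expect_equal(tvLoss(matrix(5, 4, 4)), 0)
  expect_equal(tvLoss(rbind(c(0, 1), c(0, 1))), 2)    # two horizontal steps
  L <- 13
  expect_equal(tvLoss(matrix(0:(L - 1), 1, L)), L - 1) # telescoping ramp
  # naive double-loop oracle on random instances
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(rnorm(30), 5, 6)
    ref <- 0
    for (r in 1:4) for (cc in 1:6) ref <- ref + abs(a[r + 1, cc] - a[r, cc])
    for (r in 1:5) for (cc in 1:5) ref <- ref + abs(a[r, cc + 1] - a[r, cc])
    expect_equal(tvLoss(a), ref)
  }
})

test_that("windowed NCC matches the naive double-loop oracle", {
  set.seed(3)
  for (i in 1:6) {
    a <- matrix(runif(40 * 40), 40); b <- matrix(runif(40 * 40), 40)
    expect_equal(nccLoss(a, b, k = 20, stride = 1), naiveNCC(a, b, 20),
                 tolerance = 1e-10)
  }
  a <- matrix(runif(40 * 40), 40)
  expect_gt(nccLoss(a, a, 20), 1 - 1e-3)               # self-correlation
  expect_lt(nccLoss(a, -a + 7, 20), -1 + 1e-3)         # anti-correlation
  expect_error(nccLoss(matrix(0, 5, 5), matrix(0, 5, 5), k = 20), "at least")
})

test_that("NCC is invariant to positive affine intensity maps", {
  set.seed(4)
  a <- matrix(runif(30 * 30), 30); b <- matrix(runif(30 * 30), 30)
  base <- nccLoss(a, b, k = 10)
  expect_equal(nccLoss(a, 3.7 * b + 0.4, k = 10), base, tolerance = 1e-3)
  expect_equal(nccLoss(0.2 * a + 5, b, k = 10), base, tolerance = 1e-3)
})

test_that("losses are equivariant under simultaneous flips of both images", {
  set.seed(5)
  a <- matrix(runif(24 * 24), 24); b <- matrix(runif(24 * 24), 24)
  fl <- function(m) m[nrow(m):1, ncol(m):1]
  expect_equal(berhuLoss(fl(a), fl(b), 0.3), berhuLoss(a, b, 0.3))
  expect_equal(tvLoss(fl(a)), tvLoss(a))
  expect_equal(nccLoss(fl(a), fl(b), k = 12), nccLoss(a, b, k = 12),
               tolerance = 1e-12)
})

test_that("strided NCC approximates the dense value on stationary textures", {
  set.seed(6)
  a <- matrix(runif(60 * 60), 60); b <- a + matrix(rnorm(3600, 0, 0.3), 60)
  dense <- nccLoss(a, b, k = 20, stride = 1)
  coarse <- nccLoss(a, b, k = 20, stride = 20)
  expect_lt(abs(dense - coarse), 0.1)
})

test_that("generator loss assembles its components", {
  set.seed(7)
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(runif(32 * 32 * 3), c(32, 32, 3))
  cfg <- lossConfig()
  lg <- generatorLoss(a, b, 0.3, cfg)
  delta <- max(cfg$deltaFrac * sqrt(mean((b - mean(b))^2)), 1e-6)
  expect_equal(lg$delta, delta)
  expect_equal(lg$total,
               berhuLoss(a, b, delta) + cfg$alpha * tvLoss(a) +
                 cfg$beta * (1 - 0.3)^2, tolerance = 1e-9)
  # identical non-constant pair with a perfect discriminator: only TV remains
  lg2 <- generatorLoss(a, a, 1, cfg)
  expect_equal(lg2$total, cfg$alpha * tvLoss(a), tolerance = 1e-9)
  # fooled-discriminator floor on zero images: beta * 1
  z <- array(0, c(24, 24, 3))
  lg3 <- generatorLoss(z, z, 0, cfg)
  expect_equal(lg3$total, cfg$beta)
})

test_that("discriminator loss follows the squared-probability form", {
  expect_equal(discriminatorLoss(0, 1), 0)      # perfect
  expect_equal(discriminatorLoss(0.5, 0.5), 0.5)
  expect_equal(discriminatorLoss(1, 0), 2)      # worst
  expect_error(discriminatorLoss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("registration loss combines NCC and DVF total variation", {
  set.seed(8)
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  cfg <- lossConfig()
  d0 <- DisplacementField(2, 2, 32, 32)
  lr <- registrationLoss(a, a, d0, cfg)
  expect_lt(lr$total, 1e-3)                      # aligned pair, constant field
  lr2 <- registrationLoss(a, -a + 1, d0, cfg)
  expect_equal(lr2$total, 2, tolerance = 1e-2)   # anti-correlated: 1 - (-1)
  b <- array(runif(32 * 32 * 3), c(32, 32, 3))
  d <- DisplacementField(matrix(rnorm(1024), 32), matrix(rnorm(1024), 32))
  lr3 <- registrationLoss(a, b, d, cfg)
  expect_equal(lr3$total,
               1 - nccLoss(a, b, k = cfg$nccK) + tvLoss(dvfX(d)) +
                 tvLoss(dvfY(d)), tolerance = 1e-9)
})
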