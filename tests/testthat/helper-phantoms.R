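# Shared fixtures: small phantoms and toy training configurations.

smallPhantom <- function(seed = 3, n = 20, H = 96, ...) {
  generatePhantom(phantomSpec(height = H, width = H, nNuclei = n,
                              seed = seed, ...))
}

# Toy study conditions: 64 px phantoms. Misaligned datasets combine ONE
# shared smooth field (the systematic slide-level residual deformation left
# by coarse registration; ~2/3 of the amplitude) with small smooth
# per-image jitter, for a combined per-image amplitude in the 4-6 px range;
# translation mode applies one constant shift to every image.
toyDataset <- function(n, seed0, mis = NULL, mode = "smooth_random",
                       H = 64, nNuclei = 12) {
  shared <- NULL; ampS <- 0
  if (!is.null(mis) && mode != "translation") {
    set.seed(seed0)
    ampS <- stats::runif(1, mis[1], mis[2]) * 2 / 3
    shared <- generateMisalignment(
      misalignmentSpec("smooth_random", amplitude = ampS,
                       smoothnessScale = 24, seed = seed0 + 13L), H, H)
  }
  lapply(seq_len(n), function(i) {
    m <- NULL
    if (!is.null(mis)) {
      if (mode == "translation") {
        m <- misalignmentSpec("translation", amplitude = c(mis, 0))
      } else {
        jit <- generateMisalignment(
          misalignmentSpec("smooth_random", amplitude = ampS / 2,
                           smoothnessScale = 24, seed = seed0 + 500L + i),
          H, H)
        m <- DisplacementField(dvfX(shared) + dvfX(jit),
                               dvfY(shared) + dvfY(jit))
      }
    }
    set.seed(seed0 + 7777 + i)
    generatePhantom(phantomSpec(height = H, width = H, nNuclei = nNuclei,
                                nucleusRadiusRange = c(2.5, 5),
                                backgroundFraction = 0.1, seed = seed0 + i),
                    misalignment = m)
  })
}

toyTrainConfig <- function(seed, useR = TRUE, cycles = 300, lrR = 1e-2,
                           freezeG = FALSE) {
  trainConfig(lrG = 1e-3, lrR = lrR, lrD = 1e-4, batchSize = 4, patch = 64,
              maxCycles = cycles, seed = seed, useRegistrationNet = useR,
              net = netConfig(depth = 2, baseFilters = 8, seed = seed),
              valEvery = 25, augment = FALSE, nccStrideTrain = 4,
              freezeGenerator = freezeG)
}

# independent 4/8-connected labeling oracle (queue-based flood fill in R)
floodLabel <- function(mask, eight = TRUE) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  offs <- if (eight) expand.grid(dy = -1:1, dx = -1:1) else
    data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        ni <- p[1] + offs$dy[o]; nj <- p[2] + offs$dx[o]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# brute-force windowed NCC oracle (naive double loop)
naiveNCC <- function(a, b, k, stride = 1, eps = 1e-5) {
  vals <- c()
  for (i in seq(1, nrow(a) - k + 1, by = stride))
    for (j in seq(1, ncol(a) - k + 1, by = stride)) {
      wa <- a[i:(i + k - 1), j:(j + k - 1)]
      wb <- b[i:(i + k - 1), j:(j + k - 1)]
      sa <- sqrt(mean((wa - mean(wa))^2)); sb <- sqrt(mean((wb - mean(wb))^2))
      vals <- c(vals, mean((wa - mean(wa)) * (wb - mean(wb))) / (sa * sb + eps))
    }
  mean(vals)
}
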