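# Internal helpers shared across modules.
#
# Image convention: numeric arrays dim (H, W, C) or matrices (H, W),
# 0-based concepts documented as 1-based R indices (row, col), top-left
# origin. Displacements are stored as (dx = column shift, dy = row shift).

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.asChannels <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
}

# luminance reduction used wherever a single-channel view of an image is
# needed (registration, screening): plain channel mean
.lum <- function(img) {
  img <- .asChannels(img)
  if (dim(img)[3] == 1L) return(img[, , 1L])
  apply(img, c(1, 2), mean)
}

# 3x3 separable binomial kernel [1,2,1]/4 with replicate borders
.gauss3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- m[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  v <- (up + 2 * m + dn) / 4
  lf <- v[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- v[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  (lf + 2 * v + rt) / 4
}

# separable Gaussian filter of arbitrary sigma, replicate borders
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in -r:r) {
    idx <- .clamp(seq_len(H) + i, 1L, H)
    out <- out + k[i + r + 1] * m[idx, , drop = FALSE]
  }
  res <- matrix(0, H, W)
  for (i in -r:r) {
    idx <- .clamp(seq_len(W) + i, 1L, W)
    res <- res + k[i + r + 1] * out[, idx, drop = FALSE]
  }
  res
}

# population standard deviation (matches the whole-image SSIM statistics)
.sdPop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

.assertSameShape <- function(a, b, what = "images") {
  if (!identical(dim(.asChannels(a)), dim(.asChannels(b))))
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
}

# evaluate f with the global RNG seeded to `seed`, restoring prior state
.withSeed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}
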