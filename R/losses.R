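# Training losses: reverse Huber (BerHu), total variation, windowed
# normalized cross-correlation, and the generator / discriminator /
# registration objectives assembled from them.

#' Loss configuration
#'
#' @param alpha total-variation weight in the generator loss (default 0.02)
#' @param beta adversarial weight in the generator loss (default 50)
#' @param deltaFrac BerHu threshold as a fraction of the per-image standard
#'   deviation of the registered target (default 0.2)
#' @param nccK NCC window size in pixels (default 20)
#' @param nccEps small positive stabilizer added to the NCC denominator
#' @param nccStride window stride; 1 evaluates every window placement
#'   (summed-area tables keep this cheap); larger strides subsample
#' @return classed list of settings
#' @export
lossConfig <- function(alpha = 0.02, beta = 50, deltaFrac = 0.2,
                       nccK = 20, nccEps = 1e-5, nccStride = 1) {
  stopifnot(alpha > 0, beta > 0, deltaFrac > 0, nccK > 0, nccEps > 0,
            nccStride >= 1)
  structure(list(alpha = alpha, beta = beta, deltaFrac = deltaFrac,
                 nccK = as.integer(nccK), nccEps = nccEps,
                 nccStride = as.integer(nccStride)),
            class = "lossConfig")
}

#' Reverse Huber (BerHu) loss
#'
#' Sum over pixels (and channels) of `|d|` where `|d| <= delta`, and
#' `(d^2 + delta^2) / (2 delta)` where `|d| > delta`; continuous and once
#' differentiable at the threshold.
#'
#' @param a,b images of identical shape
#' @param delta positive threshold (intensity units)
#' @return scalar loss
#' @examples
#' berhuLoss(matrix(3), matrix(0), delta = 1)  # (9 + 1) / 2 = 5
#' @export
berhuLoss <- function(a, b, delta) {
  .assertSameShape(a, b)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar")
  d <- abs(a - b)
  big <- d > delta
  sum(d[!big]) + sum((d[big]^2 + delta^2) / (2 * delta))
}

.berhuGrad <- function(a, b, delta) {
  d <- a - b
  g <- sign(d)
  big <- abs(d) > delta
  g[big] <- d[big] / delta
  g
}

#' Anisotropic total variation
#'
#' Sum of absolute vertical and horizontal first differences over interior
#' index pairs (no wraparound, no ghost pixels), summed over channels.
#'
#' @param a matrix or (H, W, C) array
#' @return scalar loss
#' @examples
#' tvLoss(rbind(c(0, 1), c(0, 1)))  # two horizontal unit steps -> 2
#' @export
tvLoss <- function(a) {
  x <- .asChannels(a)
  H <- dim(x)[1]; W <- dim(x)[2]
  s <- 0
  if (H > 1) s <- s + sum(abs(x[-1, , , drop = FALSE] - x[-H, , , drop = FALSE]))
  if (W > 1) s <- s + sum(abs(x[, -1, , drop = FALSE] - x[, -W, , drop = FALSE]))
  s
}

.tvGrad <- function(a) {
  g <- tv_grad(.asChannels(a) * 1.0)
  if (is.matrix(a)) g[, , 1] else g
}

# window sums of all k x k windows at given stride via summed-area table
.winSums <- function(m, k, stride) {
  H <- nrow(m); W <- ncol(m)
  s <- matrix(0, H + 1, W + 1)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i <- seq(1, H - k + 1, by = stride)
  j <- seq(1, W - k + 1, by = stride)
  s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
    s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]
}

#' Windowed normalized cross-correlation
#'
#' Mean over all `k x k` window placements (at the given stride) of the
#' windowed Pearson correlation between `a` and `b`, with a small stabilizer
#' in the denominator; windows with zero variance contribute 0. Channels are
#' averaged. Value lies in `[-1, 1]` up to the stabilizer.
#'
#' @param a,b images of identical shape, at least `k` pixels in each dimension
#' @param k window size in pixels (default 20)
#' @param stride window stride (default 1: every placement)
#' @param eps denominator stabilizer
#' @return scalar in approximately `[-1, 1]`
#' @export
nccLoss <- function(a, b, k = 20, stride = 1, eps = 1e-5) {
  .assertSameShape(a, b)
  xa <- .asChannels(a); xb <- .asChannels(b)
  H <- dim(xa)[1]; W <- dim(xa)[2]
  if (H < k || W < k) stop(sprintf("images must be at least %d x %d", k, k))
  k2 <- k * k
  tot <- 0
  for (c in seq_len(dim(xa)[3])) {
    pa <- xa[, , c]; pb <- xb[, , c]
    sa <- .winSums(pa, k, stride);  sb <- .winSums(pb, k, stride)
    saa <- .winSums(pa * pa, k, stride); sbb <- .winSums(pb * pb, k, stride)
    sab <- .winSums(pa * pb, k, stride)
    mua <- sa / k2; mub <- sb / k2
    va <- pmax(saa / k2 - mua^2, 0); vb <- pmax(sbb / k2 - mub^2, 0)
    cov <- sab / k2 - mua * mub
    tot <- tot + mean(cov / (sqrt(va * vb) + eps))
  }
  tot / dim(xa)[3]
}

# gradient of nccLoss w.r.t. its second argument (compiled window loop;
# used by the registration step where the window grid is coarse)
.nccGradB <- function(a, b, k = 20, stride = 1, eps = 1e-5) {
  xa <- .asChannels(a); xb <- .asChannels(b)
  g <- ncc_grad_b(xa * 1.0, xb * 1.0, as.integer(k), as.integer(stride), eps)
  array(g, dim(xb))
}

#' Generator objective
#'
#' `BerHu(I_VS, I_HSreg, delta) + alpha * TV(I_VS) + beta * (1 - D(I_VS))^2`
#' where `delta = deltaFrac * SD(I_HSreg)` (per-image population SD, floored
#' at 1e-6 for constant targets) and `D(.)` is the discriminator probability.
#'
#' @param iVS generator output image
#' @param iHSreg registered histology target, same shape
#' @param dOfVS discriminator probability/ies in `[0, 1]` for `iVS` (a batch
#'   mean is used when a vector is supplied)
#' @param cfg a [lossConfig()]
#' @return list with `total` and the `berhu`, `tv`, `adv`, `delta` components
#' @export
generatorLoss <- function(iVS, iHSreg, dOfVS, cfg = lossConfig()) {
  .assertSameShape(iVS, iHSreg)
  if (any(dOfVS < 0 | dOfVS > 1)) stop("dOfVS must lie in [0, 1]")
  delta <- max(cfg$deltaFrac * .sdPop(iHSreg), 1e-6)
  bh <- berhuLoss(iVS, iHSreg, delta)
  tv <- tvLoss(iVS)
  adv <- mean((1 - dOfVS)^2)
  list(total = bh + cfg$alpha * tv + cfg$beta * adv,
       berhu = bh, tv = tv, adv = adv, delta = delta)
}

#' Discriminator objective
#'
#' `D(I_VS)^2 + (1 - D(I_HSraw))^2`; the raw (unregistered) histology image
#' serves as the real example so that no input-target alignment is needed.
#' Vector inputs are averaged element-wise (batch mean).
#'
#' @param dOfVS discriminator probability/ies for generated images
#' @param dOfReal discriminator probability/ies for real histology images
#' @return scalar loss
#' @examples
#' discriminatorLoss(0, 1)    # perfect discriminator -> 0
#' discriminatorLoss(1, 0)    # worst case -> 2
#' @export
discriminatorLoss <- function(dOfVS, dOfReal) {
  if (any(dOfVS < 0 | dOfVS > 1) || any(dOfReal < 0 | dOfReal > 1))
    stop("discriminator outputs must lie in [0, 1]")
  mean(dOfVS^2) + mean((1 - dOfReal)^2)
}

#' Registration objective
#'
#' `1 - NCC(I_VS, I_HSreg, k) + tvWeight * TV(dvf)` where the total
#' variation sums both displacement planes. With the default `tvWeight = 1`
#' this is the printed objective; the trainer passes
#' `tvWeight = 1 / (H * W)` so the regularizer is a per-pixel mean -- a sum
#' would grow with patch area and drown the correlation term's gradient,
#' freezing the field at zero (the balance must be patch-size invariant for
#' one coefficient to serve all scales).
#'
#' @param iVS generator output
#' @param iHSreg registered target
#' @param dvf the (post-processed) [DisplacementField-class]
#' @param cfg a [lossConfig()]
#' @param tvWeight weight of the displacement total-variation term
#' @return list with `total`, `ncc`, `tvDVF` (unweighted)
#' @export
registrationLoss <- function(iVS, iHSreg, dvf, cfg = lossConfig(),
                             tvWeight = 1) {
  ncc <- nccLoss(iVS, iHSreg, k = cfg$nccK, stride = cfg$nccStride,
                 eps = cfg$nccEps)
  tvd <- tvLoss(dvfX(dvf)) + tvLoss(dvfY(dvf))
  list(total = 1 - ncc + tvWeight * tvd, ncc = ncc, tvDVF = tvd)
}
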