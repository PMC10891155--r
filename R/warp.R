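# Displacement-field post-processing and differentiable sub-pixel warping
# (the spatial transformation module).

#' Displacement post-processing configuration
#'
#' The raw field predicted by the registration network is (1) smoothed per
#' plane with a 3x3 Gaussian kernel (separable `[1,2,1]/4`, replicate
#' borders), (2) clipped per plane to mean +/- `adaptiveClipSD` standard
#' deviations computed on that smoothed plane, and (3) clipped to
#' `[-absClip, absClip]` pixels, in that order.
#'
#' @param adaptiveClipSD outlier clip width in standard deviations (default 3)
#' @param absClip absolute displacement bound in pixels (default 30)
#' @return classed list of settings
#' @export
dvfPostConfig <- function(adaptiveClipSD = 3, absClip = 30) {
  if (absClip <= 0) stop("absClip must be > 0")
  if (adaptiveClipSD <= 0) stop("adaptiveClipSD must be > 0")
  structure(list(adaptiveClipSD = adaptiveClipSD, absClip = absClip),
            class = "dvfPostConfig")
}

# per-plane pipeline; returns plane plus the pass-through mask used by the
# straight-through gradient during training
.postPlane <- function(p, cfg) {
  sm <- .gauss3(p)
  mu <- mean(sm); s <- .sdPop(sm)
  lo <- max(mu - cfg$adaptiveClipSD * s, -cfg$absClip)
  hi <- min(mu + cfg$adaptiveClipSD * s, cfg$absClip)
  out <- .clamp(sm, lo, hi)
  list(plane = out, mask = (sm >= lo) & (sm <= hi))
}

#' Post-process a raw displacement field
#'
#' Applies, in order: 3x3 Gaussian smoothing per plane (replicate borders),
#' per-plane clipping to mean +/- 3 SD of the smoothed plane, and absolute
#' clipping to `[-30, 30]` pixels (defaults of [dvfPostConfig()]).
#'
#' @param dvf a [DisplacementField-class] (finite values required)
#' @param cfg a [dvfPostConfig()]
#' @return the post-processed [DisplacementField-class]
#' @examples
#' d <- DisplacementField(100, 0, height = 8, width = 8)
#' range(dvfX(postprocessDVF(d)))   # clipped to 30
#' @export
postprocessDVF <- function(dvf, cfg = dvfPostConfig()) {
  stopifnot(is(dvf, "DisplacementField"))
  if (!all(is.finite(dvf@dx)) || !all(is.finite(dvf@dy)))
    stop("displacement field contains non-finite values")
  DisplacementField(.postPlane(dvf@dx, cfg)$plane,
                    .postPlane(dvf@dy, cfg)$plane)
}

# bilinear sample positions with border replication; shared by forward/grad;
# returns linear indices of the four corners plus interpolation weights
.warpCoords <- function(H, W, dvf) {
  xs <- rep(seq_len(W), each = H) + as.vector(dvf@dx)
  ys <- rep.int(seq_len(H), W) + as.vector(dvf@dy)
  inx <- xs >= 1 & xs <= W
  iny <- ys >= 1 & ys <= H
  xs <- .clamp(xs, 1, W); ys <- .clamp(ys, 1, H)
  x0 <- floor(xs); y0 <- floor(ys)
  x0 <- pmin(x0, W - 1); y0 <- pmin(y0, H - 1)  # keep x1,y1 in range
  if (W == 1) x0 <- pmax(x0, 1)
  if (H == 1) y0 <- pmax(y0, 1)
  x1 <- pmin(x0 + 1, W); y1 <- pmin(y0 + 1, H)
  list(wx = xs - x0, wy = ys - y0,
       k00 = y0 + H * (x0 - 1), k01 = y0 + H * (x1 - 1),
       k10 = y1 + H * (x0 - 1), k11 = y1 + H * (x1 - 1),
       inx = inx, iny = iny)
}

#' Warp an image by a displacement field
#'
#' Differentiable sub-pixel warping: `out(p) = bilinear(img, p + d(p))`, with
#' border replication for out-of-bounds samples. Gradients with respect to
#' both the image and the field are available via [warpImageGrad()].
#'
#' @param img matrix (H, W) or array (H, W, C)
#' @param dvf a [DisplacementField-class] with matching height/width
#' @return warped image with the shape of `img`
#' @examples
#' img <- matrix(1:16, 4, 4)
#' identical(warpImage(img, DisplacementField(0, 0, 4, 4)), img * 1)
#' @export
warpImage <- function(img, dvf) {
  stopifnot(is(dvf, "DisplacementField"))
  x <- .asChannels(img)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (!identical(dim(dvf@dx), c(H, W)))
    stop("image and displacement field dimensions differ")
  out <- warp_bilinear(x, dvf@dx, dvf@dy)
  if (is.matrix(img)) out[, , 1] else out
}

#' Gradients of [warpImage()]
#'
#' Back-propagates an upstream gradient through the bilinear sampler,
#' returning gradients with respect to the source image and to both
#' displacement planes. Samples clamped by border replication have zero
#' field gradient.
#'
#' @param img source image as in [warpImage()]
#' @param dvf the displacement field used in the forward pass
#' @param dout upstream gradient, same shape as the warp output
#' @return list with `dimg`, `ddx`, `ddy`
#' @export
warpImageGrad <- function(img, dvf, dout) {
  x <- .asChannels(img); g <- .asChannels(dout)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  cs <- .warpCoords(H, W, dvf)
  wx <- cs$wx; wy <- cs$wy
  k00 <- cs$k00; k01 <- cs$k01; k10 <- cs$k10; k11 <- cs$k11
  live <- cs$inx & cs$iny
  dimg <- array(0, dim(x))
  ddx <- matrix(0, H, W); ddy <- matrix(0, H, W)
  scatter <- function(idx, val) {
    u <- sort.int(unique(idx))
    a <- rowsum(val, idx, reorder = TRUE)
    v <- numeric(H * W)
    v[u] <- a
    v
  }
  for (c in seq_len(C)) {
    p <- as.vector(x[, , c]); gc <- as.vector(g[, , c])
    dimg[, , c] <- dimg[, , c] +
      matrix(scatter(k00, gc * (1 - wy) * (1 - wx)) +
             scatter(k01, gc * (1 - wy) * wx) +
             scatter(k10, gc * wy * (1 - wx)) +
             scatter(k11, gc * wy * wx), H, W)
    dvx <- (1 - wy) * (p[k01] - p[k00]) + wy * (p[k11] - p[k10])
    dvy <- (1 - wx) * (p[k10] - p[k00]) + wx * (p[k11] - p[k01])
    ddx <- ddx + matrix(gc * dvx * as.numeric(cs$inx), H, W)
    ddy <- ddy + matrix(gc * dvy * as.numeric(cs$iny), H, W)
  }
  void <- !live  # fully replicated corner: no image-position sensitivity at all
  list(dimg = if (is.matrix(img)) dimg[, , 1] else dimg, ddx = ddx, ddy = ddy,
       clampedFraction = mean(void))
}

#' Align a raw histology target to the generator output
#'
#' Warps the original raw histochemical target by the post-processed
#' displacement field predicted by the registration network, producing the
#' dynamically registered training target. Always computed from the original
#' raw image, never from a previously warped copy, to avoid cumulative
#' resampling blur.
#'
#' @param heRaw RGB image (H, W, 3)
#' @param dvf a raw [DisplacementField-class] (will be post-processed)
#' @param cfg a [dvfPostConfig()]
#' @param postprocess set to `FALSE` if `dvf` is already post-processed
#' @return the registered target image
#' @export
alignTarget <- function(heRaw, dvf, cfg = dvfPostConfig(), postprocess = TRUE) {
  if (postprocess) dvf <- postprocessDVF(dvf, cfg)
  warpImage(heRaw, dvf)
}
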