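# Training-data preparation: coarse two-step registration (whole-slide
# rigid, per-tile affine), tiling into training FOVs with center cropping,
# and PSNR/SSIM screening of training pairs.
#
# Coordinate convention: 1-based (row, col), top-left origin; shifts are
# (dx = columns, dy = rows). Affine matrices act on coordinates centered at
# the image center and map reference (fixed) coordinates of the aligned
# output to source coordinates is the *resampling* direction; the returned
# matrix maps moving -> fixed coordinates (its inverse is used to resample).

#' Screening configuration for training pairs
#'
#' Pairs whose pre-screening virtual staining falls below a PSNR of 15 dB
#' or an SSIM of 0.6 against the histology target are rejected; boundary
#' values are kept.
#'
#' @param psnrMin minimum PSNR in dB (default 15)
#' @param ssimMin minimum SSIM (default 0.6)
#' @export
screenConfig <- function(psnrMin = 15, ssimMin = 0.6) {
  stopifnot(psnrMin > 0, ssimMin > 0, ssimMin <= 1)
  structure(list(psnrMin = psnrMin, ssimMin = ssimMin),
            class = "screenConfig")
}

# bilinear rotation (degrees, about the image center, zero fill)
.rotateImage <- function(img, degrees) {
  k <- degrees / 90
  if (abs(k - round(k)) < 1e-9) return(.rot90(.asChannels(img), round(k)))
  x <- .asChannels(img)
  H <- dim(x)[1]; W <- dim(x)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  cols <- matrix(rep(seq_len(W), each = H), H, W) - cx
  rows <- matrix(rep(seq_len(H), W), H, W) - cy
  # backward map: rotate output coords by -theta
  sx <- co * cols + si * rows + cx
  sy <- -si * cols + co * rows + cy
  out <- array(0, dim(x))
  inb <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  d <- DisplacementField(sx - (cols + cx), sy - (rows + cy))
  w <- warpImage(x, d)
  for (c in seq_len(dim(x)[3])) out[, , c] <- ifelse(inb, w[, , c], 0)
  out
}

# frequency-domain cross-correlation r(u) = sum_p a(p) * b(p + u) on a
# common zero-padded grid (no circular aliasing)
.xcorrFFT <- function(a, b, Hp, Wp) {
  ap <- matrix(0, Hp, Wp); bp <- matrix(0, Hp, Wp)
  ap[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  bp[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  Re(fft(Conj(fft(ap)) * fft(bp), inverse = TRUE)) / (Hp * Wp)
}

#' Rigid whole-slide registration by maximum cross-correlation coefficient
#'
#' Searches a grid of rotation angles; for each angle the moving image is
#' de-rotated and the integer shift maximizing the overlap-restricted
#' Pearson cross-correlation coefficient of the mean-subtracted luminance
#' images is found (frequency-domain products; means and variances are
#' computed within each overlap, so partial overlaps are comparable).
#' Shifts with less than 25% overlap are excluded. The returned angle/shift
#' describe the moving image relative to the fixed one
#' (`moving ~ translate(rotate(fixed, angle), shift)`). Ties are broken by
#' smallest `|shift|`, then smallest `|angle|`.
#'
#' @param moving,fixed images (any channel count; luminance mean is used)
#' @param angleGrid candidate rotation angles in degrees
#' @param minOverlap minimum admissible overlap fraction of the fixed image
#' @return list with `angle` (degrees), `shift` (`c(dx, dy)` pixels), and
#'   the correlation coefficient `cc`
#' @export
rigidRegisterWSI <- function(moving, fixed, angleGrid = c(0, 90, -90, 180),
                             minOverlap = 0.25) {
  fl <- .lum(fixed); ml <- .lum(moving)
  if (length(fl) == 0 || length(ml) == 0) stop("empty image")
  if (.sdPop(fl) == 0 || .sdPop(ml) == 0)
    stop("constant image: cross-correlation undefined")
  fl <- fl - mean(fl)
  best <- NULL
  for (a in angleGrid) {
    mr <- .lum(.rotateImage(ml, -a))
    mr <- mr - mean(mr)
    Hp <- nrow(fl) + nrow(mr); Wp <- ncol(fl) + ncol(mr)
    onesF <- matrix(1, nrow(fl), ncol(fl))
    onesM <- matrix(1, nrow(mr), ncol(mr))
    sfm <- .xcorrFFT(fl, mr, Hp, Wp)
    sf <- .xcorrFFT(fl, onesM, Hp, Wp)
    sm <- .xcorrFFT(onesF, mr, Hp, Wp)
    sff <- .xcorrFFT(fl^2, onesM, Hp, Wp)
    smm <- .xcorrFFT(onesF, mr^2, Hp, Wp)
    ov <- pmax(round(.xcorrFFT(onesF, onesM, Hp, Wp)), 1)
    # per-overlap Pearson correlation coefficient
    cov <- sfm - sf * sm / ov
    vf <- pmax(sff - sf^2 / ov, 0)
    vm <- pmax(smm - sm^2 / ov, 0)
    cc <- cov / (sqrt(vf * vm) + 1e-9)
    cc[ov < minOverlap * length(fl)] <- -Inf
    mx <- max(cc)
    pk <- which(cc == mx, arr.ind = TRUE)
    for (row in seq_len(nrow(pk))) {
      dy <- unname(pk[row, 1]) - 1; dx <- unname(pk[row, 2]) - 1
      if (dy > Hp / 2) dy <- dy - Hp
      if (dx > Wp / 2) dx <- dx - Wp
      cand <- list(angle = a, shift = c(dx, dy), cc = mx)
      if (is.null(best) || cand$cc > best$cc + 1e-9 ||
          (abs(cand$cc - best$cc) <= 1e-9 &&
           (sum(cand$shift^2) < sum(best$shift^2) ||
            (sum(cand$shift^2) == sum(best$shift^2) &&
             abs(cand$angle) < abs(best$angle)))))
        best <- cand
    }
  }
  best
}

# apply a 2x3 affine (moving -> fixed, centered coords) by backward sampling
#' Resample an image under an affine transform
#'
#' `M` is a 2 x 3 matrix mapping moving-image coordinates (centered at the
#' image center) to fixed/reference coordinates; the output is the moving
#' image rendered on the fixed grid (bilinear, replicate borders).
#'
#' @param img image to transform
#' @param M 2 x 3 affine matrix (linear part must be invertible)
#' @return transformed image, same size
#' @export
applyAffine <- function(img, M) {
  A <- M[, 1:2]; t <- M[, 3]
  if (abs(det(A)) < 1e-12) stop("affine linear part is singular")
  x <- .asChannels(img)
  H <- dim(x)[1]; W <- dim(x)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  cols <- matrix(rep(seq_len(W), each = H), H, W) - cx
  rows <- matrix(rep(seq_len(H), W), H, W) - cy
  Ai <- solve(A)
  sx <- Ai[1, 1] * (cols - t[1]) + Ai[1, 2] * (rows - t[2])
  sy <- Ai[2, 1] * (cols - t[1]) + Ai[2, 2] * (rows - t[2])
  out <- warpImage(x, DisplacementField(sx - cols, sy - rows))
  if (is.matrix(img)) out[, , 1] else out
}

.affineCriterion <- function(moving, fixed, M, criterion) {
  w <- .lum(applyAffine(moving, M))
  f <- .lum(fixed)
  if (criterion == "ncc") {
    s <- .sdPop(w) * .sdPop(f)
    if (s == 0) return(0)
    return(abs(mean((w - mean(w)) * (f - mean(f))) / s))
  }
  # mutual information on 32-bin joint histogram
  nb <- 32
  qz <- function(v) pmin(floor((v - min(v)) / max(diff(range(v)), 1e-12) * nb) + 1, nb)
  jj <- table(factor(qz(as.vector(w)), levels = 1:nb),
              factor(qz(as.vector(f)), levels = 1:nb))
  p <- jj / sum(jj)
  px <- rowSums(p); py <- colSums(p)
  nzi <- p > 0
  sum(p[nzi] * log(p[nzi] / (px[row(p)[nzi]] * py[col(p)[nzi]])))
}

#' Multi-modal affine registration of an image patch
#'
#' Optimizes a 6-parameter affine transform of the moving patch against the
#' fixed patch by Nelder-Mead over a two-level image pyramid. The default
#' criterion is the absolute Pearson correlation of luminance (robust to the
#' contrast inversion between modalities); mutual information is available
#' via `criterion = "mi"`.
#'
#' @param moving,fixed patches of equal size
#' @param criterion `"ncc"` (absolute correlation) or `"mi"`
#' @param maxIter optimizer iteration budget per pyramid level
#' @param minCriterion value below which the result is flagged degenerate
#'   and the identity is returned
#' @return list with `matrix` (2 x 3, moving -> fixed, centered
#'   coordinates), `value` (criterion at the optimum), `criterion`, and
#'   `lowCriterion` flag
#' @export
affineRegisterPatch <- function(moving, fixed, criterion = c("ncc", "mi"),
                                maxIter = 200, minCriterion = 0.1) {
  criterion <- match.arg(criterion)
  .assertSameShape(moving, fixed, "patches")
  idM <- cbind(diag(2), c(0, 0))
  par2M <- function(p) cbind(matrix(p[1:4], 2, 2), p[5:6])
  obj <- function(p, mv, fx) -.affineCriterion(mv, fx, par2M(p), criterion)
  p0 <- c(1, 0, 0, 1, 0, 0)
  # coarse level (half resolution) then full resolution
  half <- function(img) {
    x <- .asChannels(img)
    x[seq(1, dim(x)[1] - 1, 2), seq(1, dim(x)[2] - 1, 2), , drop = FALSE]
  }
  lvls <- if (min(dim(.asChannels(moving))[1:2]) >= 64)
    list(list(mv = half(moving), fx = half(fixed), sc = 0.5),
         list(mv = moving, fx = fixed, sc = 1)) else
    list(list(mv = moving, fx = fixed, sc = 1))
  p <- p0
  for (lv in lvls) {
    pl <- p; pl[5:6] <- pl[5:6] * lv$sc
    fit <- stats::optim(pl, obj, mv = lv$mv, fx = lv$fx,
                        method = "Nelder-Mead",
                        control = list(maxit = maxIter,
                                       parscale = c(rep(0.01, 4), 1, 1)))
    p <- fit$par; p[5:6] <- p[5:6] / lv$sc
  }
  val <- .affineCriterion(moving, fixed, par2M(p), criterion)
  id0 <- .affineCriterion(moving, fixed, idM, criterion)
  if (!is.finite(val) || val < minCriterion || val < id0)
    return(list(matrix = idM, value = id0, criterion = criterion,
                lowCriterion = id0 < minCriterion))
  if (abs(det(par2M(p)[, 1:2])) < 1e-6)
    stop("affine optimization produced a singular transform")
  list(matrix = par2M(p), value = val, criterion = criterion,
       lowCriterion = val < minCriterion)
}

#' Tile a coarsely registered slide pair into training FOVs
#'
#' Partitions both slides into non-overlapping `tile x tile` FOVs, refines
#' each histology tile with [affineRegisterPatch()] (optional), center-crops
#' both tiles by `(tile - crop) / 2` per side, and discards tiles whose
#' cropped histology contains less than `minTissue` tissue.
#'
#' @param afWsi autofluorescence slide (H, W, 2)
#' @param heWsi registered histology slide (H, W, 3), `0..255`
#' @param tile tile size (production default 3248)
#' @param crop center-crop size (production default 2048)
#' @param registerTiles run the per-tile affine refinement
#' @param minTissue minimum tissue fraction of the cropped histology tile
#' @param backgroundThreshold tissue = luminance below this 8-bit value
#' @return list of pairs, each `list(af, he, row, col, affine,
#'   tissueFraction)`; offsets are the 1-based top-left corner of the crop
#' @export
tilePairedWSI <- function(afWsi, heWsi, tile = 3248, crop = 2048,
                          registerTiles = TRUE, minTissue = 0.05,
                          backgroundThreshold = 235) {
  af <- .asChannels(afWsi); he <- .asChannels(heWsi)
  if (!identical(dim(af)[1:2], dim(he)[1:2]))
    stop("slides must have identical height/width after coarse registration")
  H <- dim(af)[1]; W <- dim(af)[2]
  if (H < tile || W < tile)
    stop(sprintf("slide (%d x %d) is smaller than one %d-px tile", H, W, tile))
  if ((tile - crop) %% 2 != 0) stop("tile - crop must be even")
  m <- (tile - crop) / 2
  out <- list()
  for (r in seq(1, H - tile + 1, by = tile))
    for (cl in seq(1, W - tile + 1, by = tile)) {
      afT <- af[r:(r + tile - 1), cl:(cl + tile - 1), , drop = FALSE]
      heT <- he[r:(r + tile - 1), cl:(cl + tile - 1), , drop = FALSE]
      aff <- NULL
      if (registerTiles) {
        aff <- tryCatch(affineRegisterPatch(heT, afT),
                        error = function(e) NULL)
        if (!is.null(aff)) heT <- applyAffine(heT, aff$matrix)
      }
      ri <- (m + 1):(m + crop)
      afC <- afT[ri, ri, , drop = FALSE]
      heC <- heT[ri, ri, , drop = FALSE]
      tf <- mean(.lum(heC) < backgroundThreshold)
      if (tf < minTissue) next
      out[[length(out) + 1]] <- list(af = afC, he = heC, row = r + m,
                                     col = cl + m,
                                     affine = if (is.null(aff)) NULL
                                              else aff$matrix,
                                     tissueFraction = tf)
    }
  out
}

#' Screen a candidate training pair
#'
#' Keeps the pair iff PSNR >= `psnrMin` and SSIM >= `ssimMin` (boundary
#' values kept); both metrics are returned.
#'
#' @param preVS pre-screening virtual staining of the pair's input
#' @param he the histology target, same shape
#' @param cfg a [screenConfig()]
#' @return list with `keep`, `psnr`, `ssim`
#' @export
screenTrainingPair <- function(preVS, he, cfg = screenConfig()) {
  .assertSameShape(preVS, he)
  p <- psnrPeak(preVS, he)
  s <- ssimGlobal(preVS, he)
  list(keep = (p >= cfg$psnrMin) && (s >= cfg$ssimMin), psnr = p, ssim = s)
}
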