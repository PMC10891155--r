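# Quantitative staining evaluation: whole-image SSIM/PSNR, stain unmixing
# by color deconvolution, nuclei segmentation and quantification, paired
# t-tests, and the FOV-level staining-artifact screening workflow.

#' SSIM metric configuration
#'
#' @param c1,c2 stabilizers of the SSIM ratio (defaults 1e-4 and 9e-4)
#' @export
metricConfig <- function(c1 = 1e-4, c2 = 9e-4) {
  stopifnot(c1 > 0, c2 > 0)
  structure(list(c1 = c1, c2 = c2), class = "metricConfig")
}

#' Slide-QC configuration
#'
#' @param fov screening field-of-view size in pixels (default 8000)
#' @param nucleiAreaThreshold minimum nuclei area fraction for a
#'   well-stained FOV (default 0.01)
#' @param eosinIntensityThreshold minimum mean eosin intensity (default 0.07)
#' @param backgroundThreshold tissue = pixels with mean RGB strictly below
#'   this 8-bit value (default 235)
#' @param odNorm optical-density scale used to map eosin concentration to
#'   `[0, 1]`: intensities are divided by `max(slide max OD, odNorm)` so a
#'   uniformly faded slide scores near zero rather than being stretched
#' @param stainVectors 2 x 3 unit-norm stain OD vectors
#' @export
qcConfig <- function(fov = 8000, nucleiAreaThreshold = 0.01,
                     eosinIntensityThreshold = 0.07,
                     backgroundThreshold = 235, odNorm = 1,
                     stainVectors = heStainVectors()) {
  stopifnot(fov > 0, nucleiAreaThreshold > 0, eosinIntensityThreshold > 0)
  structure(list(fov = as.integer(fov),
                 nucleiAreaThreshold = nucleiAreaThreshold,
                 eosinIntensityThreshold = eosinIntensityThreshold,
                 backgroundThreshold = backgroundThreshold, odNorm = odNorm,
                 stainVectors = stainVectors), class = "qcConfig")
}

.to01 <- function(img) {
  img <- .asChannels(img)
  if (max(img) > 1.5) img / 255 else img
}

#' Whole-image structural similarity (SSIM)
#'
#' Global single-window statistic
#' `(2 mu_A mu_B + c1)(2 cov_AB + c2) / ((mu_A^2 + mu_B^2 + c1)(var_A + var_B + c2))`
#' computed per channel on `[0, 1]` intensities and averaged over channels.
#' A conventional sliding-window variant is available via `windowed`.
#'
#' @param a,b images of identical shape (`0..255` inputs are rescaled)
#' @param cfg a [metricConfig()]
#' @param windowed optional window size for a local-window average (unused
#'   by the standard evaluation)
#' @return scalar similarity; 1 for identical images
#' @export
ssimGlobal <- function(a, b, cfg = metricConfig(), windowed = NULL) {
  .assertSameShape(a, b)
  xa <- .to01(a); xb <- .to01(b)
  one <- function(pa, pb) {
    muA <- mean(pa); muB <- mean(pb)
    vA <- mean((pa - muA)^2); vB <- mean((pb - muB)^2)
    cAB <- mean((pa - muA) * (pb - muB))
    (2 * muA * muB + cfg$c1) * (2 * cAB + cfg$c2) /
      ((muA^2 + muB^2 + cfg$c1) * (vA + vB + cfg$c2))
  }
  vals <- vapply(seq_len(dim(xa)[3]), function(c) {
    if (is.null(windowed)) return(one(xa[, , c], xb[, , c]))
    k <- windowed
    H <- dim(xa)[1]; W <- dim(xa)[2]
    is <- seq(1, H - k + 1, by = k); js <- seq(1, W - k + 1, by = k)
    mean(vapply(is, function(i) mean(vapply(js, function(j)
      one(xa[i:(i + k - 1), j:(j + k - 1), c],
          xb[i:(i + k - 1), j:(j + k - 1), c]), 0)), 0))
  }, 0)
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(max(reference)^2 / MSE)` where the peak is the maximum
#' intensity of the reference image (not a fixed dynamic range) and the MSE
#' is averaged over pixels and channels. Identical images yield `Inf`.
#'
#' @param iVS test image
#' @param iHS reference image, same shape
#' @return PSNR in dB (`Inf` for identical images)
#' @export
psnrPeak <- function(iVS, iHS) {
  .assertSameShape(iVS, iHS)
  a <- .to01(iVS); b <- .to01(iHS)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(b)^2 / mse)
}

#' Stain unmixing by color deconvolution
#'
#' Per pixel, optical density `-log((rgb + 1) / 256)` is projected onto the
#' two stain vectors by least squares (Beer-Lambert inversion); negative
#' concentrations are clipped to zero.
#'
#' @param rgb RGB image (H, W, 3), 8-bit scale `0..255`
#' @param stainVectors 2 x 3 matrix of unit-norm, linearly independent
#'   OD vectors (rows: hematoxylin, eosin)
#' @return list with matrices `hema` and `eosin` (OD concentrations)
#' @export
stainUnmix <- function(rgb, stainVectors = heStainVectors()) {
  V <- stainVectors
  if (abs(det(V %*% t(V))) < 1e-8)
    stop("stain vectors are degenerate (not linearly independent)")
  rgb <- .asChannels(rgb)
  if (max(rgb) <= 1.5) rgb <- rgb * 255
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  od <- matrix(0, H * W, 3)
  for (ch in 1:3) od[, ch] <- -log((as.vector(rgb[, , ch]) + 1) / 256)
  conc <- od %*% t(V) %*% solve(V %*% t(V))
  conc[conc < 0] <- 0
  list(hema = matrix(conc[, 1], H, W), eosin = matrix(conc[, 2], H, W))
}

#' Segment nuclei from a hematoxylin optical-density map
#'
#' Otsu threshold on the hematoxylin channel followed by a binary opening
#' (erosion then dilation) with a radius-1 disc. The threshold is floored
#' at `minOD` (absolute optical density) so that channels carrying only
#' unmixing cross-talk -- e.g. a slide with fully faded hematoxylin -- do
#' not segment noise; an all-zero channel yields an empty mask.
#'
#' @param hemaOD non-negative matrix of hematoxylin OD
#' @param minOD minimum OD a stained nucleus must reach (default 0.1)
#' @return binary matrix
#' @export
segmentNuclei <- function(hemaOD, minOD = 0.1) {
  if (any(hemaOD < 0)) stop("optical density must be non-negative")
  mx <- max(hemaOD)
  if (mx == 0) return(matrix(0, nrow(hemaOD), ncol(hemaOD)))
  th <- max(EBImage::otsu(hemaOD / mx, range = c(0, 1)), minOD / mx)
  mask <- (hemaOD / mx) > th
  br <- EBImage::makeBrush(3, shape = "diamond")
  opened <- EBImage::dilate(EBImage::erode(EBImage::Image(mask * 1), br), br)
  matrix(as.numeric(EBImage::imageData(opened) > 0.5),
         nrow(hemaOD), ncol(hemaOD))
}

#' Nuclei count and mean size from a binary mask
#'
#' 8-connected component count and mean component area; an empty mask
#' yields count 0 and `NA` mean area.
#'
#' @param mask binary matrix (values 0/1)
#' @return list with `count` and `meanArea` (pixels)
#' @export
nucleiStats <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  lab <- label_components8(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0) return(list(count = 0L, meanArea = NA_real_))
  areas <- tabulate(lab[lab > 0], nbins = n)
  list(count = as.integer(n), meanArea = mean(areas))
}

#' Two-tailed paired t-test
#'
#' Classical paired t statistic on the differences with `n - 1` degrees of
#' freedom (wraps [stats::t.test()]).
#'
#' @param x,y paired numeric vectors of equal length (>= 2)
#' @return list with `t`, `p`, `df`
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (all(x == y)) return(list(t = 0, p = 1, df = length(x) - 1))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Staining-quality metrics of one field of view
#'
#' Metric 1: area fraction of segmented nuclei within the tissue region
#' (tissue = mean RGB strictly below the background threshold). Metric 2:
#' mean eosin concentration over the tissue region after mapping to `[0, 1]`
#' by the slide's OD scale (see [qcConfig()]).
#'
#' @param heFOV RGB image (H, W, 3), `0..255`
#' @param cfg a [qcConfig()]
#' @param odScale optional precomputed slide-level eosin OD scale
#' @return list with `nucleiAreaFraction`, `eosinMeanIntensity`,
#'   `tissueFraction`; or `NULL` with a warning when the FOV has no tissue
#' @export
fovQualityMetrics <- function(heFOV, cfg = qcConfig(), odScale = NULL) {
  rgb <- .asChannels(heFOV)
  if (max(rgb) <= 1.5) rgb <- rgb * 255
  tissue <- .lum(rgb) < cfg$backgroundThreshold
  if (!any(tissue)) return(NULL)
  un <- stainUnmix(rgb, cfg$stainVectors)
  nmask <- segmentNuclei(un$hema)
  m1 <- sum(nmask * tissue) / sum(tissue)
  sc <- odScale %||% max(max(un$eosin), cfg$odNorm)
  m2 <- mean(pmin(un$eosin[tissue] / sc, 1))
  list(nucleiAreaFraction = m1, eosinMeanIntensity = m2,
       tissueFraction = mean(tissue))
}

#' Screen a slide for staining artifacts, FOV by FOV
#'
#' Divides the slide into square FOVs, computes the two staining-quality
#' metrics for each, and classifies a FOV as well-stained iff both metrics
#' strictly exceed their thresholds (ties and single failures are "poor").
#' FOVs without tissue are marked skipped.
#'
#' @param wsi RGB image (H, W, 3), `0..255`
#' @param cfg a [qcConfig()]; set `fov` smaller than the slide for a grid
#' @return a [QualityReport-class]
#' @export
classifyFOVs <- function(wsi, cfg = qcConfig()) {
  rgb <- .asChannels(wsi)
  if (max(rgb) <= 1.5) rgb <- rgb * 255
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  f <- min(cfg$fov, H, W)
  # slide-level eosin OD scale shared by all FOVs
  un <- stainUnmix(rgb, cfg$stainVectors)
  odScale <- max(max(un$eosin), cfg$odNorm)
  rows <- seq(1, H - f + 1, by = f)
  cols <- seq(1, W - f + 1, by = f)
  out <- list()
  for (r in rows) for (cl in cols) {
    fovImg <- rgb[r:(r + f - 1), cl:(cl + f - 1), , drop = FALSE]
    m <- fovQualityMetrics(fovImg, cfg, odScale = odScale)
    if (is.null(m)) {
      out[[length(out) + 1]] <- data.frame(
        row = r, col = cl, nucleiAreaFraction = NA_real_,
        eosinMeanIntensity = NA_real_, classification = NA_character_,
        skipped = TRUE, reason = "no tissue")
      next
    }
    well <- (m$nucleiAreaFraction > cfg$nucleiAreaThreshold) &&
            (m$eosinMeanIntensity > cfg$eosinIntensityThreshold)
    out[[length(out) + 1]] <- data.frame(
      row = r, col = cl, nucleiAreaFraction = m$nucleiAreaFraction,
      eosinMeanIntensity = m$eosinMeanIntensity,
      classification = if (well) "well" else "poor",
      skipped = FALSE, reason = "")
  }
  new("QualityReport", fovTable = do.call(rbind, out), imageMetrics = list(),
      config = unclass(cfg))
}

#' Full quantitative comparison of a stained pair
#'
#' SSIM, PSNR, and nuclei count/size statistics for a virtually stained
#' image against its histochemical reference; when lists of images are
#' supplied, per-FOV metrics plus paired t-tests on the nuclei statistics
#' are returned.
#'
#' @param vs RGB image or list of images (virtual staining)
#' @param hs matching reference image(s)
#' @param cfg a [metricConfig()]
#' @param stainVectors stain OD vectors for the nuclei channel
#' @return a list of metrics (per-image vectors plus t-test results for
#'   list input)
#' @export
evaluateStaining <- function(vs, hs, cfg = metricConfig(),
                             stainVectors = heStainVectors()) {
  if (!is.list(vs)) { vs <- list(vs); hs <- list(hs) }
  n <- length(vs)
  ss <- pp <- cntV <- cntH <- szV <- szH <- numeric(n)
  for (i in seq_len(n)) {
    ss[i] <- ssimGlobal(vs[[i]], hs[[i]], cfg)
    pp[i] <- psnrPeak(vs[[i]], hs[[i]])
    nv <- nucleiStats(segmentNuclei(stainUnmix(vs[[i]], stainVectors)$hema))
    nh <- nucleiStats(segmentNuclei(stainUnmix(hs[[i]], stainVectors)$hema))
    cntV[i] <- nv$count; cntH[i] <- nh$count
    szV[i] <- nv$meanArea %||% NA_real_; szH[i] <- nh$meanArea %||% NA_real_
  }
  res <- list(ssim = ss, psnr = pp, nucleiCountVS = cntV, nucleiCountHS = cntH,
              nucleiSizeVS = szV, nucleiSizeHS = szH)
  if (n >= 2) {
    res$countTest <- pairedTTest(cntV, cntH)
    ok <- is.finite(szV) & is.finite(szH)
    if (sum(ok) >= 2) res$sizeTest <- pairedTTest(szV[ok], szH[ok])
  }
  res
}
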