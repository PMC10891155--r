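# Synthetic paired autofluorescence / H&E phantom tissue with known ground
# truth (nuclei, stain concentrations, misalignment, under-staining
# artifacts). Every downstream stage is testable against these phantoms
# without any external data.

#' Default hematoxylin / eosin stain color vectors
#'
#' The classical optical-density RGB vectors for hematoxylin
#' `(0.650, 0.704, 0.286)` and eosin `(0.072, 0.990, 0.105)`, normalized to
#' unit length; rows are stains, columns R, G, B.
#'
#' @return a 2 x 3 matrix with unit-norm rows
#' @export
heStainVectors <- function() {
  v <- rbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  v / sqrt(rowSums(v^2))
}

#' Phantom specification
#'
#' @param height,width canvas size in pixels
#' @param nNuclei number of nuclei to place
#' @param nucleusRadiusRange ellipse semi-axis range in pixels
#' @param nucleusOverlapAllowed allow overlapping nuclei
#' @param cytoplasmTextureScale correlation length of the eosin texture (px)
#' @param backgroundFraction fraction of the canvas that is background void
#' @param hematoxylinODNucleus nuclear hematoxylin optical density
#' @param eosinODCytoplasm mean cytoplasmic eosin optical density
#' @param noiseSD additive Gaussian noise SD on the autofluorescence channels
#' @param seed integer; all phantom randomness flows from it
#' @return classed list of settings
#' @export
phantomSpec <- function(height = 256, width = 256, nNuclei = 80,
                        nucleusRadiusRange = c(3, 6),
                        nucleusOverlapAllowed = FALSE,
                        cytoplasmTextureScale = 8,
                        backgroundFraction = 0.15,
                        hematoxylinODNucleus = 0.85,
                        eosinODCytoplasm = 0.35,
                        noiseSD = 0.01, seed = 1) {
  if (height <= 0 || width <= 0) stop("height and width must be positive")
  if (nNuclei < 0) stop("nNuclei must be >= 0")
  if (any(nucleusRadiusRange <= 0)) stop("nucleus radii must be > 0")
  if (backgroundFraction < 0 || backgroundFraction > 1)
    stop("backgroundFraction must lie in [0, 1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nNuclei = as.integer(nNuclei),
                 nucleusRadiusRange = nucleusRadiusRange,
                 nucleusOverlapAllowed = nucleusOverlapAllowed,
                 cytoplasmTextureScale = cytoplasmTextureScale,
                 backgroundFraction = backgroundFraction,
                 hematoxylinODNucleus = hematoxylinODNucleus,
                 eosinODCytoplasm = eosinODCytoplasm,
                 noiseSD = noiseSD, seed = as.integer(seed)),
            class = "phantomSpec")
}

#' Under-staining artifact specification
#'
#' Emulates faded hematoxylin (pale nuclei) and faded eosin (washed-out
#' cytoplasmic/extracellular color) by scaling the respective optical
#' density before re-rendering.
#'
#' @param hemaFade,eosinFade fade factors in `[0, 1]`; 1 removes the stain
#' @param regionMask binary matrix restricting the artifact, or `"whole"`
#' @return classed list
#' @export
artifactSpec <- function(hemaFade = 0, eosinFade = 0, regionMask = "whole") {
  if (hemaFade < 0 || hemaFade > 1 || eosinFade < 0 || eosinFade > 1)
    stop("fade factors must lie in [0, 1]")
  structure(list(hemaFade = hemaFade, eosinFade = eosinFade,
                 regionMask = regionMask), class = "artifactSpec")
}

#' Misalignment specification
#'
#' @param mode `"translation"` or `"smooth_random"`
#' @param amplitude pixels; for `"translation"` a length-2 `(dx, dy)` vector
#'   (a scalar is taken as a pure horizontal shift); for `"smooth_random"`
#'   the maximum per-pixel displacement norm
#' @param smoothnessScale Gaussian correlation length of the random field (px)
#' @param seed integer
#' @return classed list
#' @export
misalignmentSpec <- function(mode = c("smooth_random", "translation"),
                             amplitude = 4, smoothnessScale = 8, seed = 1) {
  mode <- match.arg(mode)
  if (any(amplitude < 0) && mode == "smooth_random")
    stop("amplitude must be >= 0")
  structure(list(mode = mode, amplitude = amplitude,
                 smoothnessScale = smoothnessScale, seed = as.integer(seed)),
            class = "misalignmentSpec")
}

#' Generate a displacement field emulating cross-modality misalignment
#'
#' `"translation"` yields a constant field; `"smooth_random"` draws white
#' noise per plane, filters it with a Gaussian of width `smoothnessScale`,
#' and rescales so the maximum per-pixel displacement norm equals
#' `amplitude`. Deterministic given the seed.
#'
#' @param mis a [misalignmentSpec()]
#' @param height,width field size
#' @return a [DisplacementField-class]
#' @export
generateMisalignment <- function(mis, height, width) {
  if (!inherits(mis, "misalignmentSpec")) stop("mis must be a misalignmentSpec")
  if (mis$mode == "translation") {
    amp <- mis$amplitude
    if (length(amp) == 1L) amp <- c(amp, 0)
    return(DisplacementField(amp[1], amp[2], height, width))
  }
  if (mis$amplitude == 0)
    return(DisplacementField(0, 0, height, width))
  .withSeed(mis$seed, function() {
    dx <- .gaussBlur(matrix(rnorm(height * width), height, width),
                     mis$smoothnessScale)
    dy <- .gaussBlur(matrix(rnorm(height * width), height, width),
                     mis$smoothnessScale)
    nrm <- sqrt(dx^2 + dy^2)
    sc <- mis$amplitude / max(nrm)
    DisplacementField(dx * sc, dy * sc)
  })
}

#' Render an H&E brightfield image from optical-density maps
#'
#' Beer-Lambert composition with unit-norm stain vectors: per pixel and
#' color component the transmitted intensity is `exp(-(c_h v_h + c_e v_e))`
#' of the white level. The 8-bit mapping `rgb = round(256 * T - 1)` is the
#' exact inverse of the [stainUnmix()] optical-density convention
#' `OD = -log((rgb + 1) / 256)`, so unmixing a rendered image recovers the
#' concentrations without bias (up to quantization); zero absorbance maps
#' to pure white (255).
#'
#' @param od array (H, W, 2): hematoxylin and eosin optical density, `>= 0`
#' @param stainVectors 2 x 3 matrix of unit-norm RGB-OD vectors
#' @return array (H, W, 3) with values in `0..255`
#' @examples
#' od <- array(0, c(2, 2, 2))
#' range(renderHE(od))  # zero absorbance -> pure white
#' @export
renderHE <- function(od, stainVectors = heStainVectors()) {
  if (any(od < 0)) stop("optical density must be non-negative")
  nv <- sqrt(rowSums(stainVectors^2))
  if (any(abs(nv - 1) > 1e-6)) stop("stain vectors must be unit-norm")
  if (abs(det(stainVectors %*% t(stainVectors))) < 1e-8)
    stop("stain vectors must be linearly independent")
  H <- dim(od)[1]; W <- dim(od)[2]
  out <- array(0, c(H, W, 3))
  for (ch in 1:3)
    out[, , ch] <- pmax(round(256 * exp(-(od[, , 1] * stainVectors[1, ch] +
                                          od[, , 2] * stainVectors[2, ch])) - 1),
                        0)
  out
}

# rasterize an ellipse; returns a logical (H, W) matrix
.ellipseMask <- function(H, W, cy, cx, ra, rb, theta) {
  r <- ceiling(max(ra, rb)) + 1
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  yy <- outer(ys - cy, rep(1, length(xs)))
  xx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  hit <- (u / ra)^2 + (v / rb)^2 <= 1
  list(ys = ys, xs = xs, hit = hit)
}

#' Generate a synthetic paired phantom sample
#'
#' Draws elliptical nuclei carrying hematoxylin optical density on a
#' textured eosin cytoplasm over a background void region, renders the ideal
#' H&E image, derives the two autofluorescence channels from the OD maps by
#' fixed monotone saturation curves (`od / (od + 0.5)`) plus Gaussian noise,
#' and optionally applies under-staining artifacts and misalignment to form
#' the raw histology target. Deterministic given `spec$seed`.
#'
#' @param spec a [phantomSpec()]
#' @param misalignment optional [misalignmentSpec()], or a precomposed
#'   [DisplacementField-class] (e.g. a systematic slide-level field plus
#'   per-sample jitter); the raw target is the ideal image displaced such
#'   that warping it by the stored `trueDVF` recovers the aligned image
#' @param artifact optional [artifactSpec()] applied to the raw target
#' @return a [PhantomSample-class]
#' @export
generatePhantom <- function(spec, misalignment = NULL, artifact = NULL) {
  if (!inherits(spec, "phantomSpec")) stop("spec must be a phantomSpec")
  H <- spec$height; W <- spec$width
  .withSeed(spec$seed, function() {
    # tissue region: smooth field thresholded at the background quantile
    field <- .gaussBlur(matrix(rnorm(H * W), H, W),
                        max(spec$cytoplasmTextureScale * 2, 4))
    tissue <- field >= quantile(field, spec$backgroundFraction)

    # nuclei placement (rejection sampling when overlap disallowed)
    mask <- matrix(0, H, W)
    occupied <- matrix(FALSE, H, W)  # nuclei grown by 1 px margin
    placed <- 0L
    tissueIdx <- which(tissue)
    if (spec$nNuclei > 0 && length(tissueIdx) == 0)
      stop("no tissue area available for nucleus placement")
    for (i in seq_len(spec$nNuclei)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        p <- tissueIdx[sample.int(length(tissueIdx), 1L)]
        cy <- ((p - 1L) %% H) + 1L
        cx <- ((p - 1L) %/% H) + 1L
        ra <- runif(1, spec$nucleusRadiusRange[1], spec$nucleusRadiusRange[2])
        rb <- runif(1, spec$nucleusRadiusRange[1], spec$nucleusRadiusRange[2])
        th <- runif(1, 0, pi)
        em <- .ellipseMask(H, W, cy, cx, ra, rb, th)
        eg <- .ellipseMask(H, W, cy, cx, ra + 1.5, rb + 1.5, th)
        if (!spec$nucleusOverlapAllowed &&
            any(occupied[eg$ys, eg$xs][eg$hit])) next
        mask[em$ys, em$xs][em$hit] <- 1
        occupied[eg$ys, eg$xs][eg$hit] <- TRUE
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(paste0("could not place nucleus %d without overlap ",
                            "after 200 retries; reduce nNuclei or allow ",
                            "overlap"), i))
      placed <- placed + 1L
    }

    # optical density maps
    odH <- spec$hematoxylinODNucleus * mask *
      (1 + 0.1 * .gaussBlur(matrix(rnorm(H * W), H, W), 2))
    odH <- pmax(odH, 0)
    tex <- .gaussBlur(matrix(rnorm(H * W), H, W), spec$cytoplasmTextureScale)
    tex <- 1 + 0.5 * tex / max(abs(tex), 1e-12)
    odE <- spec$eosinODCytoplasm * tex * tissue * (1 - 0.5 * mask)
    odE <- pmax(odE, 0)
    od <- array(c(odH, odE), c(H, W, 2))

    heIdeal <- renderHE(od)

    # autofluorescence: fixed monotone saturation of the OD maps plus noise
    af <- array(0, c(H, W, 2))
    af[, , 1] <- .clamp(odH / (odH + 0.5) + rnorm(H * W, 0, spec$noiseSD), 0, 1)
    af[, , 2] <- .clamp(odE / (odE + 0.5) + rnorm(H * W, 0, spec$noiseSD), 0, 1)

    sample <- new("PhantomSample", af = af, heIdeal = heIdeal, heRaw = heIdeal,
                  nucleiMask = mask, nucleiCount = placed, odMaps = od,
                  trueDVF = NULL, spec = unclass(spec))
    if (!is.null(artifact))
      sample@heRaw <- degradeStaining(sample, artifact)
    if (!is.null(misalignment)) {
      d <- if (is(misalignment, "DisplacementField")) misalignment
           else generateMisalignment(misalignment, H, W)
      sample@trueDVF <- d
      sample@heRaw <- warpImage(sample@heRaw,
                                DisplacementField(-dvfX(d), -dvfY(d)))
    }
    sample
  })
}

#' Apply an under-staining artifact and re-render
#'
#' Scales the hematoxylin OD by `(1 - hemaFade)` and the eosin OD by
#' `(1 - eosinFade)` inside the region mask, then re-renders the H&E image.
#'
#' @param sample a [PhantomSample-class]
#' @param art an [artifactSpec()]
#' @return degraded RGB image (H, W, 3), `0..255`
#' @export
degradeStaining <- function(sample, art) {
  stopifnot(is(sample, "PhantomSample"), inherits(art, "artifactSpec"))
  od <- odMaps(sample)
  H <- dim(od)[1]; W <- dim(od)[2]
  region <- if (identical(art$regionMask, "whole")) matrix(1, H, W)
            else art$regionMask
  if (!identical(dim(region), c(H, W)))
    stop("artifact region mask dimensions differ from the sample")
  od[, , 1] <- od[, , 1] * (1 - art$hemaFade * region)
  od[, , 2] <- od[, , 2] * (1 - art$eosinFade * region)
  renderHE(od)
}
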