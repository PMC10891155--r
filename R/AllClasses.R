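#' Per-pixel displacement vector field
#'
#' Two planes of per-pixel displacements in units of pixels: `dx` shifts along
#' the horizontal (column) direction, `dy` along the vertical (row) direction.
#' Sampling convention: an image warped by a field `d` takes its output value
#' at pixel `p` from location `p + d(p)` in the source (see [warpImage()]).
#'
#' @slot dx numeric matrix of horizontal displacements (pixels)
#' @slot dy numeric matrix of vertical displacements (pixels)
#' @export
setClass("DisplacementField", representation(dx = "matrix", dy = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@dx), dim(object@dy)))
      return("dx and dy planes must have identical dimensions")
    if (!all(is.finite(object@dx)) || !all(is.finite(object@dy)))
      return("displacement values must be finite")
    TRUE
  })

#' Construct a displacement field
#'
#' @param dx,dy numeric matrices of horizontal (column) and vertical (row)
#'   per-pixel displacements in pixels. Scalars are recycled to `height` x
#'   `width`.
#' @param height,width required when `dx`/`dy` are scalars.
#' @return a [DisplacementField-class] object
#' @examples
#' d <- DisplacementField(4, 0, height = 8, width = 8)
#' range(dvfX(d))
#' @export
DisplacementField <- function(dx, dy, height = NULL, width = NULL) {
  if (length(dx) == 1L && !is.matrix(dx)) {
    stopifnot(!is.null(height), !is.null(width))
    dx <- matrix(dx, height, width)
    dy <- matrix(dy, height, width)
  }
  new("DisplacementField", dx = dx, dy = dy)
}

#' @describeIn DisplacementField horizontal (column) displacement plane
#' @param d a `DisplacementField`
#' @export
dvfX <- function(d) d@dx

#' @describeIn DisplacementField vertical (row) displacement plane
#' @export
dvfY <- function(d) d@dy

#' @export
setMethod("dim", "DisplacementField", function(x) dim(x@dx))

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField %d x %d px; |d| in [%.3f, %.3f]\n",
              nrow(object@dx), ncol(object@dx),
              min(sqrt(object@dx^2 + object@dy^2)),
              max(sqrt(object@dx^2 + object@dy^2))))
})

#' Synthetic paired phantom sample
#'
#' Holds one synthetic autofluorescence / H&E pair with full ground truth:
#' the two-channel autofluorescence input (DAPI-role, TxRed-role), the ideal
#' (pixel-aligned) rendered H&E image, the possibly misaligned raw histology
#' target, the binary nuclei mask with its count, the underlying
#' hematoxylin/eosin optical-density maps, and the true displacement field
#' when misalignment was simulated.
#'
#' @slot af array (H, W, 2) autofluorescence channels in `[0, 1]`
#' @slot heIdeal array (H, W, 3) rendered H&E, 8-bit scale `0..255`
#' @slot heRaw array (H, W, 3) misaligned/degraded histology target, `0..255`
#' @slot nucleiMask binary matrix (H, W)
#' @slot nucleiCount integer
#' @slot odMaps array (H, W, 2): hematoxylin and eosin optical density
#' @slot trueDVF `DisplacementField` or `NULL`
#' @slot spec the generating specification (list)
#' @export
setClass("PhantomSample", representation(
  af = "array", heIdeal = "array", heRaw = "array",
  nucleiMask = "matrix", nucleiCount = "integer",
  odMaps = "array", trueDVF = "ANY", spec = "list"),
  validity = function(object) {
    hw <- dim(object@af)[1:2]
    for (s in list(dim(object@heIdeal)[1:2], dim(object@nucleiMask),
                   dim(object@odMaps)[1:2]))
      if (!identical(s, hw)) return("all phantom images must share height/width")
    if (!all(object@nucleiMask %in% c(0, 1)))
      return("nucleiMask must be binary")
    TRUE
  })

#' @describeIn PhantomSample autofluorescence channels (H, W, 2)
#' @param x a `PhantomSample`
#' @export
afImage <- function(x) x@af

#' @describeIn PhantomSample pixel-aligned rendered H&E image (0..255)
#' @export
heIdeal <- function(x) x@heIdeal

#' @describeIn PhantomSample raw (misaligned/degraded) histology target
#' @export
heRaw <- function(x) x@heRaw

#' @describeIn PhantomSample binary nuclei ground-truth mask
#' @export
nucleiMask <- function(x) x@nucleiMask

#' @describeIn PhantomSample number of simulated nuclei
#' @export
nucleiCount <- function(x) x@nucleiCount

#' @describeIn PhantomSample hematoxylin/eosin optical density maps (H, W, 2)
#' @export
odMaps <- function(x) x@odMaps

#' @describeIn PhantomSample ground-truth displacement field (or NULL)
#' @export
trueDVF <- function(x) x@trueDVF

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample %d x %d px, %d nuclei%s\n",
              dim(object@af)[1], dim(object@af)[2], object@nucleiCount,
              if (is.null(object@trueDVF)) "" else ", with misalignment"))
})

#' Convolutional network handle
#'
#' Thin S4 wrapper around the compiled single-precision network engine. The
#' `ptr` slot is an external pointer valid for the current session; networks
#' are persisted via their parameter list ([netParameters()]) together with
#' the build configuration, and can be reconstructed with [rebuildNet()].
#'
#' @slot ptr external pointer to the engine object
#' @slot type `"unet"` or `"cnn"`
#' @slot depth,baseFilters,inChannels,outChannels integers
#' @slot attention logical, attention-gated skip connections (generator)
#' @slot final `"sigmoid"` or `"linear"` output activation
#' @slot seed integer initialization seed
#' @export
setClass("ConvNet", representation(
  ptr = "externalptr", type = "character", depth = "integer",
  baseFilters = "integer", inChannels = "integer", outChannels = "integer",
  attention = "logical", final = "character", seed = "integer"))

setMethod("show", "ConvNet", function(object) {
  cat(sprintf("ConvNet <%s> depth %d, base %d, %d -> %d channels, %s params\n",
              object@type, object@depth, object@baseFilters,
              object@inChannels, object@outChannels,
              format(parameterCount(object), big.mark = ",")))
})

#' Jointly trained staining model
#'
#' Result of [trainRegiStain()]: the virtual-staining generator (restored to
#' the checkpoint with the lowest validation generator loss), the
#' discriminator, the registration network (or `NULL` for the ablation
#' without it), and the training state (iteration counters, loss history,
#' best checkpoint bookkeeping).
#'
#' @slot generator,discriminator `ConvNet`
#' @slot regnet `ConvNet` or `NULL`
#' @slot state list: `tD`, `itersG`, `itersR`, `lossHistory` (data.frame),
#'   `bestLG`, `bestCycle`
#' @slot config the training configuration used
#' @export
setClass("RegiStainModel", representation(
  generator = "ConvNet", discriminator = "ConvNet", regnet = "ANY",
  state = "list", config = "list"))

#' @describeIn RegiStainModel the trained generator network
#' @param m a `RegiStainModel`
#' @export
generatorNet <- function(m) m@generator

#' @describeIn RegiStainModel the registration network (NULL when ablated)
#' @export
registrationNet <- function(m) m@regnet

#' @describeIn RegiStainModel training state list
#' @export
trainState <- function(m) m@state

setMethod("show", "RegiStainModel", function(object) {
  st <- object@state
  cat(sprintf(paste0("RegiStainModel: %d cycles, t_D = %d, G iters = %d, ",
                     "R iters = %d\n  best validation L_G = %.4f (cycle %d)\n"),
              nrow(st$lossHistory), st$tD, st$itersG, st$itersR,
              st$bestLG, st$bestCycle))
})

#' Slide-quality report
#'
#' Per-FOV staining-quality metrics and classification produced by
#' [classifyFOVs()], plus optional whole-image statistics.
#'
#' @slot fovTable data.frame with one row per FOV: `row`, `col` (top-left
#'   1-based offsets), `nucleiAreaFraction`, `eosinMeanIntensity`,
#'   `classification` (`"well"`/`"poor"`), and `skipped`/`reason`
#' @slot imageMetrics list of whole-image statistics (may be empty)
#' @slot config the QC configuration used
#' @export
setClass("QualityReport", representation(
  fovTable = "data.frame", imageMetrics = "list", config = "list"))

#' @describeIn QualityReport per-FOV metric and classification table
#' @param x a `QualityReport`
#' @export
fovTable <- function(x) x@fovTable

setMethod("show", "QualityReport", function(object) {
  tb <- object@fovTable
  cat(sprintf("QualityReport: %d FOVs (%d well, %d poor, %d skipped)\n",
              nrow(tb), sum(tb$classification == "well", na.rm = TRUE),
              sum(tb$classification == "poor", na.rm = TRUE),
              sum(tb$skipped)))
})
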