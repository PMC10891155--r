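# Image and configuration I/O shared by all stages: TIFF/PNG images,
# two-plane 32-bit TIFF displacement fields, YAML run configuration.

#' Read an image file
#'
#' Supports 8/16-bit single- or multi-channel TIFF and PNG. Values are
#' returned on their native integer scale (`0..255` or `0..65535`), with
#' the bit depth recorded in the `bitsPerSample` attribute.
#'
#' @param path file path (.tif/.tiff/.png)
#' @return matrix (H, W) or array (H, W, C) with attribute `bitsPerSample`
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      x <- tiff::readTIFF(path, info = TRUE, all = FALSE)
      bits <- attr(x, "bits.per.sample") %||% 8
      v <- unclass(x) * (2^bits - 1)
      attributes(v) <- list(dim = dim(x))
      attr(v, "bitsPerSample") <- bits
      v
    } else if (ext == "png") {
      x <- png::readPNG(path)
      v <- x * 255
      attributes(v) <- list(dim = dim(x))
      attr(v, "bitsPerSample") <- 8
      v
    } else stop(sprintf("unsupported image format '%s'", ext))
  }, error = function(e) stop(sprintf("cannot read '%s': %s", path,
                                      conditionMessage(e)), call. = FALSE))
  img
}

#' Write an image file
#'
#' @param img matrix or (H, W, C) array on an integer scale
#' @param path output path (.tif/.tiff/.png)
#' @param bits 8 or 16 (TIFF only; PNG is 8-bit)
#' @export
writeImage <- function(img, path, bits = 8) {
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^bits - 1
  x <- .clamp(unclass(img) / maxv, 0, 1)
  attr(x, "bitsPerSample") <- NULL
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  else if (ext == "png") png::writePNG(x, path)
  else stop(sprintf("unsupported image format '%s'", ext))
  invisible(path)
}

#' Read / write a displacement field as a two-plane 32-bit float TIFF
#'
#' Plane 1 holds horizontal (column) displacements, plane 2 vertical (row)
#' displacements, in pixels. TIFF float samples are stored on a `[0, 1]`
#' scale, so displacements are affine-encoded as `(d + 64) / 128`; the
#' fixed +/- 64 px range comfortably covers the post-processing bound of
#' +/- 30 px and round-trips to ~1e-5 px precision.
#'
#' @param d a [DisplacementField-class] with displacements within +/- 64 px
#' @param path file path
#' @return `readDVF` returns a [DisplacementField-class]
#' @export
writeDVF <- function(d, path) {
  if (max(abs(dvfX(d)), abs(dvfY(d))) > 64)
    stop("displacements beyond +/- 64 px cannot be stored")
  tiff::writeTIFF(list((dvfX(d) + 64) / 128, (dvfY(d) + 64) / 128), path,
                  bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname writeDVF
#' @export
readDVF <- function(path) {
  pl <- tiff::readTIFF(path, all = TRUE)
  if (length(pl) != 2) stop("displacement TIFF must contain two planes")
  DisplacementField(unclass(pl[[1]]) * 128 - 64, unclass(pl[[2]]) * 128 - 64)
}

.configDefaults <- function() {
  list(
    seed = 1,
    phantom = list(height = 256, width = 256, nNuclei = 80,
                   backgroundFraction = 0.15, noiseSD = 0.01),
    prep = list(tile = 3248, crop = 2048, psnrMin = 15, ssimMin = 0.6),
    loss = list(alpha = 0.02, beta = 50, deltaFrac = 0.2, nccK = 20),
    train = list(lrG = 1e-4, lrR = 1e-4, lrD = 1e-5, batchSize = 4,
                 patch = 256, maxCycles = 300, depth = 4, baseFilters = 32,
                 useRegistrationNet = TRUE),
    infer = list(tile = 2048, overlap = 32),
    qc = list(fov = 8000, nucleiAreaThreshold = 0.01,
              eosinIntensityThreshold = 0.07)
  )
}

.checkPositive <- list(
  "loss.alpha" = "alpha > 0", "loss.beta" = "beta > 0",
  "loss.deltaFrac" = "deltaFrac > 0", "loss.nccK" = "nccK > 0",
  "train.lrG" = "lrG > 0", "train.lrR" = "lrR > 0", "train.lrD" = "lrD > 0",
  "train.batchSize" = "batchSize >= 1", "prep.psnrMin" = "psnrMin > 0",
  "qc.nucleiAreaThreshold" = "nucleiAreaThreshold > 0",
  "qc.eosinIntensityThreshold" = "eosinIntensityThreshold > 0")

#' Load and validate a run configuration
#'
#' Reads a YAML file, applies defaults for missing keys, rejects unknown
#' keys, and validates constraints; an empty file yields the full default
#' configuration. Re-loading a saved snapshot reproduces the identical
#' resolved configuration.
#'
#' @param path YAML file path (or `NULL` for pure defaults)
#' @return nested configuration list (classed `runConfig`)
#' @export
loadRunConfig <- function(path = NULL) {
  def <- .configDefaults()
  usr <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path))
    usr <- yaml::read_yaml(path) %||% list()
  }
  bad <- setdiff(names(usr), names(def))
  if (length(bad))
    stop(sprintf("unknown configuration key '%s'", bad[1]))
  out <- def
  for (sec in names(usr)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(usr[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop(sprintf("unknown configuration key '%s.%s'", sec, badk[1]))
      out[[sec]][names(usr[[sec]])] <- usr[[sec]]
    } else out[[sec]] <- usr[[sec]]
  }
  for (key in names(.checkPositive)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- out[[parts[1]]][[parts[2]]]
    ok <- if (grepl(">=", .checkPositive[[key]])) v >= 1 else v > 0
    if (!is.numeric(v) || !ok)
      stop(sprintf("configuration constraint violated: %s",
                   .checkPositive[[key]]))
  }
  structure(out, class = "runConfig")
}

#' Save a resolved configuration snapshot
#'
#' @param cfg a configuration list from [loadRunConfig()]
#' @param path output YAML path
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
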