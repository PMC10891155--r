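# Builders for the three networks: generator G (attention U-Net),
# discriminator D (strided CNN classifier) and registration network R
# (plain U-Net emitting a raw two-channel displacement field).

#' Network configuration
#'
#' @param depth number of resolution levels (downsamplings); input spatial
#'   dims must be divisible by `2^depth`
#' @param baseFilters filters at the first level (doubled per level)
#' @param inChannels,outChannels input/output channel counts
#' @param seed integer initialization seed (deterministic weights)
#' @return classed list of settings
#' @export
netConfig <- function(depth = 4, baseFilters = 32, inChannels = 2,
                      outChannels = 3, seed = 1) {
  stopifnot(depth >= 1, baseFilters >= 1, inChannels >= 1, outChannels >= 1)
  structure(list(depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters),
                 inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 seed = as.integer(seed)),
            class = "netConfig")
}

.newConvNet <- function(type, cfg, cin, cout, attention, final) {
  ptr <- net_create(type, cfg$depth, cfg$baseFilters, cin, cout,
                    attention, final, cfg$seed)
  new("ConvNet", ptr = ptr, type = type, depth = cfg$depth,
      baseFilters = cfg$baseFilters, inChannels = as.integer(cin),
      outChannels = as.integer(cout), attention = attention, final = final,
      seed = cfg$seed)
}

#' Build the virtual-staining generator (attention U-Net)
#'
#' Maps a 2-channel autofluorescence input to a 3-channel RGB output of the
#' same spatial size. Encoder-decoder with skip connections gated by
#' attention blocks; sigmoid output keeps intensities in `[0, 1]`.
#'
#' @param cfg a [netConfig()]; `inChannels`/`outChannels` default to 2/3
#' @return a [ConvNet-class]
#' @export
buildGenerator <- function(cfg = netConfig()) {
  .newConvNet("unet", cfg, cfg$inChannels %||% 2L, 3L, TRUE, "sigmoid")
}

#' Build the discriminator (strided CNN classifier)
#'
#' Strided convolutional stack with leaky activations, global average
#' pooling and a sigmoid head emitting one probability per image.
#'
#' @param cfg a [netConfig()]
#' @return a [ConvNet-class]
#' @export
buildDiscriminator <- function(cfg = netConfig(inChannels = 3)) {
  .newConvNet("cnn", cfg, 3L, 1L, FALSE, "sigmoid")
}

#' Build the registration network (plain U-Net)
#'
#' Consumes the channel concatenation of the generator output and the raw
#' histology target (6 channels) and emits a raw 2-channel displacement
#' field of the same spatial size, which is then post-processed by
#' [postprocessDVF()].
#'
#' @param cfg a [netConfig()]
#' @return a [ConvNet-class]
#' @export
buildRegistrationNet <- function(cfg = netConfig(inChannels = 6)) {
  .newConvNet("unet", cfg, 6L, 2L, FALSE, "linear")
}

.as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d, 1L))
  x
}

#' Forward pass through a network
#'
#' @param net a [ConvNet-class]
#' @param x input array `(H, W, C)` or batch `(H, W, C, N)`
#' @param train keep caches for a subsequent backward pass
#' @return for U-Nets an array matching the input batch shape with
#'   `outChannels` channels; for the discriminator a numeric vector of one
#'   probability per image
#' @export
netForward <- function(net, x, train = FALSE) {
  single <- length(dim(x)) == 3L
  y <- net_forward(net@ptr, .as4d(x), train)
  if (net@type == "cnn") return(as.numeric(y))
  if (single) array(y, dim(y)[1:3]) else y
}

#' Number of trainable parameters
#' @param net a [ConvNet-class]
#' @export
parameterCount <- function(net) net_nparams(net@ptr)

#' Extract network parameters (checkpointing)
#'
#' Returns a named list of numeric matrices/vectors; together with the
#' build configuration stored in the object slots this fully determines the
#' network and can be re-imported with [setNetParameters()] or
#' [rebuildNet()].
#'
#' @param net a [ConvNet-class]
#' @export
netParameters <- function(net) net_params(net@ptr)

#' @rdname netParameters
#' @param params a parameter list from [netParameters()]
#' @export
setNetParameters <- function(net, params) {
  net_set_params(net@ptr, params)
  invisible(net)
}

#' Reconstruct a network from its description and parameters
#'
#' @param net a [ConvNet-class] serving as the architecture description
#' @param params optional parameter list (defaults to `net`'s parameters)
#' @return a fresh, independent [ConvNet-class]
#' @export
rebuildNet <- function(net, params = netParameters(net)) {
  ptr <- net_create(net@type, net@depth, net@baseFilters, net@inChannels,
                    net@outChannels, net@attention, net@final, net@seed)
  out <- new("ConvNet", ptr = ptr, type = net@type, depth = net@depth,
             baseFilters = net@baseFilters, inChannels = net@inChannels,
             outChannels = net@outChannels, attention = net@attention,
             final = net@final, seed = net@seed)
  net_set_params(ptr, params)
  out
}
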