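# Alternating training loop: per cycle, updateRatio(t_D) generator steps
# (discriminator and registration frozen), one discriminator step, one
# registration step. The registration network dynamically warps the raw
# histology target into a pixel-accurate training target for the generator.

#' Training configuration
#'
#' Defaults follow the production settings (Adam, learning rates 1e-4 for
#' generator/registration and 1e-5 for the discriminator, batch size 4,
#' 256-px patches); toy configurations pass smaller nets and patches.
#'
#' @param lrG,lrR,lrD Adam learning rates
#' @param batchSize images per step
#' @param patch training patch size in pixels (must be divisible by
#'   `2^net$depth`)
#' @param maxCycles number of alternating cycles
#' @param seed integer; controls splits, batch order and augmentation
#' @param useRegistrationNet `FALSE` ablates the registration network: the
#'   raw target is used directly and no registration steps run
#' @param loss a [lossConfig()]; `nccStrideTrain` subsamples NCC windows
#'   during registration updates
#' @param net a [netConfig()] shared by the three builders (generator seed,
#'   discriminator seed+1, registration seed+2)
#' @param valFraction validation split fraction (default 0.1)
#' @param valEvery validate (and checkpoint) every this many cycles
#' @param augment apply random flips/rotations
#' @param nccStrideTrain NCC window stride used in registration updates
#' @param freezeGenerator hold the generator fixed (inference mode): no
#'   generator updates run; used when fitting the registration network
#'   against an already-trained generator (see the methods vignette)
#' @return classed list of settings
#' @export
trainConfig <- function(lrG = 1e-4, lrR = 1e-4, lrD = 1e-5, batchSize = 4,
                        patch = 256, maxCycles = 300, seed = 1,
                        useRegistrationNet = TRUE, loss = lossConfig(),
                        net = netConfig(), valFraction = 0.1, valEvery = 10,
                        augment = TRUE, nccStrideTrain = 10,
                        freezeGenerator = FALSE) {
  stopifnot(lrG > 0, lrR > 0, lrD > 0, batchSize >= 1, maxCycles >= 1,
            patch %% (2^net$depth) == 0)
  structure(list(lrG = lrG, lrR = lrR, lrD = lrD,
                 batchSize = as.integer(batchSize), patch = as.integer(patch),
                 maxCycles = as.integer(maxCycles), seed = as.integer(seed),
                 useRegistrationNet = useRegistrationNet, loss = loss,
                 net = net, valFraction = valFraction,
                 valEvery = as.integer(valEvery), augment = augment,
                 nccStrideTrain = as.integer(nccStrideTrain),
                 freezeGenerator = freezeGenerator),
            class = "trainConfig")
}

#' Generator-updates-per-cycle schedule
#'
#' `max(3, floor(12 - t_D / 4000))`: the generator receives many more
#' updates than the discriminator early on, decaying to a floor of 3 as the
#' discriminator accumulates iterations. Updates per cycle are ratio:1:1
#' for G:D:R.
#'
#' @param tD total discriminator iteration count (non-negative)
#' @return integer number of generator updates for the coming cycle
#' @examples
#' updateRatio(0)      # 12
#' updateRatio(4000)   # 11
#' updateRatio(48000)  # 3 (floor)
#' @export
updateRatio <- function(tD) {
  if (any(tD < 0)) stop("tD must be non-negative")
  pmax(3, floor(12 - tD / 4000))
}

#' Standardize a patch to zero mean and unit variance
#'
#' Per channel: `(x - mean) / max(SD, eps)` with population SD; constant
#' patches map to zeros.
#'
#' @param patch matrix or (H, W, C) array
#' @param eps variance floor (default 1e-8)
#' @return standardized patch, same shape
#' @export
normalizePatch <- function(patch, eps = 1e-8) {
  x <- .asChannels(patch)
  for (c in seq_len(dim(x)[3])) {
    p <- x[, , c]
    x[, , c] <- (p - mean(p)) / max(.sdPop(p), eps)
  }
  if (is.matrix(patch)) x[, , 1] else x
}

.rot90 <- function(x, k) {
  k <- k %% 4
  if (k == 0) return(x)
  x <- .asChannels(x)
  for (i in seq_len(k))
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
  x
}

#' Randomly flip and rotate a training pair
#'
#' Left-right and up-down flips each with probability 0.5, plus a rotation
#' drawn uniformly from 0, 90, 180, 270 degrees; the identical transform is
#' applied to input and target so the pair stays pixel-aligned. Uses the
#' current RNG state (seed at the call site for reproducibility).
#'
#' @param input,target images with equal spatial dims (square for rotations)
#' @return list with transformed `input` and `target`
#' @export
augmentPair <- function(input, target) {
  fliplr <- runif(1) < 0.5
  flipud <- runif(1) < 0.5
  k <- sample(0:3, 1)
  tf <- function(x) {
    m <- is.matrix(x)
    x <- .asChannels(x)
    if (fliplr) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    if (flipud) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    x <- .rot90(x, k)
    if (m) x[, , 1] else x
  }
  list(input = tf(input), target = tf(target))
}

# coerce a dataset element into list(af [0,1] (H,W,2), he [0,1] (H,W,3))
.asPair <- function(s) {
  if (is(s, "PhantomSample"))
    return(list(af = afImage(s), he = heRaw(s) / 255))
  he <- s$he %||% s$heRaw
  if (max(he) > 1.5) he <- he / 255
  list(af = .asChannels(s$af), he = .asChannels(he))
}

# draw a batch of augmented, normalized patches; returns 4-D arrays
.drawBatch <- function(pairs, cfg) {
  p <- cfg$patch; B <- cfg$batchSize
  xa <- array(0, c(p, p, 2, B)); xh <- array(0, c(p, p, 3, B))
  idx <- sample.int(length(pairs), B, replace = TRUE)
  for (b in seq_len(B)) {
    s <- pairs[[idx[b]]]
    H <- dim(s$af)[1]; W <- dim(s$af)[2]
    r0 <- if (H > p) sample.int(H - p + 1, 1) else 1L
    c0 <- if (W > p) sample.int(W - p + 1, 1) else 1L
    af <- s$af[r0:(r0 + p - 1), c0:(c0 + p - 1), , drop = FALSE]
    he <- s$he[r0:(r0 + p - 1), c0:(c0 + p - 1), , drop = FALSE]
    if (cfg$augment) {
      aug <- augmentPair(af, he)
      af <- aug$input; he <- aug$target
    }
    xa[, , , b] <- normalizePatch(af)
    xh[, , , b] <- he
  }
  list(af = xa, he = xh)
}

# registration forward for a batch: raw DVF -> per-image post-processing and
# warping; returns registered targets plus caches for the backward pass
.registerBatch <- function(regnet, ivs, he, cfg, train = FALSE) {
  B <- dim(ivs)[4]
  rin <- array(0, c(dim(ivs)[1], dim(ivs)[2], 6, B))
  rin[, , 1:3, ] <- ivs; rin[, , 4:6, ] <- he
  raw <- net_forward(regnet@ptr, rin, train)
  pc <- dvfPostConfig()
  ihs <- array(0, dim(he))
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    px <- .postPlane(raw[, , 1, b], pc)
    py <- .postPlane(raw[, , 2, b], pc)
    d <- DisplacementField(px$plane, py$plane)
    ihs[, , , b] <- warpImage(he[, , , b], d)
    cache[[b]] <- list(d = d, mx = px$mask, my = py$mask)
  }
  list(ihs = ihs, cache = cache, raw = raw)
}

# mean validation generator loss over a set of pairs
.validationLG <- function(gen, disc, regnet, pairs, cfg) {
  tot <- 0
  for (s in pairs) {
    p <- cfg$patch
    af <- s$af[seq_len(min(dim(s$af)[1], p)), seq_len(min(dim(s$af)[2], p)), ,
               drop = FALSE]
    he <- s$he[seq_len(min(dim(s$he)[1], p)), seq_len(min(dim(s$he)[2], p)), ,
               drop = FALSE]
    x <- array(normalizePatch(af), c(dim(af), 1))
    hv <- array(he, c(dim(he), 1))
    ivs <- net_forward(gen@ptr, x, FALSE)
    d <- as.numeric(net_forward(disc@ptr, ivs, FALSE))
    if (!is.null(regnet)) {
      reg <- .registerBatch(regnet, ivs, hv, cfg, train = FALSE)
      tgt <- reg$ihs[, , , 1]
    } else tgt <- he
    lg <- generatorLoss(ivs[, , , 1], tgt, d, cfg$loss)
    tot <- tot + lg$total
  }
  tot / length(pairs)
}

#' Train the virtual-staining model
#'
#' Runs the alternating schedule: per cycle, [updateRatio()] generator
#' updates (registration and discriminator frozen; the training target is
#' the raw histology warped by the frozen registration network's
#' post-processed displacement field, recomputed from the original raw
#' target every time), then one discriminator update (real = raw target),
#' then one registration update (generator frozen; gradients flow through
#' the spatial transformer into the registration network). With
#' `useRegistrationNet = FALSE` the raw target is used directly and no
#' registration updates run (ablation). The generator checkpoint with the
#' lowest validation generator loss is restored into the returned model.
#'
#' @param dataset list of [PhantomSample-class] objects or lists with
#'   elements `af` (H, W, 2, in `[0, 1]`) and `he`/`heRaw` (H, W, 3)
#' @param config a [trainConfig()]
#' @param verbose print progress every validation
#' @param init optional [RegiStainModel-class] whose generator/discriminator
#'   (and registration network, when present in both) parameters warm-start
#'   the new networks; architectures must match
#' @return a [RegiStainModel-class]
#' @export
trainRegiStain <- function(dataset, config = trainConfig(), verbose = FALSE,
                           init = NULL) {
  if (length(dataset) == 0) stop("dataset must be non-empty")
  pairs <- lapply(dataset, .asPair)
  for (s in pairs)
    if (any(!is.finite(s$af)) || any(!is.finite(s$he)))
      stop("divergent input: dataset contains non-finite values")
  cfg <- config
  .withSeed(cfg$seed, function() {
    nval <- max(1L, round(cfg$valFraction * length(pairs)))
    if (length(pairs) < 2L) nval <- 0L
    vi <- if (nval > 0) sample.int(length(pairs), nval) else integer(0)
    valPairs <- pairs[vi]
    trPairs <- if (nval > 0) pairs[-vi] else pairs
    if (length(valPairs) == 0) valPairs <- trPairs[1]

    ncfg <- cfg$net
    gen <- buildGenerator(ncfg)
    disc <- buildDiscriminator(netConfig(ncfg$depth, ncfg$baseFilters,
                                         3, 1, ncfg$seed + 1L))
    regnet <- if (cfg$useRegistrationNet)
      buildRegistrationNet(netConfig(ncfg$depth, ncfg$baseFilters,
                                     6, 2, ncfg$seed + 2L)) else NULL
    if (!is.null(init)) {
      net_set_params(gen@ptr, netParameters(init@generator))
      net_set_params(disc@ptr, netParameters(init@discriminator))
      if (!is.null(regnet) && !is.null(init@regnet))
        net_set_params(regnet@ptr, netParameters(init@regnet))
    }
    L <- cfg$loss
    nccStride <- cfg$nccStrideTrain
    tD <- 0L; itersG <- 0L; itersR <- 0L
    bestLG <- Inf; bestCycle <- 0L; bestParams <- NULL
    hist <- vector("list", cfg$maxCycles)

    v0 <- .validationLG(gen, disc, regnet, valPairs, cfg)
    initialValLG <- v0
    bestLG <- v0; bestParams <- net_params(gen@ptr)

    for (cyc in seq_len(cfg$maxCycles)) {
      ratio <- updateRatio(tD)
      gstats <- c(LG = NA_real_, berhu = NA_real_, tv = NA_real_,
                  adv = NA_real_)
      gsteps <- if (isTRUE(cfg$freezeGenerator)) 0L else ratio
      if (gsteps > 0) gstats[] <- 0

      for (gstep in seq_len(gsteps)) {
        bt <- .drawBatch(trPairs, cfg)
        B <- cfg$batchSize
        ivs <- net_forward(gen@ptr, bt$af, TRUE)
        dv <- as.numeric(net_forward(disc@ptr, ivs, TRUE))
        if (!is.null(regnet)) {
          reg <- .registerBatch(regnet, ivs, bt$he, cfg, train = FALSE)
          tgt <- reg$ihs
        } else tgt <- bt$he
        dIVS <- array(0, dim(ivs))
        lgsum <- c(0, 0, 0, 0)
        for (b in seq_len(B)) {
          a <- ivs[, , , b]; t <- tgt[, , , b]
          delta <- max(L$deltaFrac * .sdPop(t), 1e-6)
          bg <- berhu_val_grad(a, t, delta)
          tv <- tvLoss(a)
          lgsum <- lgsum + c(bg$value + L$alpha * tv +
                               L$beta * (1 - dv[b])^2,
                             bg$value, tv, (1 - dv[b])^2)
          dIVS[, , , b] <- (bg$grad + L$alpha * .tvGrad(a)) / B
        }
        # adversarial gradient flows through the (frozen) discriminator
        dAdv <- net_backward(disc@ptr, -2 * L$beta * (1 - dv) / B)
        dIVS <- dIVS + dAdv
        if (any(!is.finite(dIVS)))
          stop(sprintf("divergent generator loss at cycle %d", cyc))
        net_backward(gen@ptr, dIVS)
        net_step(gen@ptr, cfg$lrG)
        itersG <- itersG + 1L
        gstats <- gstats + lgsum / B
      }
      if (gsteps > 0) gstats <- gstats / gsteps

      # discriminator update: generated vs raw-real, one joint batch
      bt <- .drawBatch(trPairs, cfg)
      B <- cfg$batchSize
      ivs <- net_forward(gen@ptr, bt$af, FALSE)
      din <- array(0, c(cfg$patch, cfg$patch, 3, 2 * B))
      din[, , , seq_len(B)] <- ivs
      din[, , , B + seq_len(B)] <- bt$he
      dall <- as.numeric(net_forward(disc@ptr, din, TRUE))
      ld <- discriminatorLoss(dall[seq_len(B)], dall[B + seq_len(B)])
      dyD <- c(2 * dall[seq_len(B)] / B, -2 * (1 - dall[B + seq_len(B)]) / B)
      net_backward(disc@ptr, dyD)
      net_step(disc@ptr, cfg$lrD)
      tD <- tD + 1L

      # registration update (generator frozen; gradient through the warp)
      lr_val <- NA_real_
      if (!is.null(regnet)) {
        bt <- .drawBatch(trPairs, cfg)
        ivs <- net_forward(gen@ptr, bt$af, FALSE)
        reg <- .registerBatch(regnet, ivs, bt$he, cfg, train = TRUE)
        dRaw <- array(0, dim(reg$raw))
        lrsum <- 0
        npx <- cfg$patch^2  # per-pixel DVF regularizer (see registrationLoss)
        for (b in seq_len(B)) {
          a <- ivs[, , , b]
          ihs <- reg$ihs[, , , b]
          cc <- reg$cache[[b]]
          lr_b <- registrationLoss(a, ihs,
                                   cc$d, lossConfig(alpha = L$alpha,
                                                    beta = L$beta,
                                                    deltaFrac = L$deltaFrac,
                                                    nccK = L$nccK,
                                                    nccEps = L$nccEps,
                                                    nccStride = nccStride),
                                   tvWeight = 1 / npx)
          lrsum <- lrsum + lr_b$total
          dIHS <- -.nccGradB(a, ihs, k = L$nccK, stride = nccStride,
                             eps = L$nccEps)
          wg <- warpImageGrad(bt$he[, , , b], cc$d, dIHS)
          ddx <- wg$ddx + .tvGrad(dvfX(cc$d)) / npx
          ddy <- wg$ddy + .tvGrad(dvfY(cc$d)) / npx
          # straight-through clipping, transpose of the symmetric smoother
          dRaw[, , 1, b] <- .gauss3(ddx * cc$mx) / B
          dRaw[, , 2, b] <- .gauss3(ddy * cc$my) / B
        }
        if (any(!is.finite(dRaw)))
          stop(sprintf("divergent registration loss at cycle %d", cyc))
        net_backward(regnet@ptr, dRaw)
        net_step(regnet@ptr, cfg$lrR)
        itersR <- itersR + 1L
        lr_val <- lrsum / B
      }

      valLG <- NA_real_
      if (cyc %% cfg$valEvery == 0 || cyc == cfg$maxCycles) {
        valLG <- .validationLG(gen, disc, regnet, valPairs, cfg)
        if (is.finite(valLG) && valLG < bestLG) {
          bestLG <- valLG; bestCycle <- cyc
          bestParams <- net_params(gen@ptr)
        }
        if (verbose)
          message(sprintf(
            "cycle %d: L_G %.4f (val %.4f, best %.4f) L_D %.4f L_R %s",
            cyc, gstats["LG"], valLG, bestLG, ld,
            ifelse(is.na(lr_val), "-", sprintf("%.4f", lr_val))))
      }
      hist[[cyc]] <- data.frame(cycle = cyc, ratio = ratio,
                                LG = gstats[["LG"]], berhu = gstats[["berhu"]],
                                tv = gstats[["tv"]], adv = gstats[["adv"]],
                                LD = ld, LR = lr_val, valLG = valLG)
    }

    net_set_params(gen@ptr, bestParams)
    state <- list(tD = tD, itersG = itersG, itersR = itersR,
                  lossHistory = do.call(rbind, hist),
                  bestLG = bestLG, bestCycle = bestCycle,
                  initialValLG = initialValLG)
    new("RegiStainModel", generator = gen, discriminator = disc,
        regnet = regnet, state = state, config = unclass(cfg))
  })
}

#' Predict the displacement field between a generated and a raw target image
#'
#' Runs the generator on the (normalized) autofluorescence input, feeds the
#' result together with the raw histology target through the registration
#' network, and post-processes the raw field.
#'
#' @param model a trained [RegiStainModel-class] (with a registration net)
#' @param sample a [PhantomSample-class] or `list(af, he)`
#' @return a [DisplacementField-class]
#' @export
predictDVF <- function(model, sample) {
  if (is.null(model@regnet)) stop("model was trained without a registration network")
  s <- .asPair(sample)
  x <- array(normalizePatch(s$af), c(dim(s$af), 1))
  ivs <- net_forward(model@generator@ptr, x, FALSE)
  hv <- array(s$he, c(dim(s$he), 1))
  reg <- .registerBatch(model@regnet, ivs, hv, model@config, train = FALSE)
  reg$cache[[1]]$d
}

#' Tiled inference with overlap blending
#'
#' Normalizes the autofluorescence image (per channel, whole image), runs
#' the generator over tiles with linear-feathered overlap blending, and
#' returns an 8-bit RGB image. A single-tile image reduces to one direct
#' forward pass.
#'
#' @param gen a trained generator ([ConvNet-class]) or [RegiStainModel-class]
#' @param af autofluorescence image (H, W, 2) in `[0, 1]`
#' @param tile tile size in pixels
#' @param overlap overlap in pixels between adjacent tiles
#' @return virtually stained RGB array (H, W, 3), values `0..255`
#' @export
inferVirtualStain <- function(gen, af, tile = 2048, overlap = 32) {
  if (is(gen, "RegiStainModel")) gen <- gen@generator
  af <- .asChannels(af)
  if (dim(af)[3] != 2) stop("autofluorescence input must have 2 channels")
  H <- dim(af)[1]; W <- dim(af)[2]
  mult <- 2^gen@depth
  x <- normalizePatch(af)
  num <- array(0, c(H, W, 3)); den <- matrix(0, H, W)
  step <- max(tile - overlap, 1)
  r0s <- if (H <= tile) 1L else unique(c(seq(1, H - tile, by = step), H - tile + 1))
  c0s <- if (W <= tile) 1L else unique(c(seq(1, W - tile, by = step), W - tile + 1))
  for (r0 in r0s) for (c0 in c0s) {
    r1 <- min(r0 + tile - 1, H); c1 <- min(c0 + tile - 1, W)
    tl <- x[r0:r1, c0:c1, , drop = FALSE]
    th <- dim(tl)[1]; tw <- dim(tl)[2]
    ph <- ceiling(th / mult) * mult; pw <- ceiling(tw / mult) * mult
    pad <- array(0, c(ph, pw, 2))
    pad[seq_len(th), seq_len(tw), ] <- tl
    if (ph > th) pad[(th + 1):ph, , ] <- pad[rep(th, ph - th), , , drop = FALSE]
    if (pw > tw) pad[, (tw + 1):pw, ] <- pad[, rep(tw, pw - tw), , drop = FALSE]
    y <- net_forward(gen@ptr, array(pad, c(ph, pw, 2, 1)), FALSE)
    y <- y[seq_len(th), seq_len(tw), , 1, drop = FALSE]
    ov <- max(overlap, 1)
    wr <- pmin(seq_len(th) / ov, rev(seq_len(th)) / ov, 1)
    wc <- pmin(seq_len(tw) / ov, rev(seq_len(tw)) / ov, 1)
    wt <- outer(wr, wc)
    for (ch in 1:3)
      num[r0:r1, c0:c1, ch] <- num[r0:r1, c0:c1, ch] + y[, , ch, 1] * wt
    den[r0:r1, c0:c1] <- den[r0:r1, c0:c1] + wt
  }
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- num[, , ch] / den
  round(out * 255)
}
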