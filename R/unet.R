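# The segmentation network: a 5-level U-Net encoder-decoder with a CBAM block
# before every encoder max-pool and an SE block after every decoder conv pair,
# ending in a 1x1 convolution over the class channels. Parameters live in a
# flat named list ("enc1.conv1.W", ...); the matching gradient list is
# produced by netBackward and consumed by the RMSprop update.

cbamAtLevel <- function(config, l) {
  config@useCBAM &&
    (l < config@levels || (l == config@levels && config@cbamAtBottleneck))
}

#' Build the attention U-Net segmentation model
#'
#' Encoder levels apply `[conv3x3 - BN - ReLU] x 2`, a CBAM block, then 2x2
#' max pooling; the deepest level is the bottleneck (no pool; CBAM there only
#' if `cbamAtBottleneck`). Decoder levels upsample by 2 (learned transposed
#' convolution, or bilinear interpolation plus a 1x1 convolution), concatenate
#' the skip feature from the matching encoder level, apply the conv pair and
#' an SE block. A final 1x1 convolution maps to the class logits. Parameter
#' initialisation is fully determined by `seed`.
#'
#' @param config a [NetworkConfig-class].
#' @param seed RNG seed for the He weight initialisation (default 1).
#' @return an object of class `csftuNet`: list with `config`, `params` (flat
#'   named list of arrays), `state` (batch-norm running statistics), `seed`.
#' @examples
#' m <- buildModel(networkConfig(levels = 2, baseFilters = 4,
#'                               cbamReduction = 2, seReduction = 2))
#' @export
buildModel <- function(config, seed = 1) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  f <- config@filtersPerLevel
  L <- config@levels
  params <- list()
  state <- list()
  addConvBlock <- function(prefix, cin, c) {
    params[[paste0(prefix, ".conv1.W")]] <<- heInit(c(3, 3, cin, c), 9 * cin)
    params[[paste0(prefix, ".conv1.b")]] <<- numeric(c)
    params[[paste0(prefix, ".bn1.gamma")]] <<- rep(1, c)
    params[[paste0(prefix, ".bn1.beta")]] <<- numeric(c)
    params[[paste0(prefix, ".conv2.W")]] <<- heInit(c(3, 3, c, c), 9 * c)
    params[[paste0(prefix, ".conv2.b")]] <<- numeric(c)
    params[[paste0(prefix, ".bn2.gamma")]] <<- rep(1, c)
    params[[paste0(prefix, ".bn2.beta")]] <<- numeric(c)
    state[[paste0(prefix, ".bn1")]] <<- list(mean = numeric(c), var = rep(1, c))
    state[[paste0(prefix, ".bn2")]] <<- list(mean = numeric(c), var = rep(1, c))
  }
  addNamed <- function(prefix, lst) {
    for (nm in names(lst)) {
      if (is.list(lst[[nm]])) addNamed(paste0(prefix, ".", nm), lst[[nm]])
      else params[[paste0(prefix, ".", nm)]] <<- lst[[nm]]
    }
  }
  withSeed(seed, {
    for (l in seq_len(L)) {
      cin <- if (l == 1L) config@inChannels else f[l - 1L]
      addConvBlock(paste0("enc", l), cin, f[l])
      if (cbamAtLevel(config, l))
        addNamed(paste0("enc", l, ".cbam"),
                 initCBAMParams(f[l], config@cbamReduction, config@spatialKernel))
    }
    for (l in rev(seq_len(L - 1L))) {
      if (config@upsampleMode == "transposed") {
        params[[paste0("dec", l, ".up.W")]] <- heInit(c(2, 2, f[l + 1L], f[l]),
                                                      4 * f[l + 1L])
      } else {
        params[[paste0("dec", l, ".up.W")]] <- heInit(c(1, 1, f[l + 1L], f[l]),
                                                      f[l + 1L])
      }
      params[[paste0("dec", l, ".up.b")]] <- numeric(f[l])
      addConvBlock(paste0("dec", l), 2L * f[l], f[l])
      if (config@useSE)
        addNamed(paste0("dec", l, ".se"), initSEParams(f[l], config@seReduction))
    }
    params[["head.W"]] <- heInit(c(1, 1, f[1L], config@numClasses), f[1L])
    params[["head.b"]] <- numeric(config@numClasses)
  })
  structure(list(config = config, params = params, state = state, seed = seed),
            class = "csftuNet")
}

#' @export
print.csftuNet <- function(x, ...) {
  nPar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("csftuNet segmentation model: %s parameters (seed %d)\n",
              format(nPar, big.mark = ","), x$seed))
  print(x$config)
  invisible(x)
}

#' Checksums of all model parameter tensors
#'
#' One sum per parameter tensor, in construction order; two models built with
#' the same configuration and seed have identical checksums.
#'
#' @param model a `csftuNet` model.
#' @return named numeric vector of per-tensor sums.
#' @export
modelChecksum <- function(model) {
  vapply(model$params, sum, numeric(1))
}

# a CBAM parameter sub-list from the flat param list
getCBAM <- function(params, prefix) {
  list(ca = list(W1 = params[[paste0(prefix, ".ca.W1")]],
                 b1 = params[[paste0(prefix, ".ca.b1")]],
                 W2 = params[[paste0(prefix, ".ca.W2")]],
                 b2 = params[[paste0(prefix, ".ca.b2")]]),
       sa = list(W = params[[paste0(prefix, ".sa.W")]],
                 b = params[[paste0(prefix, ".sa.b")]]))
}

getSE <- function(params, prefix) {
  list(W1 = params[[paste0(prefix, ".W1")]], b1 = params[[paste0(prefix, ".b1")]],
       W2 = params[[paste0(prefix, ".W2")]], b2 = params[[paste0(prefix, ".b2")]])
}

# conv - BN - ReLU - conv - BN - ReLU
convBlockForward <- function(x, p, prefix, state, training) {
  c1 <- convForward(x, p[[paste0(prefix, ".conv1.W")]],
                    p[[paste0(prefix, ".conv1.b")]])
  b1 <- bnForward(c1$out, p[[paste0(prefix, ".bn1.gamma")]],
                  p[[paste0(prefix, ".bn1.beta")]],
                  state[[paste0(prefix, ".bn1")]], training)
  r1 <- reluForward(b1$out)
  c2 <- convForward(r1$out, p[[paste0(prefix, ".conv2.W")]],
                    p[[paste0(prefix, ".conv2.b")]])
  b2 <- bnForward(c2$out, p[[paste0(prefix, ".bn2.gamma")]],
                  p[[paste0(prefix, ".bn2.beta")]],
                  state[[paste0(prefix, ".bn2")]], training)
  r2 <- reluForward(b2$out)
  list(out = r2$out,
       state = setNames(list(b1$state, b2$state),
                        paste0(prefix, c(".bn1", ".bn2"))),
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

convBlockBackward <- function(dout, p, prefix, cache, grads) {
  d <- reluBackward(dout, cache$r2)
  bb2 <- bnBackward(d, p[[paste0(prefix, ".bn2.gamma")]], cache$b2)
  grads[[paste0(prefix, ".bn2.gamma")]] <- bb2$dgamma
  grads[[paste0(prefix, ".bn2.beta")]] <- bb2$dbeta
  cb2 <- convBackward(bb2$dx, p[[paste0(prefix, ".conv2.W")]], cache$c2)
  grads[[paste0(prefix, ".conv2.W")]] <- cb2$dW
  grads[[paste0(prefix, ".conv2.b")]] <- cb2$db
  d <- reluBackward(cb2$dx, cache$r1)
  bb1 <- bnBackward(d, p[[paste0(prefix, ".bn1.gamma")]], cache$b1)
  grads[[paste0(prefix, ".bn1.gamma")]] <- bb1$dgamma
  grads[[paste0(prefix, ".bn1.beta")]] <- bb1$dbeta
  cb1 <- convBackward(bb1$dx, p[[paste0(prefix, ".conv1.W")]], cache$c1)
  grads[[paste0(prefix, ".conv1.W")]] <- cb1$dW
  grads[[paste0(prefix, ".conv1.b")]] <- cb1$db
  list(dx = cb1$dx, grads = grads)
}

# Full forward pass. x: (H, W, inChannels). Returns logits (H, W, numClasses),
# the updated batch-norm state, and (when withCache) everything backward needs.
netForward <- function(model, x, training = FALSE, withCache = training) {
  cfg <- model$config
  p <- model$params
  L <- cfg@levels
  d <- dim(x)
  div <- 2L^(L - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf(
      "input spatial size %dx%d is not divisible by %d (required for %d levels)",
      d[1], d[2], div, L), call. = FALSE)
  state <- model$state
  cache <- if (withCache) list(enc = vector("list", L),
                               dec = vector("list", L - 1L)) else NULL
  skips <- vector("list", L - 1L)
  cur <- x
  for (l in seq_len(L)) {
    blk <- convBlockForward(cur, p, paste0("enc", l), state, training)
    state[names(blk$state)] <- blk$state
    cur <- blk$out
    lc <- list(block = blk$cache)
    if (cbamAtLevel(cfg, l)) {
      cb <- cbamForward(cur, getCBAM(p, paste0("enc", l, ".cbam")))
      cur <- cb$out
      lc$cbam <- cb$cache
    }
    if (l < L) {
      skips[[l]] <- cur
      mp <- maxpoolForward(cur)
      cur <- mp$out
      lc$pool <- mp$cache
    }
    if (withCache) cache$enc[[l]] <- lc
  }
  for (l in rev(seq_len(L - 1L))) {
    lc <- list()
    if (cfg@upsampleMode == "transposed") {
      up <- upconvForward(cur, p[[paste0("dec", l, ".up.W")]],
                          p[[paste0("dec", l, ".up.b")]])
      cur <- up$out
      lc$up <- up$cache
    } else {
      bi <- bilinearUpForward(cur)
      cv <- convForward(bi$out, p[[paste0("dec", l, ".up.W")]],
                        p[[paste0("dec", l, ".up.b")]])
      cur <- cv$out
      lc$up <- list(bi = bi$cache, conv = cv$cache)
    }
    nSkip <- dim(skips[[l]])[3]
    dd <- dim(cur)
    cat3 <- array(0, c(dd[1], dd[2], nSkip + dd[3]))
    cat3[, , seq_len(nSkip)] <- skips[[l]]
    cat3[, , nSkip + seq_len(dd[3])] <- cur
    lc$nSkip <- nSkip
    blk <- convBlockForward(cat3, p, paste0("dec", l), state, training)
    state[names(blk$state)] <- blk$state
    cur <- blk$out
    lc$block <- blk$cache
    if (cfg@useSE) {
      se <- seForward(cur, getSE(p, paste0("dec", l, ".se")))
      cur <- se$out
      lc$se <- se$cache
    }
    if (withCache) cache$dec[[l]] <- lc
  }
  hd <- convForward(cur, p[["head.W"]], p[["head.b"]])
  if (withCache) cache$head <- hd$cache
  list(logits = hd$out, state = state, cache = cache)
}

# Full backward pass; returns the flat gradient list (same names as params).
netBackward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  L <- cfg@levels
  grads <- list()
  hb <- convBackward(dlogits, p[["head.W"]], cache$head)
  grads[["head.W"]] <- hb$dW
  grads[["head.b"]] <- hb$db
  dcur <- hb$dx
  dskips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    lc <- cache$dec[[l]]
    if (cfg@useSE) {
      sb <- seBackward(dcur, getSE(p, paste0("dec", l, ".se")), lc$se)
      for (nm in names(sb$grads))
        grads[[paste0("dec", l, ".se.", nm)]] <- sb$grads[[nm]]
      dcur <- sb$dx
    }
    bb <- convBlockBackward(dcur, p, paste0("dec", l), lc$block, grads)
    grads <- bb$grads
    dcat <- bb$dx
    nSkip <- lc$nSkip
    dd <- dim(dcat)
    dskips[[l]] <- dcat[, , seq_len(nSkip), drop = FALSE]
    dup <- dcat[, , (nSkip + 1L):dd[3], drop = FALSE]
    if (cfg@upsampleMode == "transposed") {
      ub <- upconvBackward(dup, p[[paste0("dec", l, ".up.W")]], lc$up)
      grads[[paste0("dec", l, ".up.W")]] <- ub$dW
      grads[[paste0("dec", l, ".up.b")]] <- ub$db
      dcur <- ub$dx
    } else {
      cb <- convBackward(dup, p[[paste0("dec", l, ".up.W")]], lc$up$conv)
      grads[[paste0("dec", l, ".up.W")]] <- cb$dW
      grads[[paste0("dec", l, ".up.b")]] <- cb$db
      dcur <- bilinearUpBackward(cb$dx, lc$up$bi)
    }
  }
  for (l in rev(seq_len(L))) {
    lc <- cache$enc[[l]]
    if (l < L) {
      dcur <- maxpoolBackward(dcur, lc$pool)
      dcur <- dcur + dskips[[l]]
    }
    if (cbamAtLevel(cfg, l)) {
      cb <- cbamBackward(dcur, getCBAM(p, paste0("enc", l, ".cbam")), lc$cbam)
      pre <- paste0("enc", l, ".cbam.")
      grads[[paste0(pre, "ca.W1")]] <- cb$grads$ca$W1
      grads[[paste0(pre, "ca.b1")]] <- cb$grads$ca$b1
      grads[[paste0(pre, "ca.W2")]] <- cb$grads$ca$W2
      grads[[paste0(pre, "ca.b2")]] <- cb$grads$ca$b2
      grads[[paste0(pre, "sa.W")]] <- cb$grads$sa$W
      grads[[paste0(pre, "sa.b")]] <- cb$grads$sa$b
      dcur <- cb$dx
    }
    bb <- convBlockBackward(dcur, p, paste0("enc", l), lc$block, grads)
    grads <- bb$grads
    dcur <- bb$dx
  }
  grads
}

#' Run the model forward on one image
#'
#' @param model a `csftuNet` from [buildModel()] or [trainModel()].
#' @param image `H x W` matrix (intensities in `[0, 1]`, or 0--255 which is
#'   rescaled), or an `(H, W, inChannels)` array. H and W must be divisible
#'   by `2^(levels - 1)`.
#' @return logits array `(H, W, numClasses)`.
#' @export
modelForward <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (max(image) > 1.5) image <- image / 255
  netForward(model, image, training = FALSE, withCache = FALSE)$logits
}

#' Segment a CT volume slice by slice
#'
#' Each axial slice is passed through the network, per-pixel class
#' probabilities are taken with a softmax, and the argmax class is emitted;
#' slice order is preserved. Inference is deterministic (batch-norm running
#' statistics, no sampling).
#'
#' @param model a `csftuNet`.
#' @param volume a [CTVolume-class] (or 3D array) whose slice size matches the
#'   model input constraint; intensities 0--255 or already in `[0, 1]`.
#' @return a [LabelVolume-class] of predictions over `{0, 1, 2}`.
#' @export
predictVolume <- function(model, volume) {
  arr <- if (is(volume, "CTVolume")) voxelData(volume) else volume
  stopifnot(length(dim(arr)) == 3L)
  d <- dim(arr)
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    logits <- modelForward(model, matrix(arr[z, , ], d[2], d[3]))
    probs <- softmaxProbs(logits)
    pm <- matrix(probs, d[2] * d[3], dim(probs)[3])
    out[z, , ] <- max.col(pm, ties.method = "first") - 1L
  }
  LabelVolume(out,
              voxelEdgeUm = if (is(volume, "CTVolume")) voxelEdge(volume) else 27,
              sourceId = "csftuNet prediction")
}
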