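# Attention blocks: CBAM (channel attention followed by spatial attention)
# and squeeze-and-excitation (SE). Forward/backward pairs with explicit
# caches, plus exported user-facing wrappers.

#' Initialise CBAM parameters for a given channel count
#'
#' The channel branch is one shared two-layer MLP (`C -> C/r`, ReLU,
#' `C/r -> C`); the spatial branch is a single `k x k` convolution collapsing
#' the concatenated channel-mean and channel-max maps to one map. Weights are
#' He-initialised from the current RNG state; biases start at zero.
#'
#' @param C number of channels; must be divisible by `r`.
#' @param r channel-MLP reduction ratio (default 16).
#' @param spatialKernel spatial convolution size (odd; default 7).
#' @return parameter list with components `ca` (W1, b1, W2, b2) and `sa` (W, b).
#' @export
initCBAMParams <- function(C, r = 16, spatialKernel = 7) {
  if (C %% r != 0)
    paramError("channel count %d is not divisible by reduction ratio %d", C, r)
  cr <- C %/% r
  list(ca = list(W1 = heInit(c(cr, C), C), b1 = numeric(cr),
                 W2 = heInit(c(C, cr), cr), b2 = numeric(C)),
       sa = list(W = heInit(c(spatialKernel, spatialKernel, 2, 1),
                            2 * spatialKernel^2),
                 b = numeric(1)))
}

#' Initialise squeeze-and-excitation parameters
#'
#' @param C number of channels; must be divisible by `r`.
#' @param r reduction ratio (default 16).
#' @return parameter list with W1, b1, W2, b2.
#' @export
initSEParams <- function(C, r = 16) {
  if (C %% r != 0)
    paramError("channel count %d is not divisible by reduction ratio %d", C, r)
  cr <- C %/% r
  list(W1 = heInit(c(cr, C), C), b1 = numeric(cr),
       W2 = heInit(c(C, cr), cr), b2 = numeric(C))
}

# shared two-layer MLP on a channel vector
caMLP <- function(v, P) {
  pre1 <- as.vector(P$W1 %*% v + P$b1)
  h1 <- pmax(pre1, 0)
  list(out = as.vector(P$W2 %*% h1 + P$b2), h1 = h1, pre1 = pre1, v = v)
}

caForward <- function(x, P) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  avg <- colMeans(xm)
  amaxIdx <- apply(xm, 2, which.max)
  mx <- xm[cbind(amaxIdx, seq_len(d[3]))]
  ba <- caMLP(avg, P$ca)
  bm <- caMLP(mx, P$ca)
  Mc <- sigmoidStable(ba$out + bm$out)
  list(Mc = Mc, cache = list(d = d, n = n, amaxIdx = amaxIdx, ba = ba, bm = bm,
                             Mc = Mc))
}

caMLPBackward <- function(dOut, branch, P) {
  dW2 <- dOut %o% branch$h1
  db2 <- dOut
  dh1 <- as.vector(crossprod(P$W2, dOut)) * (branch$pre1 > 0)
  dW1 <- dh1 %o% branch$v
  db1 <- dh1
  dv <- as.vector(crossprod(P$W1, dh1))
  list(dv = dv, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

caBackward <- function(dMc, P, cache) {
  ds <- dMc * cache$Mc * (1 - cache$Mc)
  ga <- caMLPBackward(ds, cache$ba, P$ca)
  gm <- caMLPBackward(ds, cache$bm, P$ca)
  d <- cache$d
  dxm <- matrix(rep(ga$dv / cache$n, each = cache$n), cache$n, d[3])
  dxm[cbind(cache$amaxIdx, seq_len(d[3]))] <-
    dxm[cbind(cache$amaxIdx, seq_len(d[3]))] + gm$dv
  dx <- dxm
  dim(dx) <- d
  list(dx = dx,
       grads = list(ca = list(W1 = ga$dW1 + gm$dW1, b1 = ga$db1 + gm$db1,
                              W2 = ga$dW2 + gm$dW2, b2 = ga$db2 + gm$db2)))
}

saForward <- function(x, P) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  amap <- rowMeans(xm)
  cmaxIdx <- max.col(xm, ties.method = "first")
  mmap <- xm[cbind(seq_len(n), cmaxIdx)]
  sin <- array(c(amap, mmap), c(d[1], d[2], 2))
  cv <- convForward(sin, P$sa$W, P$sa$b)
  Ms <- sigmoidStable(cv$out[, , 1])
  list(Ms = Ms, cache = list(d = d, n = n, cmaxIdx = cmaxIdx, conv = cv$cache,
                             Ms = Ms))
}

saBackward <- function(dMs, P, cache) {
  d <- cache$d
  dlogit <- dMs * cache$Ms * (1 - cache$Ms)
  dim(dlogit) <- c(d[1], d[2], 1)
  cb <- convBackward(dlogit, P$sa$W, cache$conv)
  damap <- as.vector(cb$dx[, , 1])
  dmmap <- as.vector(cb$dx[, , 2])
  dxm <- matrix(rep(damap / d[3], d[3]), cache$n, d[3])
  dxm[cbind(seq_len(cache$n), cache$cmaxIdx)] <-
    dxm[cbind(seq_len(cache$n), cache$cmaxIdx)] + dmmap
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, grads = list(sa = list(W = cb$dW, b = cb$db)))
}

cbamForward <- function(x, P) {
  ca <- caForward(x, P)
  Fc <- chmul(x, ca$Mc)
  sa <- saForward(Fc, P)
  out <- Fc * as.vector(sa$Ms)      # Ms broadcasts over the channel axis
  list(out = out, cache = list(x = x, Fc = Fc, ca = ca, sa = sa))
}

cbamBackward <- function(dout, P, cache) {
  Ms <- cache$sa$Ms
  dFc <- dout * as.vector(Ms)
  d <- dim(dout)
  dMs <- rowSums(matrix(dout * cache$Fc, d[1] * d[2], d[3]))
  dim(dMs) <- c(d[1], d[2])
  sb <- saBackward(dMs, P, cache$sa$cache)
  dFc <- dFc + sb$dx
  dx <- chmul(dFc, cache$ca$Mc)
  dMc <- colSums(matrix(dFc * cache$x, d[1] * d[2], d[3]))
  cb <- caBackward(dMc, P, cache$ca$cache)
  dx <- dx + cb$dx
  list(dx = dx, grads = c(cb$grads, sb$grads))
}

seForward <- function(x, P) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  z <- colMeans(xm)
  br <- caMLP(z, P)
  s <- sigmoidStable(br$out)
  out <- chmul(x, s)
  list(out = out, cache = list(d = d, n = n, br = br, s = s, x = x))
}

seBackward <- function(dout, P, cache) {
  d <- cache$d
  dx <- chmul(dout, cache$s)
  dsvec <- colSums(matrix(dout * cache$x, cache$n, d[3]))
  dpre <- dsvec * cache$s * (1 - cache$s)
  g <- caMLPBackward(dpre, cache$br, P)
  dx <- dx + array(rep(g$dv / cache$n, each = cache$n), d)
  list(dx = dx, grads = list(W1 = g$dW1, b1 = g$db1, W2 = g$dW2, b2 = g$db2))
}

# ---- exported wrappers -----------------------------------------------------

#' Channel attention weights of a feature map
#'
#' Global average pooling and global max pooling over the spatial axes each
#' yield a length-C descriptor; both pass through the shared two-layer MLP,
#' the outputs are summed and squashed by a sigmoid. One weight per channel,
#' each strictly in (0, 1).
#'
#' @param x feature map array `(H, W, C)`.
#' @param params CBAM parameters from [initCBAMParams()] (their `C` must
#'   match).
#' @return numeric vector of C channel weights.
#' @export
channelAttention <- function(x, params) {
  stopifnot(length(dim(x)) == 3L)
  if (length(params$ca$b2) != dim(x)[3])
    paramError("params built for %d channels but feature map has %d",
               length(params$ca$b2), dim(x)[3])
  caForward(x, params)$Mc
}

#' Spatial attention map of a feature map
#'
#' The channel-wise mean map and channel-wise max map (each `H x W`) are
#' concatenated and convolved with a single `k x k` filter; the sigmoid of
#' the result is the per-position weight map, strictly in (0, 1).
#'
#' @param x feature map array `(H, W, C)` (normally already channel-weighted).
#' @param params CBAM parameters from [initCBAMParams()].
#' @return `H x W` matrix of spatial weights.
#' @export
spatialAttention <- function(x, params) {
  stopifnot(length(dim(x)) == 3L)
  saForward(x, params)$Ms
}

#' Apply a CBAM block to a feature map
#'
#' `F' = (F (*) Mc) (*) Ms`: the input is rescaled per channel by the channel
#' attention weights, then per position by the spatial attention map. Shape
#' is preserved exactly.
#'
#' @inheritParams channelAttention
#' @return feature map of the same shape as `x`.
#' @export
cbamApply <- function(x, params) {
  stopifnot(length(dim(x)) == 3L)
  cbamForward(x, params)$out
}

#' Apply a squeeze-and-excitation block to a feature map
#'
#' Squeeze: global average pool to a length-C descriptor. Excitation:
#' `s = sigmoid(W2 relu(W1 z))` (with biases). Scale: channel c of the input
#' is multiplied by `s_c`. Shape is preserved.
#'
#' @param x feature map array `(H, W, C)`.
#' @param params SE parameters from [initSEParams()].
#' @return feature map of the same shape as `x`.
#' @export
seApply <- function(x, params) {
  stopifnot(length(dim(x)) == 3L)
  if (length(params$b2) != dim(x)[3])
    paramError("params built for %d channels but feature map has %d",
               length(params$b2), dim(x)[3])
  seForward(x, params)$out
}
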