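# Neural-network layer primitives.
#
# Feature maps are arrays (H, W, C); batch size is 1 throughout (the training
# protocol optimises per image). Convolutions are computed as sums of shifted
# matrix products: for a k x k kernel, the output (H*W, Cout) matrix is
# sum over the k^2 taps of X_shift (H*W, Cin) %*% W[tap] (Cin, Cout), which
# keeps all heavy lifting inside BLAS. Every forward returns the cache its
# backward needs; backwards return dx plus parameter gradients.

heInit <- function(dims, fanIn) array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)

# multiply/add a per-channel vector onto the last axis of an array or the
# columns of an (n, C) matrix, without sweep()'s aperm overhead
chmul <- function(x, v) x * rep(v, each = length(x) / length(v))
chadd <- function(x, v) x + rep(v, each = length(x) / length(v))

# weight array (k, k, Cin, Cout) -> (Cin*k*k, Cout) matrix matching the
# compiled im2col layout (channel fastest within each tap, taps in (ki, kj)
# order)
convWeightMat <- function(W) {
  d <- dim(W)
  m <- aperm(W, c(3, 1, 2, 4))
  dim(m) <- c(d[3] * d[1] * d[2], d[4])
  m
}

# Same-padding stride-1 convolution. W: (k, k, Cin, Cout); b: length Cout.
# Compiled im2col + one GEMM; the cache keeps the im2col matrix for the
# weight gradient.
convForward <- function(x, W, b, withCache = TRUE) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x)
  stopifnot(d[3] == cin)
  res <- .convForwardCpp(x, convWeightMat(W), b, k, withCache)
  list(out = res$out,
       cache = if (withCache) list(cols = res$cols, k = k, cin = cin,
                                   cout = cout, H = d[1], W = d[2]))
}

convBackward <- function(dout, W, cache) {
  k <- cache$k; cin <- cache$cin; cout <- cache$cout
  res <- .convBackwardCpp(dout, convWeightMat(W), cache$cols, k, cin)
  dWm <- res$dWm
  dim(dWm) <- c(cin, k, k, cout)
  list(dx = res$dx, dW = aperm(dWm, c(2, 3, 1, 4)), db = as.vector(res$db))
}

# Per-channel batch normalisation (batch of one image: statistics over H x W).
bnForward <- function(x, gamma, beta, state, training, momentum = 0.1,
                      eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- chadd(xm, -mu)
    va <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
    xc <- chadd(xm, -mu)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- chmul(xc, invstd)
  out <- chadd(chmul(xhat, gamma), beta)
  dim(out) <- d
  list(out = out, state = state,
       cache = list(xhat = xhat, invstd = invstd, n = n, d = d,
                    training = training))
}

bnBackward <- function(dout, gamma, cache) {
  d <- cache$d; n <- cache$n
  dm <- dout
  dim(dm) <- c(n, d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  if (cache$training) {
    t1 <- chadd(dm, -dbeta / n)
    t2 <- chmul(cache$xhat, dgamma / n)
    dx <- chmul(t1 - t2, gamma * cache$invstd)
  } else {
    dx <- chmul(dm, gamma * cache$invstd)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(dout, cache) dout * cache

sigmoidStable <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling, stride 2 (compiled). Requires even H and W; ties go to
# the first candidate in (top-left, bottom-left, top-right, bottom-right)
# order for determinism.
maxpoolForward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop(sprintf("spatial size %dx%d not divisible by 2 at a pooling stage",
                 d[1], d[2]), call. = FALSE)
  res <- .maxpoolForwardCpp(x)
  list(out = res$out, cache = res$pick)
}

maxpoolBackward <- function(dout, cache) .maxpoolBackwardCpp(dout, cache)

# Learned 2x2 stride-2 transposed convolution. W: (2, 2, Cin, Cout).
upconvForward <- function(x, W, b) {
  d <- dim(x)
  cin <- dim(W)[3]; cout <- dim(W)[4]
  xm <- x
  dim(xm) <- c(d[1] * d[2], cin)
  out <- array(0, c(2L * d[1], 2L * d[2], cout))
  for (ki in 1:2) for (kj in 1:2) {
    blk <- xm %*% matrix(W[ki, kj, , ], cin, cout)
    dim(blk) <- c(d[1], d[2], cout)
    out[seq(ki, 2L * d[1], 2L), seq(kj, 2L * d[2], 2L), ] <- blk
  }
  out <- chadd(out, b)
  list(out = out, cache = list(xm = xm, d = d, cin = cin, cout = cout))
}

upconvBackward <- function(dout, W, cache) {
  d <- cache$d; cin <- cache$cin; cout <- cache$cout
  dW <- array(0, dim(W))
  dxm <- matrix(0, d[1] * d[2], cin)
  db <- numeric(cout)
  for (ki in 1:2) for (kj in 1:2) {
    blk <- dout[seq(ki, 2L * d[1], 2L), seq(kj, 2L * d[2], 2L), , drop = FALSE]
    dim(blk) <- c(d[1] * d[2], cout)
    dW[ki, kj, , ] <- crossprod(cache$xm, blk)
    dxm <- dxm + blk %*% t(matrix(W[ki, kj, , ], cin, cout))
    db <- db + colSums(blk)
  }
  dx <- dxm
  dim(dx) <- c(d[1], d[2], cin)
  list(dx = dx, dW = dW, db = db)
}

# Factor-2 bilinear interpolation matrix (half-pixel centres, edge clamped).
bilinearMatrix <- function(n) {
  m <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    p <- i / 2 + 0.25
    l <- floor(p)
    w <- p - l
    lo <- min(max(l, 1L), n)
    hi <- min(max(l + 1L, 1L), n)
    m[i, lo] <- m[i, lo] + (1 - w)
    m[i, hi] <- m[i, hi] + w
  }
  m
}

bilinearUpForward <- function(x) {
  d <- dim(x)
  Rm <- bilinearMatrix(d[1]); Cm <- bilinearMatrix(d[2])
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Rm %*% x[, , c] %*% t(Cm)
  list(out = out, cache = list(Rm = Rm, Cm = Cm, d = d))
}

bilinearUpBackward <- function(dout, cache) {
  d <- cache$d
  dx <- array(0, d)
  for (c in seq_len(d[3]))
    dx[, , c] <- t(cache$Rm) %*% dout[, , c] %*% cache$Cm
  dx
}

# Per-pixel softmax over the channel axis of a (H, W, K) logit array.
softmaxProbs <- function(logits) {
  d <- dim(logits)
  lm <- logits
  dim(lm) <- c(d[1] * d[2], d[3])
  lm <- lm - apply(lm, 1, max)
  e <- exp(lm)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# d(loss)/d(logits) from d(loss)/d(probs) through the per-pixel softmax.
softmaxBackward <- function(dprobs, probs) {
  d <- dim(probs)
  pm <- probs; gm <- dprobs
  dim(pm) <- c(d[1] * d[2], d[3])
  dim(gm) <- c(d[1] * d[2], d[3])
  inner <- rowSums(pm * gm)
  dl <- pm * (gm - inner)
  dim(dl) <- d
  dl
}
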