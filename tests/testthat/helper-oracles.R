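# Literal brute-force oracles, written as plain double loops over pixels so
# they stay independent of the vectorised implementation they check.

bfCounts <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  tp <- 0; nx <- 0; ny <- 0; uni <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      tp <- tp + X[i, j] * Y[i, j]
      nx <- nx + X[i, j]
      ny <- ny + Y[i, j]
      uni <- uni + max(X[i, j], Y[i, j])
    }
  }
  list(tp = tp, nx = nx, ny = ny, uni = uni)
}

bfTversky <- function(X, Y, beta = 0.75, eps = 1e-6) {
  ct <- bfCounts(X, Y)
  (ct$tp + eps) / (beta * ct$nx + (1 - beta) * ct$ny + eps)
}

bfDice <- function(X, Y) {
  ct <- bfCounts(X, Y)
  if (ct$nx + ct$ny == 0) return(1)
  2 * ct$tp / (ct$nx + ct$ny)
}

bfIoU <- function(X, Y) {
  ct <- bfCounts(X, Y)
  if (ct$uni == 0) return(1)
  ct$tp / ct$uni
}

bfFocalTversky <- function(X, Y, alpha = 1, beta = 0.75, gamma = 2, eps = 1e-6) {
  alpha * (1 - bfTversky(X, Y, beta, eps))^gamma
}

# forward-difference gradient magnitude with edge replication, double loop
bfGradMag <- function(I) {
  I <- as.matrix(I)
  ny <- nrow(I); nx <- ncol(I)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      gy <- if (i < ny) I[i + 1, j] - I[i, j] else 0
      gx <- if (j < nx) I[i, j + 1] - I[i, j] else 0
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

bfBoundaryLoss <- function(P, Tm, lambda) {
  gp <- bfGradMag(P)
  gt <- bfGradMag(Tm)
  s <- 0
  for (i in seq_len(nrow(gp)))
    for (j in seq_len(ncol(gp)))
      s <- s + (gp[i, j] - gt[i, j])^2
  lambda * s
}

# exhaustive voxel count by triple loop
bfVoxelCount <- function(mask) {
  d <- dim(mask)
  n <- 0
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        if (mask[z, y, x] > 0) n <- n + 1
  n
}

# all 2^9 binary 3x3 masks as a 512 x 9 matrix (row-major bit order)
allMasks3x3 <- function() {
  m <- matrix(0L, 512, 9)
  for (i in 0:511) m[i + 1, ] <- as.integer(intToBits(i)[1:9])
  m
}

randomMask <- function(ny, nx, p = 0.5) {
  matrix(as.integer(runif(ny * nx) < p), ny, nx)
}

# small random phantom-like training samples for quick network tests
tinySamples <- function(n, side = 32, seed = 1) {
  makeTrainingSet(n, specRanges = list(noiseSd = c(2, 4)), seed = seed,
                  side = side)
}

# reduced network used in the segmentation-recovery checks
tinyNetConfig <- function(base = 8, levels = 3) {
  networkConfig(levels = levels, baseFilters = base, cbamReduction = base,
                seReduction = base, spatialKernel = 7)
}

# soft Dice (sums instead of hard counts), for the Dice-loss identity check
diceScore2soft <- function(X, Y) 2 * sum(X * Y) / (sum(X) + sum(Y))
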