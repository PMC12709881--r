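# Composite segmentation objective: focal Tversky overlap term plus a
# boundary-smoothing term that matches predicted and true gradient magnitudes.
# Low-level functions operate on a pair of same-shape arrays (soft
# probabilities or hard masks); segmentationLoss() lifts them to the 3-class
# task one-vs-rest and supplies the analytic gradient used in training.

checkSameShape <- function(X, Y) {
  if (!identical(dim(X) %||% length(X), dim(Y) %||% length(Y)))
    stop("shape mismatch between prediction and truth", call. = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tversky index between a prediction and a truth mask
#'
#' `T = (|X intersect Y| + eps) / (beta |X| + (1 - beta) |Y| + eps)` with
#' `|X intersect Y|` the elementwise-product sum and `|X|`, `|Y|` the mask
#' sums (the `"printed"` variant). The `"standard"` form
#' `(TP + eps) / (TP + beta FN + (1 - beta) FP + eps)` is available via
#' `variant`; the two coincide on hard masks up to the role of `beta`.
#' At `beta = 0.5` both reduce to the Dice coefficient.
#'
#' @param X prediction: soft probabilities in `[0, 1]` or a hard 0/1 mask.
#' @param Y truth: hard 0/1 mask of the same shape.
#' @param beta false-negative/false-positive balance (default 0.75).
#' @param epsilon stabilising constant (default 1e-6).
#' @param variant `"printed"` (default) or `"standard"`.
#' @return the Tversky index, in `[0, 1]` up to `epsilon`.
#' @examples
#' X <- c(1, 1, 1, 1, 0); Y <- c(1, 1, 0, 0, 1)
#' tverskyIndex(X, Y, beta = 0.5)   # equals Dice = 2*2/(4+3)... here 2/3.5
#' @export
tverskyIndex <- function(X, Y, beta = 0.75, epsilon = 1e-6,
                         variant = c("printed", "standard")) {
  checkSameShape(X, Y)
  variant <- match.arg(variant)
  tp <- sum(X * Y)
  if (variant == "printed") {
    denom <- beta * sum(X) + (1 - beta) * sum(Y)
  } else {
    fn <- sum((1 - X) * Y)
    fp <- sum(X * (1 - Y))
    denom <- tp + beta * fn + (1 - beta) * fp
  }
  (tp + epsilon) / (denom + epsilon)
}

#' Focal Tversky loss
#'
#' `alpha * (1 - T)^gamma` where `T` is the [tverskyIndex()]. Given a pair of
#' masks/probability maps it returns the two-set value; given a probability
#' array `(H, W, K)` and an integer label matrix it is computed one-vs-rest
#' per foreground class (classes `1..K-1`; background channel 1 excluded) and
#' averaged with equal weight.
#'
#' @param X prediction mask/probabilities, or `(H, W, K)` class-probability
#'   array.
#' @param Y truth mask, or `(H, W)` integer label matrix over `0..K-1`.
#' @param config a [LossConfig-class] (defaults via [lossConfig()]).
#' @return loss value in `[0, alpha]`.
#' @export
focalTverskyLoss <- function(X, Y, config = lossConfig()) {
  if (length(dim(X)) == 3L && length(dim(Y) %||% 0) == 2L) {
    K <- dim(X)[3]
    per <- vapply(seq_len(K - 1L), function(cls) {
      focalTverskyLoss(X[, , cls + 1L], (Y == cls) * 1, config)
    }, numeric(1))
    return(mean(per))
  }
  t <- tverskyIndex(X, Y, beta = config@beta, epsilon = config@epsilon,
                    variant = config@variant)
  config@alpha * (1 - t)^config@gamma
}

# Per-pixel gradient magnitude: forward first differences with edge
# replication (boundary differences are zero), or Sobel.
gradMagnitude <- function(I, op = c("forward", "sobel")) {
  op <- match.arg(op)
  I <- as.matrix(I)
  if (op == "forward") {
    nx <- ncol(I); ny <- nrow(I)
    gx <- I[, c(seq_len(nx)[-1], nx), drop = FALSE] - I
    gy <- I[c(seq_len(ny)[-1], ny), , drop = FALSE] - I
    sqrt(gx^2 + gy^2)
  } else {
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    gx <- as.matrix(EBImage::filter2(I, kx, boundary = "replicate"))
    gy <- as.matrix(EBImage::filter2(I, t(kx), boundary = "replicate"))
    sqrt(gx^2 + gy^2)
  }
}

#' Boundary-smoothing loss
#'
#' `lambda * sum_ij (|grad Ipred(i,j)| - |grad Itrue(i,j)|)^2`: penalises
#' mismatch between the predicted and true per-pixel gradient magnitudes, so
#' the prediction is pushed to place sharp class boundaries where the truth
#' has them and to stay smooth elsewhere.
#'
#' @param Ipred,Itrue same-shape matrices (probability or label maps), or
#'   `(H, W, K)` probabilities vs `(H, W)` labels for the one-vs-rest
#'   multi-class form (averaged over foreground classes).
#' @param lambdaSmooth weight `lambda >= 0` (default 0.001).
#' @param gradientOp `"forward"` (default) or `"sobel"`.
#' @return loss value `>= 0`.
#' @export
boundarySmoothnessLoss <- function(Ipred, Itrue, lambdaSmooth = 0.001,
                                   gradientOp = c("forward", "sobel")) {
  gradientOp <- match.arg(gradientOp)
  if (lambdaSmooth < 0) paramError("lambdaSmooth must be >= 0")
  if (length(dim(Ipred)) == 3L && length(dim(Itrue) %||% 0) == 2L) {
    K <- dim(Ipred)[3]
    per <- vapply(seq_len(K - 1L), function(cls) {
      boundarySmoothnessLoss(Ipred[, , cls + 1L], (Itrue == cls) * 1,
                             lambdaSmooth, gradientOp)
    }, numeric(1))
    return(mean(per))
  }
  checkSameShape(Ipred, Itrue)
  gp <- gradMagnitude(Ipred, gradientOp)
  gt <- gradMagnitude(Itrue, gradientOp)
  lambdaSmooth * sum((gp - gt)^2)
}

#' Total segmentation loss
#'
#' Sum of the focal Tversky term and the boundary-smoothing term,
#' `L = L_focalTversky + L_smooth`. With `lambdaSmooth = 0` it equals
#' [focalTverskyLoss()] exactly; a perfect prediction gives 0 (up to
#' `epsilon`).
#'
#' @inheritParams focalTverskyLoss
#' @return loss value `>= 0`.
#' @export
totalLoss <- function(X, Y, config = lossConfig()) {
  focalTverskyLoss(X, Y, config) +
    boundarySmoothnessLoss(X, Y, config@lambdaSmooth, config@gradientOp)
}

#' Pixel-wise cross-entropy loss
#'
#' Mean negative log-probability of the true class over all pixels; the
#' conventional baseline objective for the ablation comparisons. Note that
#' the plain (soft) Dice loss is the `beta = 0.5`, `gamma = 1`,
#' `lambdaSmooth = 0` configuration of the composite objective.
#'
#' @param probs `(H, W, K)` softmax class probabilities.
#' @param labels `(H, W)` integer label map over `0..K-1`.
#' @param epsilon floor applied inside the log (default 1e-12).
#' @return mean cross-entropy, `>= 0`.
#' @export
crossEntropyLoss <- function(probs, labels, epsilon = 1e-12) {
  d <- dim(probs)
  if (!identical(d[1:2], dim(labels)))
    stop("shape mismatch between prediction and truth", call. = FALSE)
  pm <- probs
  dim(pm) <- c(d[1] * d[2], d[3])
  idx <- cbind(seq_len(d[1] * d[2]), as.integer(labels) + 1L)
  -mean(log(pmax(pm[idx], epsilon)))
}

# ---- training-facing loss with analytic gradient ---------------------------

# Value and d(loss)/d(probs) of the composite loss for a 3-class softmax
# output. probs: (H, W, K); labels: (H, W) over 0..K-1. One-vs-rest per
# foreground class, equal class weights; the boundary term uses forward
# differences (the training default).
segmentationLoss <- function(probs, labels, config = lossConfig()) {
  K <- dim(probs)[3]
  nFg <- K - 1L
  grad <- array(0, dim(probs))
  ftTotal <- 0
  smTotal <- 0
  for (cls in seq_len(nFg)) {
    Xc <- probs[, , cls + 1L]
    Yc <- (labels == cls) * 1
    tp <- sum(Xc * Yc)
    if (config@variant == "printed") {
      N <- tp + config@epsilon
      D <- config@beta * sum(Xc) + (1 - config@beta) * sum(Yc) + config@epsilon
      dTdX <- (Yc * D - N * config@beta) / D^2
    } else {
      fn <- sum((1 - Xc) * Yc)
      fp <- sum(Xc * (1 - Yc))
      N <- tp + config@epsilon
      D <- tp + config@beta * fn + (1 - config@beta) * fp + config@epsilon
      dD <- Yc - config@beta * Yc + (1 - config@beta) * (1 - Yc)
      dTdX <- (Yc * D - N * dD) / D^2
    }
    t <- N / D
    ftTotal <- ftTotal + config@alpha * (1 - t)^config@gamma
    dLdT <- -config@alpha * config@gamma * (1 - t)^(config@gamma - 1)
    gradC <- dLdT * dTdX / nFg
    if (config@lambdaSmooth > 0) {
      ny <- nrow(Xc); nx <- ncol(Xc)
      gxP <- Xc[, c(seq_len(nx)[-1], nx)] - Xc
      gyP <- Xc[c(seq_len(ny)[-1], ny), ] - Xc
      magP <- sqrt(gxP^2 + gyP^2)
      magT <- gradMagnitude(Yc, "forward")
      r <- magP - magT
      smTotal <- smTotal + sum(r^2)
      safe <- ifelse(magP > 0, 1 / magP, 0)
      coef <- 2 * (config@lambdaSmooth / nFg) * r * safe
      dgx <- coef * gxP
      dgy <- coef * gyP
      dgx[, nx] <- 0                    # replicated edge: gradient is zero
      dgy[ny, ] <- 0
      dX <- -dgx - dgy
      dX[, -1] <- dX[, -1] + dgx[, -nx]
      dX[-1, ] <- dX[-1, ] + dgy[-ny, ]
      gradC <- gradC + dX
    }
    grad[, , cls + 1L] <- gradC
  }
  value <- ftTotal / nFg + config@lambdaSmooth * smTotal / nFg
  list(value = value, focalTversky = ftTotal / nFg,
       smooth = config@lambdaSmooth * smTotal / nFg, grad = grad)
}
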