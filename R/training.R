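#' Deterministically split sample ids into train/validation/test sets
#'
#' Ids are shuffled under `seed`, `testCount` ids are withheld for the test
#' set first, and the remainder is split `ratio[1]:ratio[2]` with rounding
#' toward the training set. The three sets are disjoint and jointly cover the
#' input.
#'
#' @param ids vector of sample identifiers (length >= `testCount + 9` for the
#'   default 8:1 ratio).
#' @param ratio train:validation ratio (default `c(8, 1)`).
#' @param testCount ids withheld as the test set (default 0).
#' @param seed shuffle seed (default 1).
#' @return list of class `DatasetSplit` with `train`, `val`, `test`.
#' @examples
#' s <- splitDataset(1:90)   # 80 train, 10 val
#' lengths(s)
#' @export
splitDataset <- function(ids, ratio = c(8, 1), testCount = 0, seed = 1) {
  n <- length(ids)
  need <- testCount + sum(ratio) / min(ratio)
  if (n < testCount + ceiling(sum(ratio) / max(1, min(ratio))))
    paramError("too few ids (%d) for testCount %d and ratio %g:%g",
               n, testCount, ratio[1], ratio[2])
  shuffled <- withSeed(seed, ids[sample.int(n)])
  test <- if (testCount > 0) shuffled[seq_len(testCount)] else ids[0]
  rest <- if (testCount > 0) shuffled[-seq_len(testCount)] else shuffled
  nVal <- floor(length(rest) * ratio[2] / sum(ratio))
  val <- if (nVal > 0) rest[seq_len(nVal)] else ids[0]
  train <- if (nVal > 0) rest[-seq_len(nVal)] else rest
  structure(list(train = train, val = val, test = test), class = "DatasetSplit")
}

# RMSprop with the usual framework defaults: smoothing 0.99, eps 1e-8, no
# momentum.
rmspropStep <- function(params, grads, sq, lr, alpha = 0.99, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- sq[[nm]]
    if (is.null(s)) s <- g * 0
    s <- alpha * s + (1 - alpha) * g^2
    sq[[nm]] <- s
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(s) + eps)
  }
  list(params = params, sq = sq)
}

# random flip / 90-degree rotation of a paired image+label sample
augmentSample <- function(image, label) {
  k <- sample.int(4L, 1L) - 1L
  if (k > 0) for (i in seq_len(k)) {
    image <- t(image[nrow(image):1, , drop = FALSE])
    label <- t(label[nrow(label):1, , drop = FALSE])
  }
  if (sample.int(2L, 1L) == 2L) { image <- image[nrow(image):1, ]; label <- label[nrow(label):1, ] }
  if (sample.int(2L, 1L) == 2L) { image <- image[, ncol(image):1]; label <- label[, ncol(label):1] }
  list(image = image, label = label)
}

# mean foreground Dice of a model over a list of (image, label) samples
meanValDice <- function(model, samples) {
  mean(vapply(samples, function(s) {
    logits <- modelForward(model, s$image)
    d <- dim(logits)
    pred <- matrix(max.col(matrix(logits, d[1] * d[2], d[3]),
                           ties.method = "first") - 1L, d[1], d[2])
    m <- multiclassMetrics(pred, s$label)
    m$dice[m$class == "mean_foreground"]
  }, numeric(1)))
}

#' Train the segmentation model
#'
#' Runs the RMSprop training loop with the composite focal-Tversky plus
#' boundary-smoothing objective over per-image steps, recording per-epoch
#' mean training loss and validation mean foreground Dice, and keeping the
#' parameters of the best-validation epoch. Fully reproducible under
#' `config@seed`.
#'
#' @param model a `csftuNet` from [buildModel()].
#' @param datasets list with `train` (non-empty) and optionally `val`; each
#'   sample is a list with `image` (`H x W` matrix in `[0, 1]`) and `label`
#'   (`H x W` integer matrix over `{0, 1, 2}`), as produced by
#'   [makeTrainingSet()].
#' @param config a [TrainConfig-class].
#' @param loss a [LossConfig-class].
#' @param checkpointPath optional RDS path for the best-validation model.
#' @param verbose print one line per epoch (default FALSE).
#' @return list with `model` (best-validation parameters, or final if no
#'   validation set), `finalModel`, `history` (data.frame epoch/trainLoss/
#'   valDice/lr) and `bestEpoch`.
#' @export
trainModel <- function(model, datasets, config = trainConfig(),
                       loss = lossConfig(), checkpointPath = NULL,
                       verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"), is(loss, "LossConfig"))
  trainSet <- datasets$train
  valSet <- datasets$val
  if (is.null(trainSet) || length(trainSet) == 0)
    paramError("empty training set")
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valDice = numeric(0), lr = numeric(0))
  best <- list(dice = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  sq <- list()
  lr <- config@lrInit
  sinceBest <- 0L
  withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      if (config@lrSchedule == "cosine")
        lr <- config@lrMin + 0.5 * (config@lrInit - config@lrMin) *
          (1 + cos(pi * (epoch - 1) / max(1, config@epochs - 1)))
      ord <- sample.int(length(trainSet))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        s <- trainSet[[ord[i]]]
        if (config@augment) s <- augmentSample(s$image, s$label)
        x <- array(s$image, c(dim(s$image), 1L))
        fw <- netForward(model, x, training = TRUE)
        model$state <- fw$state
        probs <- softmaxProbs(fw$logits)
        sl <- segmentationLoss(probs, s$label, loss)
        if (!is.finite(sl$value))
          stop(sprintf(
            "non-finite loss (%g) at epoch %d, sample %d; aborting training",
            sl$value, epoch, ord[i]), call. = FALSE)
        losses[i] <- sl$value
        dlogits <- softmaxBackward(sl$grad, probs)
        grads <- netBackward(model, fw$cache, dlogits)
        upd <- rmspropStep(model$params, grads, sq, lr)
        model$params <- upd$params
        sq <- upd$sq
      }
      valDice <- if (length(valSet)) meanValDice(model, valSet) else NA_real_
      history[epoch, ] <- list(epoch, mean(losses), valDice, lr)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f, val Dice %s, lr %g",
                        epoch, mean(losses),
                        if (is.na(valDice)) "-" else sprintf("%.4f", valDice), lr))
      improved <- if (length(valSet)) valDice > best$dice else TRUE
      if (improved) {
        best <- list(dice = if (length(valSet)) valDice else -Inf,
                     params = model$params, state = model$state, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (config@lrSchedule == "plateau" && sinceBest >= config@plateauPatience) {
          lr <- max(lr * 0.5, config@lrMin)
          sinceBest <- 0L
        }
      }
    }
  })
  bestModel <- model
  bestModel$params <- best$params
  bestModel$state <- best$state
  if (!is.null(checkpointPath))
    saveRDS(list(model = bestModel, config = config, loss = loss,
                 history = history), checkpointPath)
  list(model = bestModel, finalModel = model, history = history,
       bestEpoch = best$epoch)
}

#' Evaluate a model on a test set
#'
#' Per-sample, per-foreground-class Dice and IoU, plus their means.
#'
#' @param model a `csftuNet`.
#' @param testSet non-empty list of samples (`image`, `label`).
#' @param path optional path; `.csv` writes the per-sample table, `.json`
#'   writes both tables.
#' @return list with `perSample` (data.frame sample/class/dice/iou) and
#'   `summary` (per-class and mean-foreground means over samples).
#' @export
evaluateModel <- function(model, testSet, path = NULL) {
  if (length(testSet) == 0) paramError("empty test set")
  rows <- lapply(seq_along(testSet), function(i) {
    s <- testSet[[i]]
    logits <- modelForward(model, s$image)
    d <- dim(logits)
    pred <- matrix(max.col(matrix(logits, d[1] * d[2], d[3]),
                           ties.method = "first") - 1L, d[1], d[2])
    m <- multiclassMetrics(pred, s$label)
    cbind(sample = i, m)
  })
  perSample <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(perSample, perSample$class), function(g)
    data.frame(class = g$class[1], dice = mean(g$dice), iou = mean(g$iou))))
  rownames(summary) <- NULL
  out <- list(perSample = perSample, summary = summary)
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    else write.csv(perSample, path, row.names = FALSE)
  }
  out
}
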