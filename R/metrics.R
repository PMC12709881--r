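#' Dice coefficient between two hard masks
#'
#' `Dice = 2 |X intersect Y| / (|X| + |Y|)`. Two empty masks agree perfectly
#' and score 1. Related to IoU by `Dice = 2 IoU / (1 + IoU)`.
#'
#' @param X,Y hard 0/1 masks (vectors, matrices or arrays) of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' diceScore(c(1, 1, 1, 1, 0), c(1, 1, 0, 0, 1))  # 2*2 / (4+3)
#' @export
diceScore <- function(X, Y) {
  checkSameShape(X, Y)
  inter <- sum(X * Y)
  denom <- sum(X) + sum(Y)
  if (denom == 0) return(1)
  2 * inter / denom
}

#' Intersection over union between two hard masks
#'
#' `IoU = |X intersect Y| / |X union Y|`; two empty masks score 1.
#'
#' @inheritParams diceScore
#' @return IoU in `[0, 1]`.
#' @export
iouScore <- function(X, Y) {
  checkSameShape(X, Y)
  inter <- sum(X * Y)
  uni <- sum(pmax(X, Y))
  if (uni == 0) return(1)
  inter / uni
}

#' Per-class Dice and IoU for multi-class label maps
#'
#' Compares two integer label maps (or [LabelVolume-class] objects) class by
#' class and reports per-class Dice/IoU plus the foreground means (background
#' class 0 excluded from the means).
#'
#' @param pred,truth integer label maps over `0..max(classes)`, same shape,
#'   or [LabelVolume-class] objects.
#' @param classes foreground class codes (default `c(1, 2)`: starchy,
#'   vitreous).
#' @return data.frame with columns `class`, `dice`, `iou`; the last row
#'   (`class = "mean_foreground"`) carries the foreground means.
#' @export
multiclassMetrics <- function(pred, truth, classes = c(1, 2)) {
  if (is(pred, "LabelVolume")) pred <- voxelData(pred)
  if (is(truth, "LabelVolume")) truth <- voxelData(truth)
  checkSameShape(pred, truth)
  rows <- lapply(classes, function(cls) {
    data.frame(class = as.character(cls),
               dice = diceScore((pred == cls) * 1, (truth == cls) * 1),
               iou = iouScore((pred == cls) * 1, (truth == cls) * 1))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = "mean_foreground",
                        dice = mean(out$dice), iou = mean(out$iou)))
}
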