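#' Network architecture configuration
#'
#' Hyperparameters of the attention U-Net. With `levels = 5` the encoder
#' performs four 2x2 max-pool downsamplings; channel counts per level default
#' to the canonical doubling rule starting at `baseFilters` and may be capped
#' at 512 with `capFilters`.
#'
#' @slot levels number of resolution levels (>= 2; default 5).
#' @slot baseFilters channels at the first level (default 64).
#' @slot filtersPerLevel integer vector of channel counts, one per level.
#' @slot cbamReduction channel-MLP reduction ratio `r` of the CBAM block (16).
#' @slot seReduction reduction ratio `r` of the squeeze-excitation block (16).
#' @slot spatialKernel CBAM spatial-attention convolution size (odd; 7).
#' @slot numClasses output classes (3: background, starchy, vitreous).
#' @slot inChannels input channels (1, grayscale).
#' @slot useCBAM apply CBAM before each encoder max-pool (ablation switch).
#' @slot useSE apply SE after each decoder conv pair (ablation switch).
#' @slot cbamAtBottleneck also apply CBAM at the bottleneck (default FALSE).
#' @slot upsampleMode `"transposed"` (learned 2x2 deconvolution) or `"bilinear"`.
#' @export
setClass("NetworkConfig",
  representation(levels = "integer", baseFilters = "integer",
                 filtersPerLevel = "integer", cbamReduction = "integer",
                 seReduction = "integer", spatialKernel = "integer",
                 numClasses = "integer", inChannels = "integer",
                 useCBAM = "logical", useSE = "logical",
                 cbamAtBottleneck = "logical", upsampleMode = "character"))

setValidity("NetworkConfig", function(object) {
  if (object@levels < 2L) return("levels must be >= 2")
  if (length(object@filtersPerLevel) != object@levels)
    return("filtersPerLevel must have one entry per level")
  if (any(object@filtersPerLevel < 1L)) return("filter counts must be positive")
  if (object@spatialKernel %% 2L == 0L) return("spatialKernel must be odd")
  if (!object@upsampleMode %in% c("transposed", "bilinear"))
    return("upsampleMode must be 'transposed' or 'bilinear'")
  # reduction ratios must divide the channel counts they gate
  if (object@useCBAM && any(object@filtersPerLevel %% object@cbamReduction != 0L))
    return("cbamReduction must divide every encoder channel count")
  if (object@useSE &&
      any(object@filtersPerLevel[-object@levels] %% object@seReduction != 0L))
    return("seReduction must divide every decoder channel count")
  TRUE
})

#' Build a NetworkConfig
#'
#' @param levels resolution levels (default 5, i.e. four downsamplings).
#' @param baseFilters channels at level 1 (default 64).
#' @param capFilters if `TRUE`, cap the doubling rule at 512 channels.
#' @param cbamReduction,seReduction attention reduction ratios (default 16).
#' @param spatialKernel CBAM spatial convolution size (default 7).
#' @param numClasses segmentation classes (default 3).
#' @param inChannels input image channels (default 1).
#' @param useCBAM,useSE ablation switches (default `TRUE`).
#' @param cbamAtBottleneck apply CBAM at the bottleneck too (default `FALSE`).
#' @param upsampleMode `"transposed"` or `"bilinear"`.
#' @param filtersPerLevel optional explicit channel counts (overrides the rule).
#' @return a [NetworkConfig-class] object.
#' @examples
#' networkConfig(levels = 3, baseFilters = 16)
#' @export
networkConfig <- function(levels = 5, baseFilters = 64, capFilters = FALSE,
                          cbamReduction = 16, seReduction = 16,
                          spatialKernel = 7, numClasses = 3, inChannels = 1,
                          useCBAM = TRUE, useSE = TRUE,
                          cbamAtBottleneck = FALSE,
                          upsampleMode = c("transposed", "bilinear"),
                          filtersPerLevel = NULL) {
  upsampleMode <- match.arg(upsampleMode)
  if (is.null(filtersPerLevel)) {
    filtersPerLevel <- baseFilters * 2^(seq_len(levels) - 1)
    if (capFilters) filtersPerLevel <- pmin(filtersPerLevel, 512)
  }
  new("NetworkConfig", levels = as.integer(levels),
      baseFilters = as.integer(baseFilters),
      filtersPerLevel = as.integer(filtersPerLevel),
      cbamReduction = as.integer(cbamReduction),
      seReduction = as.integer(seReduction),
      spatialKernel = as.integer(spatialKernel),
      numClasses = as.integer(numClasses), inChannels = as.integer(inChannels),
      useCBAM = isTRUE(useCBAM), useSE = isTRUE(useSE),
      cbamAtBottleneck = isTRUE(cbamAtBottleneck), upsampleMode = upsampleMode)
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: %d levels, filters (%s)\n", object@levels,
              paste(object@filtersPerLevel, collapse = ", ")))
  cat(sprintf("  CBAM %s (r=%d, %dx%d) | SE %s (r=%d) | upsample %s | %d classes\n",
              if (object@useCBAM) "on" else "off", object@cbamReduction,
              object@spatialKernel, object@spatialKernel,
              if (object@useSE) "on" else "off", object@seReduction,
              object@upsampleMode, object@numClasses))
})

#' Loss configuration for the composite training objective
#'
#' Fully determines the total loss: the focal Tversky term
#' `alpha * (1 - T)^gamma` per foreground class, plus a boundary-smoothing
#' term `lambda * sum((|grad pred| - |grad true|)^2)`.
#'
#' @slot alpha positive scale of the focal Tversky term (default 1).
#' @slot beta false-negative/false-positive balance in `[0, 1]` (default 0.75).
#' @slot gamma focusing exponent, > 0 (default 2).
#' @slot lambdaSmooth weight of the boundary-smoothing term, >= 0 (default 0.001).
#' @slot epsilon stabilising constant in the Tversky ratio (default 1e-6).
#' @slot variant `"printed"` Tversky denominator `beta|X| + (1-beta)|Y|` or the
#'   `"standard"` `TP + beta*FN + (1-beta)*FP` form (identical on hard masks up
#'   to the role assignment of beta).
#' @slot gradientOp `"forward"` first differences or `"sobel"` for the
#'   boundary term's image gradient.
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 lambdaSmooth = "numeric", epsilon = "numeric",
                 variant = "character", gradientOp = "character"))

setValidity("LossConfig", function(object) {
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@beta < 0 || object@beta > 1) return("beta must lie in [0, 1]")
  if (object@gamma <= 0) return("gamma must be > 0")
  if (object@lambdaSmooth < 0) return("lambdaSmooth must be >= 0")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  if (!object@variant %in% c("printed", "standard"))
    return("variant must be 'printed' or 'standard'")
  if (!object@gradientOp %in% c("forward", "sobel"))
    return("gradientOp must be 'forward' or 'sobel'")
  TRUE
})

#' Build a LossConfig
#'
#' @param alpha scale of the focal Tversky term (default 1.0).
#' @param beta Tversky balance parameter (default 0.75).
#' @param gamma focusing exponent (default 2.0).
#' @param lambdaSmooth boundary-term weight (default 0.001; 0 disables it). The
#'   term is an unnormalised sum over pixels whose raw magnitude scales with
#'   the class-boundary perimeter (hundreds at 128--256 pixel slices) while
#'   the focal Tversky term stays in \[0, alpha\]; the default keeps the
#'   boundary term active without letting it dominate the overlap objective.
#' @param epsilon Tversky ratio stabiliser (default 1e-6).
#' @param variant Tversky denominator form, `"printed"` (default) or `"standard"`.
#' @param gradientOp boundary gradient operator, `"forward"` (default) or `"sobel"`.
#' @return a [LossConfig-class] object.
#' @examples
#' lossConfig(beta = 0.75, gamma = 2)
#' @export
lossConfig <- function(alpha = 1.0, beta = 0.75, gamma = 2.0,
                       lambdaSmooth = 0.001, epsilon = 1e-6,
                       variant = c("printed", "standard"),
                       gradientOp = c("forward", "sobel")) {
  new("LossConfig", alpha = alpha, beta = beta, gamma = gamma,
      lambdaSmooth = lambdaSmooth, epsilon = epsilon,
      variant = match.arg(variant), gradientOp = match.arg(gradientOp))
}

setMethod("show", "LossConfig", function(object) {
  cat(sprintf(
    "LossConfig: alpha=%g beta=%g gamma=%g lambda=%g eps=%g (%s Tversky, %s gradient)\n",
    object@alpha, object@beta, object@gamma, object@lambdaSmooth,
    object@epsilon, object@variant, object@gradientOp))
})

#' Training configuration
#'
#' Defaults follow the segmentation protocol: RMSprop, batch size 1, initial
#' learning rate 1e-4 decaying no lower than 1e-5, 50 epochs, train:validation
#' split 8:1.
#'
#' @slot epochs training epochs (default 50).
#' @slot batchSize images per optimisation step (default 1).
#' @slot lrInit initial learning rate (default 1e-4).
#' @slot lrMin learning-rate floor (default 1e-5).
#' @slot lrSchedule `"plateau"` (halve on validation plateau) or `"cosine"`.
#' @slot plateauPatience epochs without improvement before halving (default 5).
#' @slot seed RNG seed controlling init, shuffling and augmentation.
#' @slot augment enable flip/rotation augmentation (default FALSE).
#' @slot splitRatio train:validation ratio as `c(train, val)` (default 8:1).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer", lrInit = "numeric",
                 lrMin = "numeric", lrSchedule = "character",
                 plateauPatience = "integer", seed = "integer",
                 augment = "logical", splitRatio = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!(object@lrMin > 0 && object@lrMin <= object@lrInit))
    return("need 0 < lrMin <= lrInit")
  if (!object@lrSchedule %in% c("plateau", "cosine"))
    return("lrSchedule must be 'plateau' or 'cosine'")
  if (length(object@splitRatio) != 2L || any(object@splitRatio <= 0))
    return("splitRatio must be two positive numbers")
  TRUE
})

#' Build a TrainConfig
#'
#' @param epochs number of epochs (default 50).
#' @param batchSize images per step (default 1).
#' @param lrInit initial learning rate (default 1e-4).
#' @param lrMin minimum learning rate (default 1e-5).
#' @param lrSchedule `"plateau"` (default) or `"cosine"`.
#' @param plateauPatience plateau patience in epochs (default 5).
#' @param seed RNG seed (default 1).
#' @param augment logical, flip/90-degree-rotation augmentation (default FALSE).
#' @param splitRatio train:validation ratio (default `c(8, 1)`).
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 50, batchSize = 1, lrInit = 1e-4, lrMin = 1e-5,
                        lrSchedule = c("plateau", "cosine"), plateauPatience = 5,
                        seed = 1, augment = FALSE, splitRatio = c(8, 1)) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lrInit = lrInit, lrMin = lrMin, lrSchedule = match.arg(lrSchedule),
      plateauPatience = as.integer(plateauPatience), seed = as.integer(seed),
      augment = isTRUE(augment), splitRatio = as.numeric(splitRatio))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs, batch %d, RMSprop lr %g -> %g (%s), seed %d, augment %s\n",
    object@epochs, object@batchSize, object@lrInit, object@lrMin,
    object@lrSchedule, object@seed, if (object@augment) "on" else "off"))
})
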