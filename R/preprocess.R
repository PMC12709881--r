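#' Clamp pixel intensities to a closed range
#'
#' Pixel truncation: values below `minVal` are set to `minVal`, values above
#' `maxVal` to `maxVal`, everything else passes through unchanged. Idempotent;
#' shape-preserving; works on arrays of any dimensionality. With the 8-bit
#' defaults `(0, 255)` it is the identity on in-range data.
#'
#' @param image numeric array or matrix of intensities.
#' @param minVal,maxVal clamp bounds (defaults 0 and 255); `minVal <= maxVal`.
#' @return the clamped array, same shape as the input.
#' @examples
#' clampPixels(c(-7, 128, 300))   # 0 128 255
#' @export
clampPixels <- function(image, minVal = 0, maxVal = 255) {
  if (minVal > maxVal)
    paramError("minVal (%g) must not exceed maxVal (%g)", minVal, maxVal)
  out <- pmin(pmax(image, minVal), maxVal)
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

#' Enhance the contrast of an 8-bit grayscale image
#'
#' The default method is a percentile linear stretch: intensities between the
#' `pLow` and `pHigh` percentiles are mapped linearly onto 0--255 and clipped;
#' this mapping is monotone non-decreasing, and a constant image is returned
#' unchanged. `"clahe"` selects contrast-limited adaptive histogram
#' equalisation (EBImage).
#'
#' @param image numeric matrix or array on the 0--255 scale.
#' @param method `"stretch"` (default) or `"clahe"`.
#' @param pLow,pHigh stretch percentiles (defaults 1 and 99).
#' @param ... further arguments passed to [EBImage::clahe()].
#' @return enhanced image on the 0--255 scale, same shape.
#' @export
enhanceContrast <- function(image, method = c("stretch", "clahe"),
                            pLow = 1, pHigh = 99, ...) {
  method <- match.arg(method)
  if (method == "stretch") {
    q <- quantile(image, c(pLow, pHigh) / 100, names = FALSE)
    if (q[2] <= q[1]) return(image)          # no contrast to stretch
    out <- (image - q[1]) / (q[2] - q[1]) * 255
    out <- pmin(pmax(out, 0), 255)
    if (!is.null(dim(image))) dim(out) <- dim(image)
    out
  } else {
    if (is.matrix(image)) return(as.matrix(EBImage::clahe(image / 255, ...)) * 255)
    out <- image
    for (z in seq_len(dim(image)[1]))
      out[z, , ] <- as.matrix(EBImage::clahe(image[z, , ] / 255, ...)) * 255
    out
  }
}

#' Remap raw label values onto the {0, 1, 2} class codes
#'
#' Replaces every value of a raw annotation image according to `mapping`
#' (e.g. starchy-endosperm annotations exported at 255 are truncated to class
#' 1, vitreous at 128 to class 2). Every value present in the image must be
#' covered by the mapping and every target must lie in `{0, 1, 2}`; per-class
#' pixel counts are preserved exactly.
#'
#' @param rawLabelImage numeric array of raw annotation values.
#' @param mapping named vector or list: names are raw values, entries the
#'   target class codes. Default `c("0" = 0, "255" = 1, "128" = 2)`.
#' @return integer array over `{0, 1, 2}`, same shape as the input.
#' @examples
#' remapLabels(matrix(c(0, 255, 128, 0), 2), c("0" = 0, "255" = 1, "128" = 2))
#' @export
remapLabels <- function(rawLabelImage, mapping = c("0" = 0, "255" = 1, "128" = 2)) {
  mapping <- unlist(mapping)
  from <- as.numeric(names(mapping))
  to <- as.integer(mapping)
  if (anyNA(from)) paramError("mapping names must be numeric raw values")
  if (!all(to %in% 0:2))
    paramError("mapping targets must lie in {0, 1, 2}; got %s",
               paste(unique(to[!to %in% 0:2]), collapse = ", "))
  vals <- unique(as.vector(rawLabelImage))
  unmapped <- setdiff(vals, from)
  if (length(unmapped))
    paramError("unmapped label value(s): %s", paste(sort(unmapped), collapse = ", "))
  out <- to[match(rawLabelImage, from)]
  dim(out) <- dim(rawLabelImage)
  if (is.null(dim(out))) out <- as.integer(out)
  out
}

#' Exhaustive Otsu threshold on the 0--255 scale
#'
#' Maximises the between-class intensity variance over all 255 possible cut
#' points of the 8-bit histogram; ties are broken toward the lower threshold.
#'
#' @param values numeric vector/array of intensities on 0--255 (rounded to
#'   integer bins internally).
#' @return the cut point `t`: the lower class is `values <= t`, the upper
#'   class `values > t`.
#' @export
otsuThreshold <- function(values) {
  v <- pmin(pmax(round(as.vector(values)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  if (n == 0) paramError("cannot threshold an empty set of values")
  p <- h / n
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * levels)
  muT <- mu[256]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid))
    paramError("cannot separate classes: degenerate single-mode histogram")
  between <- rep(-Inf, 255)
  between[valid] <- (muT * w0[valid] - mu[1:255][valid])^2 / (w0[valid] * w1[valid])
  which.max(between) - 1L   # which.max takes the first (lowest) maximiser
}

#' Canny edge detection on a single slice
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and hysteresis (weak edges are kept only in
#' connected components containing a strong edge). By default the high
#' threshold is the Otsu threshold of the slice intensities and the low
#' threshold is half of it, giving a parameter-free operating point for
#' bright-object scenes.
#'
#' @param image numeric matrix (y, x) on the 0--255 scale.
#' @param sigma Gaussian smoothing in pixels (default 1.4).
#' @param high,low hysteresis thresholds on the Sobel gradient magnitude;
#'   defaults `high = otsuThreshold(image)`, `low = 0.5 * high`.
#' @return logical matrix of edge pixels.
#' @export
cannyEdges <- function(image, sigma = 1.4, high = NULL, low = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(high)) high <- otsuThreshold(image)
  if (is.null(low)) low <- 0.5 * high
  g <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
  # Sobel in matrix coordinates: rows = y, cols = x
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (columns)
  ky <- t(kx)                                                # d/dy (rows)
  gx <- as.matrix(EBImage::filter2(g, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(g, ky, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  # quantise gradient direction to 0/45/90/135 degrees
  theta <- atan2(gy, gx) * 180 / pi
  theta[theta < 0] <- theta[theta < 0] + 180
  bin <- ifelse(theta < 22.5 | theta >= 157.5, 0L,
         ifelse(theta < 67.5, 45L, ifelse(theta < 112.5, 90L, 135L)))
  ny <- nrow(mag); nx <- ncol(mag)
  shift <- function(m, dy, dx) {             # neighbour value, -Inf off-grid
    out <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  # neighbour offsets along the gradient direction (dy, dx)
  nbr <- list(`0` = c(0, 1), `45` = c(1, 1), `90` = c(1, 0), `135` = c(1, -1))
  keep <- matrix(FALSE, ny, nx)
  for (b in names(nbr)) {
    d <- nbr[[b]]
    sel <- bin == as.integer(b)
    ge <- mag >= shift(mag, d[1], d[2]) & mag >= shift(mag, -d[1], -d[2])
    keep[sel & ge] <- TRUE
  }
  thin <- mag * keep
  strong <- thin >= high
  weak <- thin >= low
  if (!any(strong)) return(strong)
  comp <- EBImage::bwlabel(matrix(as.numeric(weak), ny, nx))
  comp <- matrix(as.integer(comp), ny, nx)
  good <- unique(comp[strong])
  weak & (comp %in% good[good > 0])
}

#' A single-kernel crop extracted from a batch scan
#'
#' @slot image sub-array `(z, y, x)` around one kernel.
#' @slot bbox 0-based half-open index ranges `(z0, z1, y0, y1, x0, x1)` into
#'   the source volume.
#' @slot kernelIndex ordinal of the kernel within the scene (1 = leftmost).
#' @export
setClass("KernelCrop",
  representation(image = "array", bbox = "integer", kernelIndex = "integer"))

setValidity("KernelCrop", function(object) {
  b <- object@bbox
  if (length(b) != 6L) return("bbox must be (z0, z1, y0, y1, x0, x1)")
  if (any(b[c(2, 4, 6)] <= b[c(1, 3, 5)])) return("bbox ranges must be non-empty")
  if (any(b < 0L)) return("bbox indices must be >= 0 (0-based, half-open)")
  if (object@kernelIndex < 0L) return("kernelIndex must be >= 0")
  d <- dim(object@image)
  if (!all(d == b[c(2, 4, 6)] - b[c(1, 3, 5)]))
    return("image extent does not match bbox")
  TRUE
})

setMethod("show", "KernelCrop", function(object) {
  b <- object@bbox
  cat(sprintf("KernelCrop %d: z [%d,%d) y [%d,%d) x [%d,%d)\n",
              object@kernelIndex, b[1], b[2], b[3], b[4], b[5], b[6]))
})

#' Split a batch scan into single-kernel crops
#'
#' Per-slice Canny edges are morphologically closed and hole-filled, the
#' filled masks are stacked and labelled as 26-connected 3D components,
#' components below the minimum-size filter are discarded, the largest
#' `expectedKernels` are kept, and one padded crop is cut per component. Crops
#' are returned left to right (increasing centroid x).
#'
#' @param volume a [CTVolume-class] batch scan: bright kernels on a darker
#'   background.
#' @param expectedKernels number of kernels in the scene (>= 1; a typical
#'   batch scan holds 3).
#' @param minSizeFrac minimum component size as a fraction of the volume's
#'   voxel count (default 0.001).
#' @param marginFrac bounding-box padding as a fraction of the box's longer
#'   side (default 0.05), clipped at the volume edges.
#' @param sigma Canny smoothing (default 1.4).
#' @return list of `expectedKernels` [KernelCrop-class] objects.
#' @export
splitBatchScan <- function(volume, expectedKernels, minSizeFrac = 0.001,
                           marginFrac = 0.05, sigma = 1.4) {
  stopifnot(is(volume, "CTVolume"))
  if (expectedKernels < 1) paramError("expectedKernels must be >= 1")
  dat <- voxelData(volume)
  d <- dim(dat)
  filled <- array(FALSE, d)
  brush <- EBImage::makeBrush(5, "disc")
  for (z in seq_len(d[1])) {
    sl <- matrix(dat[z, , ], d[2], d[3])
    if (max(sl) == min(sl)) next               # blank slice: no edges
    edges <- cannyEdges(sl, sigma = sigma)
    closed <- EBImage::closing(matrix(as.numeric(edges), d[2], d[3]), brush)
    filled[z, , ] <- as.matrix(EBImage::fillHull(closed)) > 0
  }
  labs <- labelComponents3d(filled)
  nComp <- max(labs)
  minSize <- minSizeFrac * prod(d)
  sizes <- if (nComp > 0) tabulate(labs[labs > 0L], nbins = nComp) else integer(0)
  keep <- which(sizes >= minSize)
  if (length(keep) < expectedKernels)
    stop(sprintf("expected %d kernels but found %d components above the size filter",
                 expectedKernels, length(keep)), call. = FALSE)
  keep <- keep[seq_len(expectedKernels)]       # labels already size-ordered
  cx <- vapply(keep, function(i) centroid3d(labs == i)[3], numeric(1))
  keep <- keep[order(cx)]
  lapply(seq_along(keep), function(i) {
    comp <- labs == keep[i]
    b <- bbox3d(comp)
    margin <- ceiling(marginFrac * max(b[c(2, 4, 6)] - b[c(1, 3, 5)]))
    lo <- pmax(b[c(1, 3, 5)] - margin, 0L)
    hi <- pmin(b[c(2, 4, 6)] + margin, d)
    img <- dat[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3], drop = FALSE]
    new("KernelCrop", image = img,
        bbox = as.integer(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])),
        kernelIndex = i)
  })
}

#' Standardise a kernel crop for the segmentation model
#'
#' Aspect-preserving resize of each slice so its longer side equals `side`,
#' centred zero-padding to `side x side`, and intensity rescaling to `[0, 1]`.
#'
#' @param crop a [KernelCrop-class], 3D array, or single-slice matrix, on the
#'   0--255 scale.
#' @param side output side length in pixels (default 256).
#' @return array `(z, side, side)` in `[0, 1]` (a matrix input yields z = 1).
#' @export
standardizeForModel <- function(crop, side = 256) {
  img <- if (is(crop, "KernelCrop")) crop@image else crop
  if (is.matrix(img)) img <- array(img, c(1L, dim(img)))
  d <- dim(img)
  if (any(d == 0L)) paramError("empty crop")
  scale <- side / max(d[2], d[3])
  newY <- max(1L, round(d[2] * scale))
  newX <- max(1L, round(d[3] * scale))
  if (newY > side) newY <- side
  if (newX > side) newX <- side
  y0 <- (side - newY) %/% 2L
  x0 <- (side - newX) %/% 2L
  out <- array(0, c(d[1], side, side))
  for (z in seq_len(d[1])) {
    sl <- matrix(img[z, , ], d[2], d[3])
    rs <- if (newY == d[2] && newX == d[3]) sl else
      as.matrix(EBImage::resize(sl, w = newY, h = newX))
    out[z, y0 + seq_len(newY), x0 + seq_len(newX)] <- rs
  }
  pmin(pmax(out / 255, 0), 1)
}
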