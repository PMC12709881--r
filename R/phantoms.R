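#' Synthetic kernel phantom specification
#'
#' Geometry and imaging parameters of a nested-ellipsoid maize-kernel phantom:
#' a bright pericarp rim enclosing a vitreous shell (label 2) around a starchy
#' core (label 1). With normalised ellipsoidal radius `rho` (1 at the seed
#' surface), the starchy core occupies `rho <= coreFraction`, the vitreous
#' shell `coreFraction < rho <= shellFraction`, and the pericarp the remaining
#' `shellFraction < rho <= 1`. The rendered image adds Gaussian boundary blur
#' and additive Gaussian noise, emulating the low class contrast and blurred
#' endosperm boundaries of real kernel CT; the labels stay crisp (pre-blur).
#'
#' @slot shape voxel extents `(z, y, x)`.
#' @slot semiAxesUm outer seed semi-axes `(z, y, x)` in micrometres.
#' @slot shellFraction radial fraction where the vitreous shell ends (pericarp
#'   begins); default 0.85.
#' @slot coreFraction radial fraction of the starchy core; default 0.55.
#' @slot intensityBg,intensityStarchy,intensityVitreous,intensityPericarp mean
#'   8-bit intensities per region (defaults 20, 150, 180, 220).
#' @slot noiseSd additive Gaussian noise standard deviation (default 6).
#' @slot blurSigma boundary blur in voxels (default 1).
#' @slot seed RNG seed of the noise draw.
#' @slot voxelEdgeUm voxel edge length in micrometres (default 27).
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", semiAxesUm = "numeric",
                 shellFraction = "numeric", coreFraction = "numeric",
                 intensityBg = "numeric", intensityStarchy = "numeric",
                 intensityVitreous = "numeric", intensityPericarp = "numeric",
                 noiseSd = "numeric", blurSigma = "numeric",
                 seed = "integer", voxelEdgeUm = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive voxel extents (z, y, x)")
  if (length(object@semiAxesUm) != 3L || any(object@semiAxesUm <= 0))
    return("semiAxesUm must be three positive lengths (z, y, x)")
  if (!(object@coreFraction > 0 && object@coreFraction < object@shellFraction &&
        object@shellFraction <= 1))
    return("need 0 < coreFraction < shellFraction <= 1")
  ints <- c(object@intensityBg, object@intensityStarchy,
            object@intensityVitreous, object@intensityPericarp)
  if (any(ints < 0 | ints > 255)) return("intensities must lie in [0, 255]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  if (object@voxelEdgeUm <= 0) return("voxelEdgeUm must be > 0")
  TRUE
})

#' Build a PhantomSpec
#'
#' Default intensities (background 20, starchy 150, vitreous 180, pericarp
#' 220) give the deliberately small 30-unit vitreous/starchy contrast gap that
#' makes the phantoms a faithful miniature of the real segmentation problem:
#' the two endosperm classes are close in intensity and their boundary is
#' blurred, while the whole seed stands out brightly from the background.
#'
#' @param shape voxel extents `(z, y, x)` (default `c(64, 96, 96)`).
#' @param semiAxesUm outer semi-axes `(z, y, x)` in micrometres; default is
#'   `c(24, 34, 28) * voxelEdgeUm` (kernel-like anisotropy at test scale).
#' @param shellFraction,coreFraction radial fractions (defaults 0.85, 0.55).
#' @param intensityBg,intensityStarchy,intensityVitreous,intensityPericarp mean
#'   region intensities on the 8-bit scale.
#' @param contrastGap optional; if given, `intensityVitreous` is set to
#'   `intensityStarchy + contrastGap`.
#' @param noiseSd additive Gaussian noise SD (default 6).
#' @param blurSigma boundary blur in voxels (default 1).
#' @param seed RNG seed (default 1).
#' @param voxelEdgeUm voxel edge in micrometres (default 27).
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(shape = c(32, 48, 48), semiAxesUm = c(12, 18, 15) * 27)
#' @export
phantomSpec <- function(shape = c(64, 96, 96), semiAxesUm = NULL,
                        shellFraction = 0.85, coreFraction = 0.55,
                        intensityBg = 20, intensityStarchy = 150,
                        intensityVitreous = 180, intensityPericarp = 220,
                        contrastGap = NULL, noiseSd = 6, blurSigma = 1,
                        seed = 1, voxelEdgeUm = 27) {
  if (is.null(semiAxesUm)) semiAxesUm <- c(24, 34, 28) * voxelEdgeUm
  if (!is.null(contrastGap)) intensityVitreous <- intensityStarchy + contrastGap
  new("PhantomSpec", shape = as.integer(shape), semiAxesUm = as.numeric(semiAxesUm),
      shellFraction = shellFraction, coreFraction = coreFraction,
      intensityBg = intensityBg, intensityStarchy = intensityStarchy,
      intensityVitreous = intensityVitreous, intensityPericarp = intensityPericarp,
      noiseSd = noiseSd, blurSigma = blurSigma, seed = as.integer(seed),
      voxelEdgeUm = voxelEdgeUm)
}

#' Vitreous/starchy contrast gap of a phantom spec
#'
#' @param spec a [PhantomSpec-class].
#' @return `abs(intensityVitreous - intensityStarchy)` in 8-bit units.
#' @export
contrastGap <- function(spec) abs(spec@intensityVitreous - spec@intensityStarchy)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels, semi-axes (%s) um, core %.2f shell %.2f\n",
              paste(object@shape, collapse = "x"),
              paste(round(object@semiAxesUm), collapse = ", "),
              object@coreFraction, object@shellFraction))
  cat(sprintf("  intensities bg/starchy/vitreous/pericarp %g/%g/%g/%g, noise %g, blur %g, seed %d\n",
              object@intensityBg, object@intensityStarchy, object@intensityVitreous,
              object@intensityPericarp, object@noiseSd, object@blurSigma, object@seed))
})

# Normalised ellipsoidal radius field for a spec, centred in the volume.
phantomRho <- function(spec) {
  d <- spec@shape
  ax <- spec@semiAxesUm / spec@voxelEdgeUm  # semi-axes in voxels, order (z,y,x)
  cz <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  rz <- ((seq_len(d[1]) - cz) / ax[1])^2
  ry <- ((seq_len(d[2]) - cy) / ax[2])^2
  rx <- ((seq_len(d[3]) - cx) / ax[3])^2
  sqrt(outer(outer(rz, ry, "+"), rx, "+"))
}

# Crisp region label field: 0 bg, 1 starchy core, 2 vitreous shell, 3 pericarp.
phantomRegions <- function(spec) {
  rho <- phantomRho(spec)
  reg <- array(0L, dim(rho))
  reg[rho <= 1] <- 3L
  reg[rho <= spec@shellFraction] <- 2L
  reg[rho <= spec@coreFraction] <- 1L
  reg
}

#' Generate a single-kernel CT phantom with ground truth
#'
#' Renders the nested-ellipsoid phantom described by `spec`: region-wise mean
#' intensities, per-slice Gaussian blur of `blurSigma` (blurring the class
#' boundaries as in real kernel CT), additive Gaussian noise of `noiseSd`,
#' clamped to `[0, 255]`. Labels are the crisp pre-blur regions (pericarp is
#' part of the seed but background in the label map). Output is identical for
#' identical `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements
#'   \describe{
#'     \item{ct}{[CTVolume-class] rendered image.}
#'     \item{labels}{[LabelVolume-class] crisp class map over `{0, 1, 2}`.}
#'     \item{truth}{list of exact ground truth: `seedCount`, `starchyCount`,
#'       `vitreousCount`, `pericarpCount` voxel counts, `centroid` (z, y, x)
#'       of the seed, `bbox` (0-based half-open `z0,z1,y0,y1,x0,x1`), and the
#'       spec itself.}
#'   }
#' @examples
#' ph <- generateKernelPhantom(phantomSpec(shape = c(24, 40, 40),
#'                                         semiAxesUm = c(9, 16, 13) * 27))
#' ph$truth$starchyCount == sum(voxelData(ph$labels) == 1)
#' @export
generateKernelPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  reg <- phantomRegions(spec)
  lut <- c(spec@intensityBg, spec@intensityStarchy,
           spec@intensityVitreous, spec@intensityPericarp)
  img <- array(lut[reg + 1L], dim(reg))
  if (spec@blurSigma > 0) {
    for (z in seq_len(dim(img)[1]))
      img[z, , ] <- EBImage::gblur(img[z, , ], sigma = spec@blurSigma,
                                   boundary = "replicate")
  }
  if (spec@noiseSd > 0)
    img <- img + withSeed(spec@seed,
                          array(rnorm(length(img), 0, spec@noiseSd), dim(img)))
  img <- pmin(pmax(round(img), 0), 255)
  labels <- array(0L, dim(reg))
  labels[reg == 1L] <- 1L
  labels[reg == 2L] <- 2L
  seed <- reg > 0L
  truth <- list(
    seedCount = sum(seed),
    starchyCount = sum(reg == 1L),
    vitreousCount = sum(reg == 2L),
    pericarpCount = sum(reg == 3L),
    centroid = centroid3d(seed),
    bbox = bbox3d(seed),
    spec = spec
  )
  list(ct = CTVolume(img, voxelEdgeUm = spec@voxelEdgeUm, sourceId = "phantom"),
       labels = LabelVolume(labels, voxelEdgeUm = spec@voxelEdgeUm,
                            sourceId = "phantom"),
       truth = truth)
}

#' Composite several phantoms into a batch-scan scene
#'
#' Places the phantoms side by side along the x axis on a uniform dim
#' background (the foam-board analogue of a multi-kernel scan), separated by
#' `spacingVox` background voxels. Ground-truth centroids and bounding boxes
#' are returned in scene coordinates for validating batch splitting.
#'
#' @param specs list of [PhantomSpec-class] objects.
#' @param spacingVox background gap between adjacent kernels in voxels
#'   (default 12); must be >= 1 or the kernels would touch.
#' @return a list with `ct` ([CTVolume-class] scene) and `truth` (list of
#'   per-kernel truth records as in [generateKernelPhantom()], coordinates
#'   shifted to the scene frame).
#' @export
generateBatchScene <- function(specs, spacingVox = 12) {
  stopifnot(length(specs) >= 1, all(vapply(specs, is, logical(1), "PhantomSpec")))
  if (spacingVox < 1)
    paramError("spacingVox = %g would make kernels overlap; need >= 1", spacingVox)
  phantoms <- lapply(specs, generateKernelPhantom)
  shapes <- vapply(specs, function(s) s@shape, integer(3))
  Z <- max(shapes[1, ]); Y <- max(shapes[2, ])
  X <- sum(shapes[3, ]) + spacingVox * (length(specs) - 1L)
  bg <- specs[[1]]@intensityBg
  scene <- array(bg, c(Z, Y, X))
  truth <- vector("list", length(specs))
  x0 <- 0L
  for (i in seq_along(specs)) {
    d <- shapes[, i]
    z0 <- (Z - d[1]) %/% 2L
    y0 <- (Y - d[2]) %/% 2L
    scene[z0 + seq_len(d[1]), y0 + seq_len(d[2]), x0 + seq_len(d[3])] <-
      voxelData(phantoms[[i]]$ct)
    tr <- phantoms[[i]]$truth
    tr$centroid <- tr$centroid + c(z0, y0, x0)
    tr$bbox <- tr$bbox + c(z0, z0, y0, y0, x0, x0)
    truth[[i]] <- tr
    x0 <- x0 + d[3] + as.integer(spacingVox)
  }
  list(ct = CTVolume(scene, voxelEdgeUm = specs[[1]]@voxelEdgeUm,
                     sourceId = "phantom-batch-scene"),
       truth = truth)
}

#' Sample a training set of paired phantom slices
#'
#' Draws `n` central cross-sections of randomly parameterised phantoms:
#' ellipse semi-axes, core/shell fractions, noise and blur are sampled
#' uniformly from `specRanges`. Each item pairs a model-ready image (scaled to
#' `[0, 1]`) with its crisp `{0, 1, 2}` label map. Fully deterministic under
#' `seed`.
#'
#' @param n number of slice pairs (>= 1).
#' @param specRanges named list of `c(min, max)` ranges; recognised names and
#'   defaults: `semiAxisFrac = c(0.26, 0.42)` (ellipse semi-axes as a fraction
#'   of `side`), `coreFraction = c(0.45, 0.65)`,
#'   `shellFraction = c(0.78, 0.92)`, `noiseSd = c(4, 8)`,
#'   `blurSigma = c(0.7, 1.3)`.
#' @param seed RNG seed (default 1).
#' @param side slice side length in pixels (default 128).
#' @return list of `n` lists, each with `image` (side x side matrix in
#'   `[0, 1]`), `label` (side x side integer matrix over `{0, 1, 2}`), and
#'   `spec` (the sampled [PhantomSpec-class]).
#' @examples
#' set1 <- makeTrainingSet(2, seed = 7)
#' identical(set1, makeTrainingSet(2, seed = 7))
#' @export
makeTrainingSet <- function(n, specRanges = list(), seed = 1, side = 128) {
  stopifnot(n >= 1)
  rng <- list(semiAxisFrac = c(0.26, 0.42), coreFraction = c(0.45, 0.65),
              shellFraction = c(0.78, 0.92), noiseSd = c(4, 8),
              blurSigma = c(0.7, 1.3))
  unknown <- setdiff(names(specRanges), names(rng))
  if (length(unknown))
    paramError("unknown specRanges entries: %s", paste(unknown, collapse = ", "))
  rng[names(specRanges)] <- specRanges
  bad <- vapply(rng, function(r) length(r) != 2 || r[1] > r[2], logical(1))
  if (any(bad))
    paramError("invalid range for: %s", paste(names(rng)[bad], collapse = ", "))
  draws <- withSeed(seed, {
    u <- function(r, m) runif(m, r[1], r[2])
    list(ay = u(rng$semiAxisFrac, n), ax = u(rng$semiAxisFrac, n),
         core = u(rng$coreFraction, n), shell = u(rng$shellFraction, n),
         noise = u(rng$noiseSd, n), blur = u(rng$blurSigma, n),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  lapply(seq_len(n), function(i) {
    spec <- phantomSpec(
      shape = c(1L, side, side),
      # z semi-axis > 0 but irrelevant for a single central slice
      semiAxesUm = c(1, draws$ay[i] * side, draws$ax[i] * side) * 27,
      coreFraction = draws$core[i], shellFraction = draws$shell[i],
      noiseSd = draws$noise[i], blurSigma = draws$blur[i],
      seed = draws$seeds[i])
    ph <- generateKernelPhantom(spec)
    list(image = voxelData(ph$ct)[1, , ] / 255,
         label = voxelData(ph$labels)[1, , ],
         spec = spec)
  })
}
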