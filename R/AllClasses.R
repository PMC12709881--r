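#' @import methods
#' @importFrom stats rnorm runif quantile median sd setNames
#' @importFrom utils write.csv read.csv head tail
NULL

#' CTVolume: a reconstructed micro-CT slice stack
#'
#' Container for a 3D stack of 8-bit grayscale CT cross-sections with its
#' physical voxel size. Axes are ordered `(z, y, x)`: `data[z, , ]` is one
#' axial slice with image rows along `y` and columns along `x`. Intensities
#' live on the 0--255 scale.
#'
#' @slot data numeric 3D array `(z, y, x)`, values in `[0, 255]`.
#' @slot voxelEdgeUm physical edge length of one (cubic) voxel, micrometres.
#' @slot sourceId free-text provenance tag (scan id, directory, ...).
#'
#' @seealso [readSliceStack()], [LabelVolume-class]
#' @export
setClass("CTVolume",
  representation(data = "array", voxelEdgeUm = "numeric", sourceId = "character"),
  prototype(data = array(0, c(1, 1, 1)), voxelEdgeUm = 27, sourceId = "")
)

setValidity("CTVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must have exactly three axes (z, y, x)")
  if (any(dim(d) < 1L)) return("every axis of data must have positive extent")
  if (anyNA(d)) return("data contains NA")
  rng <- range(d)
  if (rng[1] < 0 || rng[2] > 255)
    return(sprintf("intensities must lie in [0, 255]; found range [%g, %g]", rng[1], rng[2]))
  if (length(object@voxelEdgeUm) != 1L || !is.finite(object@voxelEdgeUm) ||
      object@voxelEdgeUm <= 0)
    return("voxelEdgeUm must be a single positive number")
  TRUE
})

#' LabelVolume: a 3-class endosperm segmentation mask
#'
#' Integer mask aligned voxel-for-voxel with a [CTVolume-class]. Class codes:
#' 0 = background (everything outside the endosperm, including pericarp),
#' 1 = starchy endosperm, 2 = vitreous endosperm.
#'
#' @slot data integer-valued 3D array `(z, y, x)` over `{0, 1, 2}`.
#' @slot voxelEdgeUm voxel edge length in micrometres.
#' @slot sourceId free-text provenance tag.
#'
#' @seealso [readLabelVolume()], [CTVolume-class]
#' @export
setClass("LabelVolume",
  representation(data = "array", voxelEdgeUm = "numeric", sourceId = "character"),
  prototype(data = array(0L, c(1, 1, 1)), voxelEdgeUm = 27, sourceId = "")
)

setValidity("LabelVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must have exactly three axes (z, y, x)")
  if (any(dim(d) < 1L)) return("every axis of data must have positive extent")
  bad <- setdiff(unique(as.vector(d)), c(0, 1, 2))
  if (length(bad))
    return(paste0("illegal class code ", paste(sort(bad), collapse = ", "),
                  "; labels must be in {0, 1, 2}"))
  if (length(object@voxelEdgeUm) != 1L || !is.finite(object@voxelEdgeUm) ||
      object@voxelEdgeUm <= 0)
    return("voxelEdgeUm must be a single positive number")
  TRUE
})

#' Construct a CTVolume
#'
#' @param data 3D numeric array `(z, y, x)` of intensities in `[0, 255]`.
#' @param voxelEdgeUm voxel edge length in micrometres (default 27).
#' @param sourceId optional provenance tag.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(runif(4 * 8 * 8, 0, 255), c(4, 8, 8)))
#' dim(voxelData(v))
#' @export
CTVolume <- function(data, voxelEdgeUm = 27, sourceId = "") {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  new("CTVolume", data = data, voxelEdgeUm = as.numeric(voxelEdgeUm),
      sourceId = as.character(sourceId))
}

#' Construct a LabelVolume
#'
#' @param data 3D array over `{0, 1, 2}` (0 background, 1 starchy, 2 vitreous).
#' @param voxelEdgeUm voxel edge length in micrometres (default 27).
#' @param sourceId optional provenance tag.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(data, voxelEdgeUm = 27, sourceId = "") {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, voxelEdgeUm = as.numeric(voxelEdgeUm),
      sourceId = as.character(sourceId))
}

#' @describeIn voxelData method for CTVolume
#' @export
setMethod("voxelData", "CTVolume", function(x) x@data)

#' @describeIn voxelData method for LabelVolume
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)

#' @describeIn voxelEdge method for CTVolume
#' @export
setMethod("voxelEdge", "CTVolume", function(x) x@voxelEdgeUm)

#' @describeIn voxelEdge method for LabelVolume
#' @export
setMethod("voxelEdge", "LabelVolume", function(x) x@voxelEdgeUm)

#' @describeIn sourceId method for CTVolume
#' @export
setMethod("sourceId", "CTVolume", function(x) x@sourceId)

#' @describeIn sourceId method for LabelVolume
#' @export
setMethod("sourceId", "LabelVolume", function(x) x@sourceId)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume: %d slices of %d x %d (z, y, x), voxel edge %g um\n",
              d[1], d[2], d[3], object@voxelEdgeUm))
  cat(sprintf("  intensity range [%g, %g]%s\n",
              min(object@data), max(object@data),
              if (nzchar(object@sourceId)) paste0("  source: ", object@sourceId) else ""))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  n <- tabulate(as.vector(object@data) + 1L, nbins = 3L)
  cat(sprintf("LabelVolume: %d x %d x %d (z, y, x), voxel edge %g um\n",
              d[1], d[2], d[3], object@voxelEdgeUm))
  cat(sprintf("  background %d | starchy %d | vitreous %d voxels\n", n[1], n[2], n[3]))
})

#' @describeIn CTVolume dimensions of the voxel array
#' @param x a CTVolume
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

#' @describeIn LabelVolume dimensions of the voxel array
#' @param x a LabelVolume
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@data))
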