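#' Separate the vitreous and starchy class masks from a segmentation output
#'
#' A [LabelVolume-class] input is split by class code directly. A grayscale
#' mask volume (network output rendered as intensities) is split by an Otsu
#' threshold computed on the histogram of its nonzero intensities: voxels
#' above the threshold are taken as vitreous (the brighter class), nonzero
#' voxels at or below it as starchy. The two returned masks are disjoint.
#'
#' @param segmentation a [LabelVolume-class], or a numeric array/[CTVolume-class]
#'   grayscale mask volume with background at 0.
#' @return list with logical arrays `vitreous` and `starchy`.
#' @export
separateClassMasks <- function(segmentation) {
  if (is(segmentation, "LabelVolume")) {
    d <- voxelData(segmentation)
    return(list(vitreous = d == 2L, starchy = d == 1L))
  }
  d <- if (is(segmentation, "CTVolume")) voxelData(segmentation) else segmentation
  nz <- d[d > 0]
  if (!length(nz))
    paramError("cannot separate classes: mask volume has no nonzero voxels")
  if (length(unique(round(nz))) < 2L)
    paramError("cannot separate classes: degenerate single-mode histogram")
  thr <- otsuThreshold(nz)
  list(vitreous = d > thr, starchy = d > 0 & d <= thr)
}

#' Extract the whole-seed binary mask from a single-kernel CT volume
#'
#' Otsu foreground thresholding of the volume intensities, followed by
#' keeping the largest 26-connected 3D component and per-slice hole filling.
#' The result is the seed mask (pericarp included) used for the seed volume V.
#'
#' @param volume a [CTVolume-class] (or 3D array) containing one kernel.
#' @return logical 3D array of seed voxels.
#' @export
extractKernelMask <- function(volume) {
  d <- if (is(volume, "CTVolume")) voxelData(volume) else volume
  if (length(unique(round(as.vector(d)))) < 2L)
    paramError("no foreground found: volume is constant")
  thr <- otsuThreshold(d)
  fg <- d > thr
  if (!any(fg)) paramError("no foreground found above the Otsu threshold")
  labs <- labelComponents3d(fg)
  mask <- labs == 1L           # components are size-ordered
  for (z in seq_len(dim(mask)[1])) {
    sl <- matrix(as.numeric(mask[z, , ]), dim(mask)[2], dim(mask)[3])
    mask[z, , ] <- as.matrix(EBImage::fillHull(sl)) > 0
  }
  mask
}

#' Volume of a binary mask in cubic micrometres
#'
#' Voxel-counting volumetry: `volume = count * voxelEdgeUm^3`, i.e. every
#' mask voxel contributes one voxel volume `dV = edge^3`.
#'
#' @param mask logical/0-1 array.
#' @param voxelEdgeUm voxel edge length in micrometres (> 0; default 27).
#' @return volume in cubic micrometres.
#' @examples
#' computeComponentVolume(array(c(rep(1, 10), rep(0, 6)), c(4, 2, 2)), 27)
#' # 10 * 27^3 = 196830
#' @export
computeComponentVolume <- function(mask, voxelEdgeUm = 27) {
  if (voxelEdgeUm <= 0) paramError("voxelEdgeUm must be > 0")
  sum(mask > 0) * voxelEdgeUm^3
}

#' Bounding-box dimensions of a mask, sorted as length >= width >= thickness
#'
#' Tight axis-aligned 3D bounding box of the mask; its three edge lengths in
#' micrometres (voxel extents times the voxel edge), sorted descending.
#'
#' @param mask non-empty logical/0-1 3D array.
#' @param voxelEdgeUm voxel edge length in micrometres (default 27).
#' @return named numeric vector `length`, `width`, `thickness` (micrometres).
#' @export
boundingBoxDims <- function(mask, voxelEdgeUm = 27) {
  if (voxelEdgeUm <= 0) paramError("voxelEdgeUm must be > 0")
  if (!any(mask > 0)) paramError("empty mask has no bounding box")
  b <- bbox3d(mask > 0)
  ext <- b[c(2, 4, 6)] - b[c(1, 3, 5)]
  dims <- sort(ext * voxelEdgeUm, decreasing = TRUE)
  names(dims) <- c("length", "width", "thickness")
  dims
}

#' Compute the per-kernel phenotype record
#'
#' The five texture phenotypes plus the seed bounding-box dimensions:
#' seed volume V (from the whole-seed mask of the CT image, pericarp
#' included), vitreous volume VV and starchy volume SV (from the class
#' masks), the ratios VV/V and SV/V, and length/width/thickness of the seed
#' bounding box. Because V covers the whole seed while VV and SV cover only
#' the endosperm, `VV/V + SV/V < 1` in general.
#'
#' @param ct single-kernel [CTVolume-class].
#' @param labels aligned [LabelVolume-class] (prediction or ground truth).
#' @param kernelId identifier written into the record.
#' @param group subgroup tag (`"mixed"`, `"NSS"`, `"SS"`, `"TST"`, or other).
#' @return one-row data.frame with columns `kernel_id, V, VV, SV, VV_over_V,
#'   SV_over_V, length, width, thickness, group` (volumes in um^3, dimensions
#'   in um).
#' @export
computePhenotypes <- function(ct, labels, kernelId = "kernel", group = "other") {
  stopifnot(is(ct, "CTVolume"), is(labels, "LabelVolume"))
  if (!all(dim(ct) == dim(labels)))
    paramError("ct and labels are not aligned: %s vs %s",
               paste(dim(ct), collapse = "x"), paste(dim(labels), collapse = "x"))
  edge <- voxelEdge(ct)
  seed <- extractKernelMask(ct)
  masks <- separateClassMasks(labels)
  V <- computeComponentVolume(seed, edge)
  VV <- computeComponentVolume(masks$vitreous, edge)
  SV <- computeComponentVolume(masks$starchy, edge)
  dims <- boundingBoxDims(seed, edge)
  data.frame(kernel_id = as.character(kernelId), V = V, VV = VV, SV = SV,
             VV_over_V = VV / V, SV_over_V = SV / V,
             length = dims[["length"]], width = dims[["width"]],
             thickness = dims[["thickness"]], group = as.character(group),
             stringsAsFactors = FALSE)
}

#' Aggregate phenotype records by subgroup
#'
#' Per group and per phenotype (`VV`, `SV`, `VV_over_V`, `SV_over_V`):
#' n, mean, median, standard deviation (0 when n = 1), min, max and
#' quartiles — the summary statistics underlying subgroup box plots.
#'
#' @param records non-empty data.frame of phenotype records.
#' @param variables phenotype columns to summarise.
#' @return data.frame with one row per group x variable.
#' @export
aggregateByGroup <- function(records,
                             variables = c("VV", "SV", "VV_over_V", "SV_over_V")) {
  if (is.null(records) || nrow(records) == 0)
    paramError("no phenotype records to aggregate")
  missing <- setdiff(c(variables, "group"), names(records))
  if (length(missing))
    paramError("records lack columns: %s", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(split(records, records$group), function(g) {
    do.call(rbind, lapply(variables, function(v) {
      x <- g[[v]]
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(group = g$group[1], variable = v, n = length(x),
                 mean = mean(x), median = q[2],
                 sd = if (length(x) > 1) sd(x) else 0,
                 min = min(x), q1 = q[1], q3 = q[3], max = max(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
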