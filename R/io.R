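#' Read a directory of CT slice images into a CTVolume
#'
#' Stacks every BMP/PNG file of a directory along the z axis, in natural
#' (numeric-aware) filename order, so `slice_2` precedes `slice_10` regardless
#' of listing order. Colour images are collapsed to Rec.601 luminance; all
#' intensities are returned on the 0--255 scale.
#'
#' @param directoryPath directory containing the slice images (all of equal
#'   height and width).
#' @param voxelEdgeUm physical voxel edge length in micrometres (default 27).
#' @return a [CTVolume-class] of shape `(n_slices, height, width)`.
#' @seealso [writeSliceStack()], [readLabelVolume()]
#' @export
readSliceStack <- function(directoryPath, voxelEdgeUm = 27) {
  files <- list.files(directoryPath, pattern = "\\.(bmp|png)$", ignore.case = TRUE)
  if (!length(files))
    stop(sprintf("no slices found in %s", directoryPath), call. = FALSE)
  files <- naturalSort(files)
  slices <- lapply(files, function(f) readSliceImage(file.path(directoryPath, f)))
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("inconsistent slice shape: %s is %dx%d but %s is %dx%d",
                 files[bad], dims[1, bad], dims[2, bad],
                 files[1], dims[1, 1], dims[2, 1]), call. = FALSE)
  }
  data <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) data[z, , ] <- slices[[z]]
  CTVolume(data, voxelEdgeUm = voxelEdgeUm, sourceId = directoryPath)
}

# One slice image file -> numeric matrix (y, x) on 0..255.
readSliceImage <- function(path) {
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) return(readBMP(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  round(img * 255)
}

#' Write a CTVolume as a slice-image stack
#'
#' One 8-bit grayscale file per axial slice, named `<prefix>_0001.<format>`
#' onward so the stack round-trips bit-exactly through [readSliceStack()].
#'
#' @param volume a [CTVolume-class].
#' @param directoryPath output directory (created if missing).
#' @param format `"png"` (default) or `"bmp"`.
#' @param prefix filename prefix (default `"slice"`).
#' @return the directory path, invisibly.
#' @export
writeSliceStack <- function(volume, directoryPath, format = c("png", "bmp"),
                            prefix = "slice") {
  stopifnot(is(volume, "CTVolume"))
  format <- match.arg(format)
  dir.create(directoryPath, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume)
  for (z in seq_len(d[1])) {
    img <- round(voxelData(volume)[z, , ])
    f <- file.path(directoryPath, sprintf("%s_%04d.%s", prefix, z, format))
    if (format == "bmp") writeBMP(img, f) else png::writePNG(img / 255, f)
  }
  invisible(directoryPath)
}

#' Read a label volume from NIfTI or an indexed-PNG stack
#'
#' Accepts either a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory of
#' indexed 8-bit PNGs (one per slice, natural filename order). Any voxel value
#' outside `{0, 1, 2}` is an error, never silently clamped.
#'
#' NIfTI orientation codes are deliberately ignored: the array is taken in
#' stored order with the third (slowest) axis as z, so the returned array is
#' `(z, y, x)` with y and x the second and first stored axes. Volumes written
#' by [writeLabelVolume()] round-trip exactly; files from other tools are not
#' reoriented.
#'
#' @param path NIfTI file or PNG-stack directory.
#' @param voxelEdgeUm voxel edge length in micrometres (default 27).
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path, voxelEdgeUm = 27) {
  if (dir.exists(path)) {
    vol <- readSliceStack(path, voxelEdgeUm = voxelEdgeUm)
    data <- voxelData(vol)
  } else {
    if (!file.exists(path))
      stop(sprintf("cannot read label volume: %s does not exist", path),
           call. = FALSE)
    nii <- RNifti::readNifti(path)
    a <- as.array(nii)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3L)
      stop(sprintf("label volume %s has %d axes; expected 3", path,
                   length(dim(a))), call. = FALSE)
    data <- aperm(a, c(3, 2, 1))   # stored slowest axis -> z
  }
  bad <- setdiff(unique(as.vector(data)), c(0, 1, 2))
  if (length(bad))
    stop(sprintf("illegal class code %s in %s; labels must be in {0, 1, 2}",
                 paste(sort(bad), collapse = ", "), path), call. = FALSE)
  LabelVolume(data, voxelEdgeUm = voxelEdgeUm, sourceId = path)
}

#' Write a label volume to NIfTI or an indexed-PNG stack
#'
#' @param labels a [LabelVolume-class].
#' @param path output `.nii`/`.nii.gz` file, or a directory (written as an
#'   indexed PNG stack).
#' @return the path, invisibly.
#' @seealso [readLabelVolume()] for the (z, y, x) axis convention.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- aperm(voxelData(labels), c(3, 2, 1))
    storage.mode(a) <- "integer"
    vx <- labels@voxelEdgeUm / 1000  # NIfTI pixdim in mm
    RNifti::writeNifti(RNifti::asNifti(a, pixdim = c(vx, vx, vx)), path)
  } else {
    vol <- CTVolume(voxelData(labels), voxelEdgeUm = labels@voxelEdgeUm)
    writeSliceStack(vol, path, format = "png", prefix = "label")
  }
  invisible(path)
}

# Column order of the phenotype table; fixed schema shared by writer/reader.
phenotypeColumns <- c("kernel_id", "V", "VV", "SV", "VV_over_V", "SV_over_V",
                      "length", "width", "thickness", "group")

#' Write phenotype records to CSV
#'
#' One row per kernel with columns `kernel_id, V, VV, SV, VV_over_V,
#' SV_over_V, length, width, thickness, group`. Volumes are in cubic
#' micrometres, dimensions in micrometres, ratios dimensionless. An empty
#' record set yields a header-only file.
#'
#' @param records a data.frame of phenotype records (as returned by
#'   [computePhenotypes()], possibly rbind-ed), or an empty data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePhenotypeTable <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(phenotypeColumns)),
                                      phenotypeColumns))
  }
  missing <- setdiff(phenotypeColumns, names(records))
  if (length(missing))
    paramError("phenotype records lack columns: %s", paste(missing, collapse = ", "))
  write.csv(records[phenotypeColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [writePhenotypeTable()]
#'
#' @param path CSV path.
#' @return a data.frame with the standard phenotype columns.
#' @export
readPhenotypeTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(kernel_id = "character", group = "character"))
}
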