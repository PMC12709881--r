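#' Access the raw voxel array of a volume object
#'
#' @param x a [CTVolume-class] or [LabelVolume-class]
#' @return the 3D array `(z, y, x)` stored in the object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Physical voxel edge length in micrometres
#'
#' @param x a [CTVolume-class] or [LabelVolume-class]
#' @return a single positive number (micrometres).
#' @export
setGeneric("voxelEdge", function(x) standardGeneric("voxelEdge"))

#' Provenance tag of a volume object
#'
#' @param x a [CTVolume-class] or [LabelVolume-class]
#' @return a character scalar.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
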