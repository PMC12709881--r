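# Internal helpers shared across modules.

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Natural (numeric-aware) sort of file names
#'
#' Orders strings so embedded integers compare numerically: `slice_2` sorts
#' before `slice_10`. This defines the slice order of every stack reader, so
#' the order is stable under any permutation of the directory listing.
#'
#' @param x character vector.
#' @return `x` in natural order.
#' @examples
#' naturalSort(c("s10.png", "s2.png", "s1.png"))
#' @export
naturalSort <- function(x) {
  if (!length(x)) return(x)
  pieces <- strsplit(x, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  width <- max(lengths(pieces))
  keymat <- vapply(pieces, function(p) {
    p <- c(p, rep("", width - length(p)))
    vapply(p, function(tok) {
      if (grepl("^\\d+$", tok)) sprintf("%020d", as.numeric(tok)) else tok
    }, character(1))
  }, character(width))
  if (width == 1L) keymat <- matrix(keymat, nrow = 1L)
  ord <- do.call(order, c(split(keymat, row(keymat)), list(x)))
  x[ord]
}

# Stop with a consistent error class for user-facing parameter problems.
paramError <- function(...) stop(sprintf(...), call. = FALSE)

# 0-based half-open bounding box of TRUE voxels in a 3D logical array,
# as c(z0, z1, y0, y1, x0, x1).
bbox3d <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no bounding box", call. = FALSE)
  as.integer(c(min(idx[, 1]) - 1L, max(idx[, 1]),
               min(idx[, 2]) - 1L, max(idx[, 2]),
               min(idx[, 3]) - 1L, max(idx[, 3])))
}

# Centroid (1-based voxel coordinates, order z, y, x) of TRUE voxels.
centroid3d <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no centroid", call. = FALSE)
  colMeans(idx)
}
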