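# 3D connected-component labelling with 26-connectivity.
#
# Strategy: label each axial slice in 2D, then merge labels with union-find,
# both within slices (adding the diagonal adjacencies 2D labelling may split)
# and across adjacent slices (any of the 9 in-plane offsets counts as a
# 26-neighbour). This keeps the per-voxel work inside vectorised primitives.

# Union-find over n nodes; returns find/union closures.
makeUnionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  list(find = find, union = union,
       roots = function() vapply(seq_len(n), find, integer(1)))
}

# All (labelA, labelB) adjacency pairs between two labelled matrices under the
# in-plane offsets (dy, dx) in {-1,0,1}^2 (self-pairs removed).
labelPairs <- function(A, B) {
  ny <- nrow(A); nx <- ncol(A)
  out <- vector("list", 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    ya <- max(1, 1 + dy):min(ny, ny + dy)
    xa <- max(1, 1 + dx):min(nx, nx + dx)
    a <- A[ya, xa, drop = FALSE]
    b <- B[ya - dy, xa - dx, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) { k <- k + 1L; out[[k]] <- cbind(a[sel], b[sel]) }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out[seq_len(k)]))
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask logical (or 0/1) 3D array `(z, y, x)`.
#' @return integer array of the same shape; 0 outside the mask, components
#'   numbered 1..n in decreasing voxel-count order (ties broken by smaller
#'   centroid x, then y, then z, for determinism).
#' @export
labelComponents3d <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[1])) {
    sl <- EBImage::bwlabel(matrix(as.numeric(mask[z, , ] > 0), d[2], d[3]))
    sl <- matrix(as.integer(sl), d[2], d[3])
    sl[sl > 0L] <- sl[sl > 0L] + offset
    labs[z, , ] <- sl
    offset <- max(offset, if (any(sl > 0L)) max(sl) else offset)
  }
  if (offset == 0L) return(labs)
  uf <- makeUnionFind(offset)
  for (z in seq_len(d[1])) {
    A <- matrix(labs[z, , ], d[2], d[3])
    prs <- labelPairs(A, A)                      # in-plane diagonal merges
    if (z < d[1]) {
      B <- matrix(labs[z + 1L, , ], d[2], d[3])
      prs <- rbind(prs, labelPairs(A, B))
    }
    prs <- prs[prs[, 1] != prs[, 2], , drop = FALSE]
    if (nrow(prs)) apply(prs, 1, function(p) uf$union(p[1], p[2]))
  }
  roots <- uf$roots()
  merged <- array(0L, d)
  sel <- labs > 0L
  merged[sel] <- roots[labs[sel]]
  # renumber by decreasing size with deterministic tie-breaking
  ids <- sort(unique(merged[merged > 0L]))
  sizes <- tabulate(merged[sel], nbins = max(ids))[ids]
  cx <- vapply(ids, function(i) centroid3d(merged == i)[3], numeric(1))
  cy <- vapply(ids, function(i) centroid3d(merged == i)[2], numeric(1))
  cz <- vapply(ids, function(i) centroid3d(merged == i)[1], numeric(1))
  ord <- order(-sizes, cx, cy, cz)
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  out <- array(0L, d)
  out[sel] <- remap[merged[sel]]
  out
}
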