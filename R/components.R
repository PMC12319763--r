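# Connected-component labelling of voxel sets.
# 26-connectivity (all touching neighbours) by default; 6 = faces only.

half_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  # keep one of each +/- pair
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, , drop = FALSE])
}

#' Label connected components of a voxel mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component labels (0 outside the mask), with the
#'   component sizes in the `sizes` attribute.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  nv <- sum(mask)
  if (nv == 0L) {
    labels <- array(0L, dim = d)
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  # crop to the bounding box of the set; label there; paste back
  w <- which(mask, arr.ind = TRUE)
  lo <- c(min(w[, 1]), min(w[, 2]), min(w[, 3]))
  hi <- c(max(w[, 1]), max(w[, 2]), max(w[, 3]))
  if (any(lo > 1L) || any(hi < d)) {
    sub <- label_components(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                 drop = FALSE], connectivity)
    labels <- array(0L, dim = d)
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    attr(labels, "sizes") <- attr(sub, "sizes")
    return(labels)
  }
  labels <- array(0L, dim = d)
  rank <- array(0L, dim = d)
  rank[mask] <- seq_len(nv)
  offs <- half_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (any(d + pmin(o, 0) < 1L + pmax(o, 0))) {
      edges[[i]] <- NULL
      next
    }
    xa <- max(1L, 1L + o[1]):min(d[1], d[1] + o[1])
    ya <- max(1L, 1L + o[2]):min(d[2], d[2] + o[2])
    za <- max(1L, 1L + o[3]):min(d[3], d[3] + o[3])
    a <- rank[xa, ya, za, drop = FALSE]
    b <- rank[xa - o[1], ya - o[2], za - o[3], drop = FALSE]
    both <- a > 0L & b > 0L
    edges[[i]] <- cbind(a[both], b[both])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    labels[mask] <- seq_len(nv)
    attr(labels, "sizes") <- rep(1L, nv)
    return(labels)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)
  labels[mask] <- comp$membership[seq_len(nv)]
  attr(labels, "sizes") <- as.integer(comp$csize)
  labels
}
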