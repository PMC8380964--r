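# Connected-component labeling of voxel sets on a 3D grid (6- or
# 26-connectivity), via union-find over precomputed neighbor offsets.

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  else if (connectivity != 26L)
    stop("connectivity must be 6 or 26")
  as.matrix(g)
}

#' Label connected components of a voxel set
#'
#' @param idx Linear (1-based) indices of the voxels in the set.
#' @param grid_dim Integer vector of 3 grid dimensions.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer vector of component labels (1..n_components), parallel
#'   to `idx`; labels are ordered by decreasing component size.
#' @export
label_components <- function(idx, grid_dim, connectivity = 26L) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  co <- arrayInd(idx, grid_dim)
  off <- neighbor_offsets(connectivity)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(off))) {
    nb <- co + matrix(off[o, ], m, 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= grid_dim[1] &
          nb[, 2] >= 1L & nb[, 2] <= grid_dim[2] &
          nb[, 3] >= 1L & nb[, 3] <= grid_dim[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * grid_dim[1] * grid_dim[2] +
      (nb[ok, 2] - 1L) * grid_dim[1] + nb[ok, 1]
    j <- match(nb_lin, idx)
    hit <- which(!is.na(j))
    if (!length(hit)) next
    a_idx <- which(ok)[hit]
    b_idx <- j[hit]
    for (k in seq_along(hit)) {
      ra <- find(a_idx[k]); rb <- find(b_idx[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  sizes <- table(roots)
  ord <- names(sort(sizes, decreasing = TRUE))
  match(as.character(roots), ord)
}
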