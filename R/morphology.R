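# Binary 3D morphology on logical arrays: connected-component labeling
# (6/26-connectivity) and iterative dilation. Pure R, vectorized over voxels;
# adequate for clinical PET grid sizes (~64^3 to 200^3).

.neighbor_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26", call. = FALSE)
  off
}

# Adjacency of in-mask voxels: returns an n x k matrix of ordinals into the
# in-mask voxel list (0 = no in-mask neighbor in that direction).
.mask_adjacency <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  pos <- array(0L, dims)
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dims)
  off <- .neighbor_offsets(connectivity)
  adj <- matrix(0L, nrow = n, ncol = nrow(off))
  for (j in seq_len(nrow(off))) {
    nb <- coords + matrix(off[j, ], nrow = n, ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (any(ok)) adj[ok, j] <- pos[nb[ok, , drop = FALSE]]
  }
  list(idx = idx, adj = adj, dims = dims)
}

#' Label connected components of a binary 3D mask
#'
#' Components are labeled 1..K in order of decreasing voxel count (ties broken
#' by smallest linear index), after discarding components smaller than
#' `min_voxels`.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param connectivity 26 (default) or 6.
#' @param min_voxels Discard components with fewer voxels than this.
#' @return Integer 3D array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L, min_voxels = 1L) {
  mask <- mask != 0
  dims <- dim(mask)
  out <- array(0L, dims)
  if (!any(mask)) return(out)
  a <- .mask_adjacency(mask, connectivity)
  n <- length(a$idx)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    frontier <- s
    comp[s] <- ncomp
    while (length(frontier)) {
      nb <- a$adj[frontier, , drop = FALSE]
      nb <- nb[nb > 0L]
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- ncomp
      frontier <- nb
    }
  }
  sizes <- tabulate(comp, nbins = ncomp)
  first <- integer(ncomp)
  first[comp[!duplicated(comp)]] <- a$idx[!duplicated(comp)]
  keep <- which(sizes >= min_voxels)
  keep <- keep[order(-sizes[keep], first[keep])]
  relabel <- integer(ncomp)
  relabel[keep] <- seq_along(keep)
  out[a$idx] <- relabel[comp]
  out
}

# Connected component containing a given voxel (array index c(i,j,k)) in a
# binary mask; returns a logical array.
.component_containing <- function(mask, voxel, connectivity = 26L) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  lin <- voxel[1] + dims[1] * (voxel[2] - 1L) + dims[1] * dims[2] * (voxel[3] - 1L)
  if (!mask[lin]) return(out)
  a <- .mask_adjacency(mask, connectivity)
  n <- length(a$idx)
  start <- match(lin, a$idx)
  visited <- logical(n)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- a$adj[frontier, , drop = FALSE]
    nb <- nb[nb > 0L]
    nb <- unique(nb[!visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  out[a$idx[visited]] <- TRUE
  out
}

#' Dilate a binary 3D mask
#'
#' Iterative dilation by `radius` steps of the chosen neighborhood
#' (26-neighborhood steps grow a Chebyshev ball).
#'
#' @param mask Logical 3D array.
#' @param radius Number of dilation steps (>= 0).
#' @param connectivity 26 (default) or 6.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, radius, connectivity = 26L) {
  mask <- mask != 0
  if (radius <= 0) return(mask)
  dims <- dim(mask)
  off <- .neighbor_offsets(connectivity)
  for (step in seq_len(radius)) {
    grown <- mask
    idx <- which(mask)
    if (!length(idx)) break
    coords <- arrayInd(idx, dims)
    for (j in seq_len(nrow(off))) {
      nb <- coords + matrix(off[j, ], nrow = nrow(coords), ncol = 3, byrow = TRUE)
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
            nb[, 2] >= 1L & nb[, 2] <= dims[2] &
            nb[, 3] >= 1L & nb[, 3] <= dims[3]
      grown[nb[ok, , drop = FALSE]] <- TRUE
    }
    mask <- grown
  }
  mask
}
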