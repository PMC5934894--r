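# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use the most naive formulation available (exhaustive scans, double loops,
# pair counting) so they stay independent of the implementation paths they
# check.

# --- small phantom builders -------------------------------------------------

plateau_sphere_phantom <- function(diameter = 30, uptake = 10, h = 4,
                                   n = 24, psf = 0, noise = 0, seed = 1L) {
  ctr <- rep(n * h / 2, 3)
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), spacing = rep(h, 3),
    lesions = list(lesion_spec("sphere", ctr, diameter, uptake)),
    psf_fwhm = psf, noise_sd = noise, seed = seed))
}

plateau_cube_phantom <- function(edge = 40, uptake = 10, h = 4, n = 20,
                                 psf = 0) {
  ctr <- rep(n * h / 2, 3)
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), spacing = rep(h, 3),
    lesions = list(lesion_spec("cube", ctr, edge, uptake)),
    psf_fwhm = psf))
}

# segmentation directly from a logical mask
seg_from_mask <- function(mask, spacing = c(4, 4, 4)) {
  segmentation(array(as.integer(mask), dim(mask)), spacing = spacing)
}

# --- oracles ----------------------------------------------------------------

# Exhaustive-scan thresholding oracle: voxel-by-voxel triple loop plus a
# naive repeated-sweep component labeling (26-connectivity). Only usable on
# tiny grids.
oracle_threshold_label <- function(voxels, threshold, min_voxels = 1L) {
  dims <- dim(voxels)
  mask <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      mask[i, j, k] <- voxels[i, j, k] >= threshold
    }
  lab <- array(0L, dims)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        if (!mask[i, j, k]) next
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          ii <- i + di; jj <- j + dj; kk <- k + dk
          if (ii < 1 || jj < 1 || kk < 1 || ii > dims[1] || jj > dims[2] ||
              kk > dims[3]) next
          if (mask[ii, jj, kk] && lab[ii, jj, kk] < lab[i, j, k]) {
            lab[i, j, k] <- lab[ii, jj, kk]
            changed <- TRUE
          }
        }
      }
    if (!changed) break
  }
  ids <- sort(unique(lab[lab > 0L]))
  sizes <- vapply(ids, function(id) sum(lab == id), integer(1))
  keep <- ids[sizes >= min_voxels]
  lab[!(lab %in% keep)] <- 0L
  # canonical: sort component voxel-count multiset
  list(labels = lab,
       sizes = sort(sizes[sizes >= min_voxels], decreasing = TRUE))
}

# Brute-force GLCM oracle: double loop over all in-mask voxel pairs.
oracle_glcm <- function(voxels, mask, n_levels, offsets, symmetric = TRUE) {
  dims <- dim(mask)
  vals <- voxels[mask]
  rng <- range(vals)
  lev <- array(NA_integer_, dims)
  if (rng[2] <= rng[1]) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L,
                      n_levels)
  }
  counts <- matrix(0, n_levels, n_levels)
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  for (r in seq_len(nrow(co))) {
    for (o in seq_len(nrow(offsets))) {
      p2 <- co[r, ] + offsets[o, ]
      if (any(p2 < 1) || any(p2 > dims)) next
      if (!mask[p2[1], p2[2], p2[3]]) next
      a <- lev[co[r, 1], co[r, 2], co[r, 3]]
      b <- lev[p2[1], p2[2], p2[3]]
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  p <- counts / sum(counts)
  nz <- p > 0
  d2 <- (row(p) - col(p))^2
  c(entropy = -sum(p[nz] * log2(p[nz])), energy = sum(p^2),
    contrast = sum(p * d2), local_homogeneity = sum(p / (1 + d2)))
}

# Pair-counting AUC oracle: wins + half ties over all (pos, neg) pairs.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Enumeration oracle for the SUVpeak sphere: voxel centers within radius.
oracle_peak_neighborhood <- function(spacing, radius_mm) {
  reach <- ceiling(radius_mm / spacing)
  pts <- expand.grid(dx = -reach[1]:reach[1], dy = -reach[2]:reach[2],
                     dz = -reach[3]:reach[3])
  d <- sqrt((pts$dx * spacing[1])^2 + (pts$dy * spacing[2])^2 +
              (pts$dz * spacing[3])^2)
  pts[d <= radius_mm + 1e-9, , drop = FALSE]
}
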