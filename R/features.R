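# Metabolic and heterogeneity parameters computed on the total MTV (union of
# all labeled voxels): SUVmax/mean/peak, TLG, cumulative SUV-volume histogram
# scalar (AUC-CSH), gray-level co-occurrence texture, and asphericity (see
# asphericity.R).

.mask_union <- function(seg) seg$labels > 0L

.check_nonempty <- function(seg) {
  if (!any(seg$labels > 0L)) {
    stop("segmentation is empty: features are undefined", call. = FALSE)
  }
}

#' SUVmax and SUVmean over the total MTV
#'
#' @param image An `suv_image`.
#' @param seg A nonempty `segmentation` on the same grid.
#' @return Named numeric vector `c(suv_max =, suv_mean =)`.
#' @export
suv_stats <- function(image, seg) {
  .check_nonempty(seg)
  vals <- image$voxels[.mask_union(seg)]
  c(suv_max = max(vals), suv_mean = mean(vals))
}

#' SUVpeak: mean SUV in a sphere centered at the hottest voxel
#'
#' The sphere (default diameter 12 mm) is centered at the center of the
#' voxel holding the global in-mask maximum; membership is by voxel-center
#' distance <= diameter/2. The sphere may extend outside the mask; portions
#' outside the image grid are clipped (recorded in attribute `clipped`).
#'
#' @param image An `suv_image`.
#' @param seg A nonempty `segmentation`.
#' @param sphere_diameter_mm Sphere diameter in mm.
#' @return SUVpeak (numeric scalar).
#' @export
suv_peak <- function(image, seg, sphere_diameter_mm = 12) {
  .check_nonempty(seg)
  vox <- image$voxels
  dims <- dim(vox)
  mask <- .mask_union(seg)
  in_idx <- which(mask)
  mx <- max(vox[in_idx])
  cand <- in_idx[vox[in_idx] >= mx - 1e-12]
  if (length(cand) > 1L) {
    # plateau lesions tie at the maximum: center on the tied voxel closest
    # to the mask centroid (deterministic; keeps the sphere inside)
    all_co <- arrayInd(in_idx, dims)
    centroid <- colMeans(all_co)
    co <- arrayInd(cand, dims)
    d2 <- rowSums(sweep(co, 2, centroid)^2)
    cand <- cand[order(d2, cand)][1]
  }
  center <- arrayInd(cand, dims)[1, ]
  r <- sphere_diameter_mm / 2
  h <- image$spacing
  reach <- floor(r / h)
  grid <- expand.grid(dx = -reach[1]:reach[1], dy = -reach[2]:reach[2],
                      dz = -reach[3]:reach[3])
  dist <- sqrt((grid$dx * h[1])^2 + (grid$dy * h[2])^2 + (grid$dz * h[3])^2)
  grid <- grid[dist <= r + 1e-9, , drop = FALSE]
  pts <- cbind(center[1] + grid$dx, center[2] + grid$dy, center[3] + grid$dz)
  ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
        pts[, 2] >= 1 & pts[, 2] <= dims[2] &
        pts[, 3] >= 1 & pts[, 3] <= dims[3]
  out <- mean(vox[pts[ok, , drop = FALSE]])
  attr(out, "clipped") <- any(!ok)
  out
}

#' Total lesion glycolysis
#'
#' The exact product `MTV * SUVmean` (ml, SUV-weighted).
#'
#' @param mtv Metabolic tumor volume in ml (>= 0).
#' @param suv_mean Mean SUV over the MTV.
#' @return TLG in ml.
#' @export
tlg <- function(mtv, suv_mean) {
  if (mtv < 0) stop("mtv must be >= 0", call. = FALSE)
  mtv * suv_mean
}

#' Area under the cumulative SUV-volume histogram
#'
#' For relative thresholds t = k/n (k = 0..n) of the in-mask SUVmax, F(t) is
#' the fraction of the MTV with SUV >= t * SUVmax; the scalar is the
#' trapezoidal area under F on [0, 1]. Uniform uptake gives 1; heterogeneous
#' uptake gives smaller values.
#'
#' @param image An `suv_image`.
#' @param seg A nonempty `segmentation`.
#' @param n_thresholds Number of threshold steps (default 100).
#' @return AUC-CSH in (0, 1].
#' @export
csh_auc <- function(image, seg, n_thresholds = 100L) {
  .check_nonempty(seg)
  vals <- image$voxels[.mask_union(seg)]
  mx <- max(vals)
  if (mx <= 0) stop("suv_max must be > 0 for CSH", call. = FALSE)
  t <- (0:n_thresholds) / n_thresholds
  fr <- vapply(t * mx, function(th) mean(vals >= th - 1e-12), numeric(1))
  sum((fr[-1] + fr[-length(fr)]) / 2) / n_thresholds
}

#' Texture (GLCM) configuration
#'
#' @param n_gray_levels Number of quantization bins (>= 2; default 64).
#' @param offsets Integer matrix of 3D displacement vectors, one per row.
#'   Default: the 13 unique direction offsets at Chebyshev distance 1.
#' @param symmetric Accumulate both (v1, v2) and (v2, v1) (default TRUE).
#' @return A `texture_config` list.
#' @export
texture_config <- function(n_gray_levels = 64L, offsets = NULL,
                           symmetric = TRUE) {
  if (n_gray_levels < 2) stop("n_gray_levels must be >= 2", call. = FALSE)
  if (is.null(offsets)) {
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    # keep one representative per +/- pair
    keep <- apply(off, 1, function(o) {
      o[1] > 0 || (o[1] == 0 && (o[2] > 0 || (o[2] == 0 && o[3] > 0)))
    })
    offsets <- off[keep, , drop = FALSE]
  }
  if (nrow(offsets) == 0) stop("offsets must be nonempty", call. = FALSE)
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 offsets = offsets, symmetric = isTRUE(symmetric)),
            class = "texture_config")
}

# Equal-width quantization over the in-mask min-max into n levels 1..n.
.quantize <- function(vals, n) {
  rng <- range(vals)
  if (rng[2] <= rng[1]) return(rep(1L, length(vals)))
  lev <- floor((vals - rng[1]) / (rng[2] - rng[1]) * n) + 1L
  pmin(lev, n)
}

#' Gray-level co-occurrence texture features
#'
#' SUVs inside the mask are quantized to `n_gray_levels` equal-width bins over
#' the lesion min-max; a single pooled co-occurrence matrix is accumulated
#' over all offsets (both voxels of a pair must lie inside the mask) and
#' normalized to joint probabilities p(i, j). Returned features:
#' entropy = -sum p log2 p (bits), energy = sum p^2,
#' contrast = sum p (i - j)^2, local homogeneity = sum p / (1 + (i - j)^2).
#' A constant-valued lesion yields the degenerate single-cell matrix
#' (0, 1, 0, 1), flagged via attribute `degenerate`.
#'
#' @param image An `suv_image`.
#' @param seg A `segmentation` with >= 2 labeled voxels.
#' @param cfg A [texture_config()].
#' @return Named numeric vector `entropy`, `energy`, `contrast`,
#'   `local_homogeneity`.
#' @export
glcm_features <- function(image, seg, cfg = texture_config()) {
  mask <- .mask_union(seg)
  if (sum(mask) < 2) stop("texture needs >= 2 labeled voxels", call. = FALSE)
  dims <- dim(mask)
  idx <- which(mask)
  vals <- image$voxels[idx]
  lev <- array(0L, dims)
  lev[idx] <- .quantize(vals, cfg$n_gray_levels)
  n <- cfg$n_gray_levels
  counts <- numeric(n * n)
  coords <- arrayInd(idx, dims)
  for (j in seq_len(nrow(cfg$offsets))) {
    nb <- coords + matrix(cfg$offsets[j, ], nrow = nrow(coords), ncol = 3,
                          byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    li <- lev[idx[ok]]
    lj <- lev[nb[ok, , drop = FALSE]]
    pair_ok <- lj > 0L
    li <- li[pair_ok]; lj <- lj[pair_ok]
    if (!length(li)) next
    cell <- (li - 1L) * n + lj
    tab <- tabulate(cell, nbins = n * n)
    counts <- counts + tab
    if (cfg$symmetric) {
      cell2 <- (lj - 1L) * n + li
      counts <- counts + tabulate(cell2, nbins = n * n)
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no in-mask voxel pairs for the given offsets",
                       call. = FALSE)
  p <- counts / total
  P <- matrix(p, nrow = n, byrow = TRUE)   # P[i, j]
  nz <- p > 0
  d2 <- (row(P) - col(P))^2
  out <- c(entropy = -sum(p[nz] * log2(p[nz])),
           energy = sum(p^2),
           contrast = sum(P * d2),
           local_homogeneity = sum(P / (1 + d2)))
  attr(out, "degenerate") <- length(unique(lev[idx])) == 1L
  out
}

#' Extract the full feature vector for one patient
#'
#' Computes every pretherapeutic parameter on the total MTV: mtv, suv_max,
#' suv_mean, suv_peak, tlg (exactly mtv * suv_mean), asp (percent), entropy,
#' energy, contrast, local_homogeneity, csh_auc.
#'
#' @param image An `suv_image`.
#' @param seg A nonempty `segmentation`.
#' @param cfg A [texture_config()].
#' @param sphere_diameter_mm SUVpeak sphere diameter (mm).
#' @return Named numeric vector of the 11 features (class `feature_vector`).
#' @export
extract_all <- function(image, seg, cfg = texture_config(),
                        sphere_diameter_mm = 12) {
  .check_nonempty(seg)
  st <- suv_stats(image, seg)
  mtv <- sum(.mask_union(seg)) * voxel_volume_ml(seg$spacing)
  tex <- glcm_features(image, seg, cfg)
  out <- c(mtv = mtv,
           suv_max = unname(st["suv_max"]),
           suv_mean = unname(st["suv_mean"]),
           suv_peak = as.numeric(suv_peak(image, seg, sphere_diameter_mm)),
           tlg = tlg(mtv, unname(st["suv_mean"])),
           asp = asphericity(seg),
           entropy = unname(tex["entropy"]),
           energy = unname(tex["energy"]),
           contrast = unname(tex["contrast"]),
           local_homogeneity = unname(tex["local_homogeneity"]),
           csh_auc = csh_auc(image, seg))
  class(out) <- c("feature_vector", "numeric")
  out
}

#' Names of the features produced by [extract_all()]
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("mtv", "suv_max", "suv_mean", "suv_peak", "tlg", "asp", "entropy",
    "energy", "contrast", "local_homogeneity", "csh_auc")
}
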