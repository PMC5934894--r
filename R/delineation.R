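# Lesion delineation. Three thresholding schemes are provided:
#   * fixed absolute SUV threshold (conventional SUV 2.5),
#   * fixed fraction of the maximum activity (t41: 41% of max),
#   * iterative background-adapted threshold T = BG + q * (Imax - BG), with
#     the background BG estimated in a shell around the current mask.
# All schemes include voxels with SUV >= threshold (ties included), label
# connected components with 26-connectivity, and discard specks below
# `min_lesion_voxels`.

#' Delineation configuration
#'
#' @param method `"BG"` (background-adapted), `"t41"` (41% of max) or
#'   `"SUV2.5"` (fixed absolute threshold).
#' @param q Relative fraction for the background-adapted scheme (default
#'   0.39) or the relative-max scheme (0.41 for t41). Must lie in (0, 1).
#' @param absolute_threshold SUV threshold for the fixed scheme.
#' @param shell_inner,shell_outer Background shell radii in dilation steps:
#'   the shell is `dilate(mask, outer) \ dilate(mask, inner)`.
#' @param convergence_tol Stop when successive thresholds differ by less than
#'   this (SUV units).
#' @param max_iterations Iteration cap for the background-adapted scheme.
#' @param min_lesion_voxels Components smaller than this are discarded.
#' @return A `delineation_config` list.
#' @export
delineation_config <- function(method = c("BG", "t41", "SUV2.5"), q = NULL,
                               absolute_threshold = 2.5, shell_inner = 2L,
                               shell_outer = 4L, convergence_tol = 0.01,
                               max_iterations = 20L, min_lesion_voxels = 2L) {
  method <- match.arg(method)
  if (is.null(q)) q <- if (method == "t41") 0.41 else 0.39
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (convergence_tol <= 0) stop("convergence_tol must be > 0", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (shell_outer <= shell_inner) {
    stop("shell_outer must exceed shell_inner", call. = FALSE)
  }
  structure(list(method = method, q = q,
                 absolute_threshold = absolute_threshold,
                 shell_inner = as.integer(shell_inner),
                 shell_outer = as.integer(shell_outer),
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 min_lesion_voxels = as.integer(min_lesion_voxels)),
            class = "delineation_config")
}

# Normalize an roi argument: NULL (whole grid), a logical array, or a list
# with integer vectors lo/hi (inclusive voxel index bounds).
.roi_mask <- function(roi, dims) {
  if (is.null(roi)) return(array(TRUE, dims))
  if (is.array(roi)) {
    stopifnot(identical(dim(roi), dims))
    return(roi != 0)
  }
  m <- array(FALSE, dims)
  lo <- pmax(as.integer(roi$lo), 1L)
  hi <- pmin(as.integer(roi$hi), dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Delineate lesions at a fixed absolute SUV threshold
#'
#' @param image An `suv_image`.
#' @param threshold Absolute SUV threshold (> 0); voxels with SUV >=
#'   threshold are included.
#' @param roi Optional region restriction: logical array or
#'   `list(lo =, hi =)` voxel-index bounds.
#' @param min_lesion_voxels Minimum component size (default 2).
#' @return A `segmentation` (possibly with zero lesions).
#' @export
delineate_fixed <- function(image, threshold, roi = NULL,
                            min_lesion_voxels = 2L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  dims <- dim(image$voxels)
  mask <- (image$voxels >= threshold) & .roi_mask(roi, dims)
  labels <- label_components(mask, connectivity = 26L,
                             min_voxels = min_lesion_voxels)
  ids <- sort(unique(labels[labels > 0L]))
  thr <- stats::setNames(rep(threshold, length(ids)), as.character(ids))
  segmentation(labels, spacing = image$spacing, thresholds = thr)
}

#' Delineate lesions at a fraction of the maximum SUV
#'
#' The threshold is `fraction * max(SUV within roi)`; thereafter identical to
#' [delineate_fixed()]. The 41%-of-maximum scheme is `fraction = 0.41`.
#'
#' @inheritParams delineate_fixed
#' @param fraction Fraction of the in-roi maximum, in (0, 1).
#' @return A `segmentation`; attribute `threshold` carries the effective SUV
#'   threshold.
#' @export
delineate_relative_max <- function(image, fraction = 0.41, roi = NULL,
                                   min_lesion_voxels = 2L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  dims <- dim(image$voxels)
  rmask <- .roi_mask(roi, dims)
  if (!any(rmask)) stop("empty roi", call. = FALSE)
  mx <- max(image$voxels[rmask])
  if (mx <= 0) stop("degenerate roi: maximum SUV is 0", call. = FALSE)
  thr <- fraction * mx
  seg <- delineate_fixed(image, thr, roi = roi,
                         min_lesion_voxels = min_lesion_voxels)
  attr(seg, "threshold") <- thr
  seg
}

# Greedy hill climb to the local maximum reachable from a seed voxel.
.hill_climb <- function(voxels, seed) {
  dims <- dim(voxels)
  off <- .neighbor_offsets(26L)
  cur <- as.integer(seed)
  repeat {
    nb <- sweep(off, 2, cur, `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- voxels[nb]
    best <- which.max(vals)
    if (vals[best] > voxels[cur[1], cur[2], cur[3]]) cur <- nb[best, ]
    else return(cur)
  }
}

#' Background-adapted iterative delineation of one lesion
#'
#' Starting from a seed voxel, the algorithm hill-climbs to the local maximum
#' (SUV `Imax`), thresholds at `T0 = q * Imax`, and then iterates: the mask is
#' the connected component containing the maximum at the current threshold;
#' the background `BG` is the mean SUV in a shell obtained by dilating the
#' mask between the inner and outer shell radii (excluding the mask itself
#' and any voxels in `exclude`); the next threshold is
#' `T = BG + q * (Imax - BG)`. Iteration stops when successive thresholds
#' differ by less than `convergence_tol` or after `max_iterations` (recorded
#' as `converged = FALSE`). An empty shell falls back to the median SUV of all
#' non-mask voxels (logged in the result).
#'
#' @param image An `suv_image`.
#' @param seed Voxel index `c(i, j, k)` (1-based) inside or near the lesion;
#'   its SUV must exceed the image median.
#' @param config A [delineation_config()] with `method = "BG"`.
#' @param exclude Optional logical array of voxels belonging to other lesions,
#'   excluded from the background shell.
#' @return List with `segmentation` (single lesion), `iterations`,
#'   `threshold` (final SUV threshold), `background`, `imax`, `converged`,
#'   `shell_fallback`.
#' @export
delineate_background_adapted <- function(image, seed,
                                         config = delineation_config("BG"),
                                         exclude = NULL) {
  if (config$method != "BG") stop("config$method must be 'BG'", call. = FALSE)
  vox <- image$voxels
  dims <- dim(vox)
  seed <- as.integer(seed)
  if (vox[seed[1], seed[2], seed[3]] <= stats::median(vox)) {
    stop("seed SUV must exceed the image median", call. = FALSE)
  }
  if (is.null(exclude)) exclude <- array(FALSE, dims)
  peak <- .hill_climb(vox, seed)
  imax <- vox[peak[1], peak[2], peak[3]]
  q <- config$q
  thr <- q * imax
  iter <- 0L
  converged <- FALSE
  shell_fallback <- FALSE
  mask <- NULL
  bg <- 0
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    mask <- .component_containing(vox >= thr & !exclude, peak)
    inner <- dilate_mask(mask, config$shell_inner)
    outer <- dilate_mask(inner, config$shell_outer - config$shell_inner)
    shell <- outer & !inner & !mask & !exclude
    if (any(shell)) {
      bg <- mean(vox[shell])
    } else {
      bg <- stats::median(vox[!mask & !exclude])
      shell_fallback <- TRUE
    }
    # lesion may extend past the initial peak component; use its own max
    imax <- max(vox[mask])
    new_thr <- bg + q * (imax - bg)
    if (abs(new_thr - thr) < config$convergence_tol) {
      thr <- new_thr
      converged <- TRUE
      mask <- .component_containing(vox >= thr & !exclude, peak)
      break
    }
    thr <- new_thr
  }
  if (!converged) {
    warning("background-adapted delineation did not converge after ",
            config$max_iterations, " iterations", call. = FALSE)
  }
  labels <- array(0L, dims)
  labels[mask] <- 1L
  seg <- segmentation(labels, spacing = image$spacing,
                      thresholds = c(`1` = thr))
  list(segmentation = seg, iterations = iter, threshold = thr,
       background = bg, imax = imax, converged = converged,
       shell_fallback = shell_fallback)
}

#' Background-adapted delineation of multiple lesions
#'
#' Runs [delineate_background_adapted()] once per seed, excluding previously
#' delineated lesions from each background shell, and merges the per-lesion
#' masks into one labeled segmentation (labels in seed order).
#'
#' @param image An `suv_image`.
#' @param seeds List of voxel-index seeds, one per lesion.
#' @param config A [delineation_config()] with `method = "BG"`.
#' @return List with `segmentation`, per-lesion `thresholds`, `details`.
#' @export
delineate_bg_multi <- function(image, seeds,
                               config = delineation_config("BG")) {
  dims <- dim(image$voxels)
  labels <- array(0L, dims)
  exclude <- array(FALSE, dims)
  thresholds <- numeric(0)
  details <- list()
  for (k in seq_along(seeds)) {
    res <- delineate_background_adapted(image, seeds[[k]], config,
                                        exclude = exclude)
    mask <- res$segmentation$labels > 0L
    mask[labels > 0L] <- FALSE       # earlier lesions keep their label
    labels[mask] <- k
    exclude <- exclude | mask
    thresholds[as.character(k)] <- res$threshold
    details[[k]] <- res[c("iterations", "threshold", "background",
                          "converged", "shell_fallback")]
  }
  list(segmentation = segmentation(labels, spacing = image$spacing,
                                   thresholds = thresholds),
       thresholds = thresholds, details = details)
}

#' Manual-correction directive
#'
#' Encodes the two manual-correction modes used during visual review:
#' re-delineating a lesion at a manually chosen threshold, or delineating a
#' missed/merged sub-volume separately.
#'
#' @param mode `"override_threshold"` or `"split_subvolume"`.
#' @param target Lesion id to re-delineate (override mode).
#' @param value SUV threshold for override mode.
#' @param region `list(lo =, hi =)` voxel bounds (or logical array) for
#'   split mode.
#' @param fraction Relative-max fraction used inside the split region
#'   (default 0.41).
#' @return A `correction_directive` list.
#' @export
correction_directive <- function(mode = c("override_threshold",
                                          "split_subvolume"),
                                 target = NULL, value = NULL, region = NULL,
                                 fraction = 0.41) {
  mode <- match.arg(mode)
  if (mode == "override_threshold" && (is.null(target) || is.null(value))) {
    stop("override_threshold needs `target` and `value`", call. = FALSE)
  }
  if (mode == "split_subvolume" && is.null(region)) {
    stop("split_subvolume needs `region`", call. = FALSE)
  }
  structure(list(mode = mode, target = target, value = value,
                 region = region, fraction = fraction),
            class = "correction_directive")
}

#' Apply manual-correction directives to a segmentation
#'
#' `override_threshold` re-delineates the target lesion's region (its current
#' extent dilated by 2 voxels) at the given SUV; an empty result removes the
#' lesion with a warning. `split_subvolume` delineates independently inside
#' the given region (relative-max at `fraction`, restricted to voxels not
#' already labeled) and appends the result as new labels. Total MTV is
#' recomputed.
#'
#' @param image An `suv_image`.
#' @param seg A `segmentation` on the same grid.
#' @param directives List of [correction_directive()] objects.
#' @return Corrected `segmentation`.
#' @export
apply_corrections <- function(image, seg, directives) {
  labels <- seg$labels
  dims <- dim(labels)
  for (d in directives) {
    if (d$mode == "override_threshold") {
      tgt <- as.integer(d$target)
      if (!any(labels == tgt)) {
        stop("directive targets nonexistent lesion ", tgt, call. = FALSE)
      }
      region <- dilate_mask(labels == tgt, 2L)
      region[labels > 0L & labels != tgt] <- FALSE
      labels[labels == tgt] <- 0L
      newmask <- region & (image$voxels >= d$value)
      if (!any(newmask)) {
        warning("override_threshold removed lesion ", tgt, call. = FALSE)
      } else {
        labels[newmask] <- tgt
      }
    } else {
      rmask <- .roi_mask(d$region, dims)
      rmask[labels > 0L] <- FALSE
      if (!any(rmask)) {
        warning("split_subvolume region is empty; directive skipped",
                call. = FALSE)
        next
      }
      sub <- delineate_relative_max(image, fraction = d$fraction, roi = rmask,
                                    min_lesion_voxels = 2L)
      add <- sub$labels > 0L
      if (!any(add)) {
        warning("split_subvolume produced no lesion", call. = FALSE)
        next
      }
      labels[add] <- max(labels) + sub$labels[add]
    }
  }
  # compact label ids
  ids <- sort(unique(labels[labels > 0L]))
  remap <- integer(max(c(ids, 1L)))
  remap[ids] <- seq_along(ids)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  segmentation(labels, spacing = seg$spacing)
}

#' Total metabolic tumor volume across segmentations
#'
#' Combines segmentations on one grid into a single labeling (earlier
#' segmentations take precedence on overlapping voxels, so no voxel is
#' counted twice) and returns the summed lesion volume in ml.
#'
#' @param segs A `segmentation` or list of them (same grid shape and spacing).
#' @return Total MTV in ml.
#' @export
total_mtv <- function(segs) {
  if (inherits(segs, "segmentation")) segs <- list(segs)
  ref <- segs[[1]]
  covered <- array(FALSE, dim(ref$labels))
  for (s in segs) {
    if (!identical(dim(s$labels), dim(ref$labels)) ||
        max(abs(s$spacing - ref$spacing)) > 1e-6) {
      stop("segmentations are not aligned to one grid", call. = FALSE)
    }
    covered <- covered | (s$labels > 0L)
  }
  sum(covered) * voxel_volume_ml(ref$spacing)
}
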