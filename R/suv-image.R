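# Core imaging containers: SUVImage (3D SUV grid + geometry) and Segmentation
# (integer label grid + ml bookkeeping). Both are light S3 classes over base
# arrays; all volumes are tracked in ml (product of mm spacings / 1000).

#' Construct an SUV image
#'
#' @param voxels 3D numeric array of standardized uptake values (dimensionless,
#'   body-weight normalized). Must be finite and non-negative.
#' @param spacing Voxel edge lengths in mm, length 3, all positive.
#' @param origin Physical position (mm) of voxel (1,1,1)'s center.
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(voxels, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    stop("SUV values must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "suv_image"
  )
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<suv_image> %dx%dx%d voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Volume of one voxel in ml
#'
#' @param x An `suv_image` or `segmentation`, or a numeric spacing vector (mm).
#' @return Voxel volume in ml (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(x) {
  spacing <- if (is.numeric(x)) x else x$spacing
  prod(spacing) / 1000
}

#' Construct a segmentation from a label grid
#'
#' Labels are non-negative integers aligned to a source image grid: 0 is
#' background, k >= 1 identifies lesion k. Per-lesion volumes and the total
#' metabolic tumor volume (MTV, ml) are derived from voxel counts.
#'
#' @param labels 3D integer array (0 = background).
#' @param spacing Voxel spacing in mm (length 3).
#' @param thresholds Optional named numeric vector of per-lesion thresholds
#'   used during delineation (bookkeeping only).
#' @return An object of class `segmentation` with fields `labels`, `spacing`,
#'   `lesion_volumes` (named, ml), `total_mtv` (ml).
#' @export
segmentation <- function(labels, spacing = c(4, 4, 4), thresholds = NULL) {
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  vv <- voxel_volume_ml(as.numeric(spacing))
  ids <- sort(unique(labels[labels > 0L]))
  counts <- if (length(ids)) tabulate(labels, nbins = max(ids))[ids] else integer(0)
  vols <- counts * vv
  names(vols) <- as.character(ids)
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         lesion_volumes = vols, total_mtv = sum(vols),
         thresholds = thresholds),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d lesion(s), total MTV %.2f ml\n",
              length(x$lesion_volumes), x$total_mtv))
  if (length(x$lesion_volumes)) {
    for (id in names(x$lesion_volumes)) {
      cat(sprintf("  lesion %s: %.2f ml\n", id, x$lesion_volumes[[id]]))
    }
  }
  invisible(x)
}

#' Number of lesions in a segmentation
#' @param seg A `segmentation`.
#' @return Integer count of distinct non-background labels.
#' @export
n_lesions <- function(seg) length(seg$lesion_volumes)

#' Read an SUV volume from NIfTI
#'
#' @param path `.nii` or `.nii.gz` file with spacing encoded in the affine.
#' @return An `suv_image`.
#' @export
read_suv_image <- function(path) {
  v <- read_nifti_volume(path)
  suv_image(v$data, spacing = v$spacing, origin = v$origin)
}

#' Write an SUV volume to NIfTI (float32)
#' @param img An `suv_image`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_suv_image <- function(img, path) {
  write_nifti_volume(img$voxels, path, spacing = img$spacing,
                     origin = img$origin, datatype = "float32")
}

#' Read a label mask from NIfTI, validating alignment against an image
#'
#' @param path NIfTI mask path (integer labels).
#' @param image Optional `suv_image`; when given, grid shape and spacing must
#'   match (spacing within 1e-6) or an alignment error is raised.
#' @return A `segmentation`.
#' @export
read_mask <- function(path, image = NULL) {
  v <- read_nifti_volume(path)
  if (!is.null(image)) {
    if (!identical(dim(v$data), dim(image$voxels))) {
      stop("mask grid shape does not match image grid", call. = FALSE)
    }
    if (max(abs(v$spacing - image$spacing)) > 1e-6) {
      stop("mask spacing does not match image spacing", call. = FALSE)
    }
  }
  segmentation(round(v$data), spacing = v$spacing)
}

#' Write a segmentation's label grid to NIfTI (int16)
#' @param seg A `segmentation`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param origin Physical origin in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(seg, path, origin = c(0, 0, 0)) {
  write_nifti_volume(seg$labels, path, spacing = seg$spacing,
                     origin = origin, datatype = "int16")
}

#' Convert an activity-concentration grid to SUV
#'
#' SUV normalizes tissue activity concentration by injected activity per body
#' weight: `SUV = conc(Bq/ml) * weight(g) / activity(Bq)` (1 ml tissue ~ 1 g).
#'
#' @param concentration 3D array of activity concentration in Bq/ml.
#' @param injected_activity_mbq Injected activity in MBq (> 0).
#' @param body_weight_kg Body weight in kg (> 0).
#' @param spacing,origin Geometry passed through to the result.
#' @return An `suv_image`.
#' @export
activity_to_suv <- function(concentration, injected_activity_mbq,
                            body_weight_kg, spacing = c(4, 4, 4),
                            origin = c(0, 0, 0)) {
  if (!is.numeric(injected_activity_mbq) || injected_activity_mbq <= 0) {
    stop("`injected_activity_mbq` must be > 0", call. = FALSE)
  }
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be > 0", call. = FALSE)
  }
  suv <- concentration * (body_weight_kg * 1000) / (injected_activity_mbq * 1e6)
  suv_image(suv, spacing = spacing, origin = origin)
}
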