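# Synthetic 3D PET phantoms: analytic lesions voxelized onto an SUV grid,
# degraded by an isotropic Gaussian point-spread function (partial-volume
# effect) and additive Gaussian noise. Ground-truth label masks are defined
# before blur/noise, so delineation accuracy can be scored against a known
# answer without any external data.

#' Specify a single phantom lesion
#'
#' @param shape `"sphere"`, `"ellipsoid"`, `"cube"` or `"union_of_spheres"`.
#' @param center Lesion center in mm (length 3). For `union_of_spheres`, a
#'   matrix with one row per sphere.
#' @param size Size parameters in mm: sphere diameter; ellipsoid axis
#'   diameters (length 3); cube edge; union_of_spheres diameters (one per row
#'   of `center`).
#' @param uptake_suv Plateau SUV inside the lesion (> background).
#' @param gradient Optional radial uptake gradient in SUV per mm (negative =
#'   uptake falls off from center), applied before blur.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(shape = c("sphere", "ellipsoid", "cube",
                                  "union_of_spheres"),
                        center, size, uptake_suv, gradient = 0) {
  shape <- match.arg(shape)
  if (any(size <= 0)) stop("lesion size parameters must be > 0", call. = FALSE)
  if (uptake_suv <= 0) stop("uptake_suv must be > 0", call. = FALSE)
  if (shape == "union_of_spheres") {
    center <- rbind(center)
    if (length(size) != nrow(center)) {
      stop("union_of_spheres needs one diameter per center row", call. = FALSE)
    }
  }
  structure(list(shape = shape, center = center, size = size,
                 uptake_suv = uptake_suv, gradient = gradient),
            class = "lesion_spec")
}

#' Specify a synthetic PET phantom
#'
#' Defaults reproduce typical clinical whole-body PET conditions: 64^3 grid of
#' 4 mm isotropic voxels, soft-tissue background SUV 1.0 and a 7 mm FWHM
#' reconstruction point-spread function.
#'
#' @param grid_shape Integer grid dimensions (length 3).
#' @param spacing Voxel spacing in mm.
#' @param background_suv Background SUV level.
#' @param lesions List of [lesion_spec()] objects (must lie inside the grid).
#' @param psf_fwhm Isotropic Gaussian PSF full width at half maximum, mm (>= 0).
#' @param noise_sd Additive Gaussian noise standard deviation, SUV units (>= 0).
#' @param seed Integer RNG seed controlling the noise realization.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = c(4, 4, 4),
                         background_suv = 1.0, lesions = list(),
                         psf_fwhm = 7, noise_sd = 0, seed = 1L) {
  if (psf_fwhm < 0 || noise_sd < 0) {
    stop("psf_fwhm and noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 background_suv = background_suv, lesions = lesions,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxel-center coordinates (mm) along each axis; voxel (1,1,1) center sits at
# spacing/2 so the grid spans [0, dim * spacing].
.axis_centers <- function(n, h) (seq_len(n) - 0.5) * h

# Logical membership mask: voxel centers inside the analytic shape.
.voxelize_lesion <- function(lesion, grid_shape, spacing) {
  xs <- .axis_centers(grid_shape[1], spacing[1])
  ys <- .axis_centers(grid_shape[2], spacing[2])
  zs <- .axis_centers(grid_shape[3], spacing[3])
  inside <- array(FALSE, grid_shape)
  sphere_mask <- function(c0, radius) {
    dx2 <- (xs - c0[1])^2
    dy2 <- (ys - c0[2])^2
    dz2 <- (zs - c0[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  }
  switch(lesion$shape,
    sphere = sphere_mask(lesion$center, lesion$size[1] / 2),
    cube = {
      half <- lesion$size[1] / 2
      inx <- abs(xs - lesion$center[1]) <= half
      iny <- abs(ys - lesion$center[2]) <= half
      inz <- abs(zs - lesion$center[3]) <= half
      outer(outer(inx, iny, `&`), inz, `&`)
    },
    ellipsoid = {
      r <- lesion$size / 2
      dx2 <- ((xs - lesion$center[1]) / r[1])^2
      dy2 <- ((ys - lesion$center[2]) / r[2])^2
      dz2 <- ((zs - lesion$center[3]) / r[3])^2
      outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    },
    union_of_spheres = {
      for (i in seq_len(nrow(lesion$center))) {
        inside <- inside | sphere_mask(lesion$center[i, ], lesion$size[i] / 2)
      }
      inside
    })
}

#' Separable Gaussian blur of a 3D array
#'
#' Zero-padded separable convolution with a normalized Gaussian kernel
#' (truncated at 4 sigma). Conserves the array sum for structures away from
#' the grid border.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (scalar, isotropic).
#' @param spacing Voxel spacing in mm.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur3d <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma_vox <- (fwhm_mm / 2.354820045) / spacing
  dims <- dim(arr)
  conv_axis <- function(a, axis) {
    s <- sigma_vox[axis]
    if (s < 1e-8) return(a)
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    n <- dims[axis]
    # banded convolution matrix; rows renormalized at the grid border so a
    # constant field is preserved exactly (edge-clamp behavior)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      rows <- seq_len(n)
      cols <- rows + o
      ok <- cols >= 1 & cols <= n
      K[cbind(rows[ok], cols[ok])] <- k[o + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    res <- K %*% m
    ap2 <- array(res, dim = dims[perm])
    aperm(ap2, order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

#' Generate a phantom image and its ground-truth segmentation
#'
#' Lesions are voxelized (a voxel belongs to a lesion iff its center lies
#' inside the analytic shape), painted at their uptake (plus any radial
#' gradient) on the background, blurred by the PSF, and degraded with
#' additive Gaussian noise clipped at zero. Ground-truth labels are recorded
#' before blur and noise. Identical spec (including seed) gives bitwise
#' identical output; the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (an `suv_image`) and `truth` (a `segmentation`).
#' @export
generate_phantom <- function(spec) {
  dims <- spec$grid_shape
  extent <- dims * spec$spacing
  vox <- array(spec$background_suv, dims)
  labels <- array(0L, dims)
  for (k in seq_along(spec$lesions)) {
    lesion <- spec$lesions[[k]]
    ctr <- rbind(lesion$center)
    if (any(ctr < 0) || any(sweep(ctr, 2, extent) > 0)) {
      stop("lesion ", k, " center lies outside the grid", call. = FALSE)
    }
    inside <- .voxelize_lesion(lesion, dims, spec$spacing)
    if (any(labels[inside] != 0L)) {
      stop("lesion ", k, " overlaps an earlier lesion", call. = FALSE)
    }
    if (lesion$uptake_suv <= spec$background_suv) {
      stop("lesion ", k, " uptake must exceed the background", call. = FALSE)
    }
    labels[inside] <- k
    vox[inside] <- lesion$uptake_suv
    if (!identical(lesion$gradient, 0) && lesion$gradient != 0) {
      idx <- which(inside)
      co <- arrayInd(idx, dims)
      centers <- cbind(.axis_centers(dims[1], spec$spacing[1])[co[, 1]],
                       .axis_centers(dims[2], spec$spacing[2])[co[, 2]],
                       .axis_centers(dims[3], spec$spacing[3])[co[, 3]])
      c0 <- if (lesion$shape == "union_of_spheres") colMeans(rbind(lesion$center))
            else lesion$center
      dist <- sqrt(rowSums(sweep(centers, 2, c0)^2))
      vox[idx] <- pmax(vox[idx] + lesion$gradient * dist, spec$background_suv)
    }
  }
  vox <- gaussian_blur3d(vox, spec$psf_fwhm, spec$spacing)
  if (spec$noise_sd > 0) {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(length(vox), sd = spec$noise_sd), dims)
  }
  vox <- pmax(vox, 0)
  list(image = suv_image(vox, spacing = spec$spacing),
       truth = segmentation(labels, spacing = spec$spacing))
}

#' Named reference phantom suite
#'
#' Fixed fixtures exercising the delineation and feature pathways:
#' `calibration_sphere` (30 mm sphere, uptake 10), `cube` (40 mm edge, 64 ml),
#' `two_lesion` (a bright and a low-uptake lesion, the configuration that
#' requires a manual sub-volume correction), `gradient` (radially decreasing
#' intra-lesion uptake) and three additional spheres spanning 18-50 mm for
#' size-dependence checks.
#'
#' @param psf_fwhm PSF FWHM in mm applied to every fixture.
#' @param noise_sd Noise SD applied to every fixture.
#' @return Named list of [phantom_spec()] objects with attribute
#'   `expected` holding per-fixture ground-truth summaries (label count and
#'   total ground-truth volume in ml where analytic).
#' @export
reference_phantom_suite <- function(psf_fwhm = 7, noise_sd = 0) {
  mid <- c(128, 128, 128)   # grid center in mm for 64^3 @ 4 mm
  sphere <- function(d, uptake = 10, center = mid)
    lesion_spec("sphere", center, d, uptake)
  specs <- list(
    calibration_sphere = phantom_spec(
      lesions = list(sphere(30)), psf_fwhm = psf_fwhm, noise_sd = noise_sd,
      seed = 101L),
    cube = phantom_spec(
      lesions = list(lesion_spec("cube", mid, 40, 10)),
      psf_fwhm = psf_fwhm, noise_sd = noise_sd, seed = 102L),
    two_lesion = phantom_spec(
      lesions = list(sphere(34, uptake = 10, center = c(88, 128, 128)),
                     sphere(22, uptake = 3, center = c(180, 128, 128))),
      psf_fwhm = psf_fwhm, noise_sd = noise_sd, seed = 103L),
    gradient = phantom_spec(
      lesions = list(lesion_spec("sphere", mid, 36, 12, gradient = -0.35)),
      psf_fwhm = psf_fwhm, noise_sd = noise_sd, seed = 104L),
    sphere_small = phantom_spec(
      lesions = list(sphere(18)), psf_fwhm = psf_fwhm, noise_sd = noise_sd,
      seed = 105L),
    sphere_medium = phantom_spec(
      lesions = list(sphere(40)), psf_fwhm = psf_fwhm, noise_sd = noise_sd,
      seed = 106L),
    sphere_large = phantom_spec(
      lesions = list(sphere(50)), psf_fwhm = psf_fwhm, noise_sd = noise_sd,
      seed = 107L)
  )
  expected <- list(
    calibration_sphere = list(n_lesions = 1L, analytic_ml = 4 / 3 * pi * 15^3 / 1000),
    cube = list(n_lesions = 1L, analytic_ml = 64),
    two_lesion = list(n_lesions = 2L, analytic_ml = NA_real_),
    gradient = list(n_lesions = 1L, analytic_ml = 4 / 3 * pi * 18^3 / 1000),
    sphere_small = list(n_lesions = 1L, analytic_ml = 4 / 3 * pi * 9^3 / 1000),
    sphere_medium = list(n_lesions = 1L, analytic_ml = 4 / 3 * pi * 20^3 / 1000),
    sphere_large = list(n_lesions = 1L, analytic_ml = 4 / 3 * pi * 25^3 / 1000)
  )
  attr(specs, "expected") <- expected
  specs
}
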