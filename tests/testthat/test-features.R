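make_gradient_fixture <- function() {
  generate_phantom(phantom_spec(
    grid_shape = c(20, 20, 20), spacing = c(4, 4, 4),
    lesions = list(lesion_spec("sphere", c(40, 40, 40), 30, 12,
                               gradient = -0.3)),
    psf_fwhm = 0))
}

test_that("suv_stats matches the exhaustive oracle and simple cases", {
  ph <- plateau_sphere_phantom(uptake = 10)
  st <- suv_stats(ph$image, ph$truth)
  expect_equal(unname(st), c(10, 10))

  # two-voxel hand case
  vox <- array(1, c(4, 4, 4)); vox[2, 2, 2] <- 10; vox[3, 2, 2] <- 5
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L; lab[3, 2, 2] <- 1L
  st2 <- suv_stats(suv_image(vox), segmentation(lab))
  expect_equal(unname(st2), c(10, 7.5))

  # gradient phantom vs brute force over the mask
  g <- make_gradient_fixture()
  vals <- g$image$voxels[g$truth$labels > 0]
  st3 <- suv_stats(g$image, g$truth)
  expect_equal(unname(st3["suv_max"]), max(vals))
  expect_equal(unname(st3["suv_mean"]), mean(vals))

  expect_error(suv_stats(g$image, segmentation(array(0L, c(20, 20, 20)),
                                               spacing = c(4, 4, 4))),
               "empty")
})

test_that("suv_peak equals the enumeration oracle", {
  # uniform lesion much larger than the sphere: peak == max
  ph <- plateau_sphere_phantom(diameter = 40, uptake = 8)
  expect_equal(as.numeric(suv_peak(ph$image, ph$truth)), 8)

  # 12 mm sphere on 4 mm voxels: centers within 6 mm = 19 voxels
  nb <- oracle_peak_neighborhood(c(4, 4, 4), 6)
  expect_equal(nrow(nb), 19L)

  # single hot voxel on background 1: mean over the enumerated sphere
  vox <- array(1, c(9, 9, 9)); vox[5, 5, 5] <- 10
  lab <- array(0L, c(9, 9, 9)); lab[5, 5, 5] <- 1L
  got <- as.numeric(suv_peak(suv_image(vox), segmentation(lab)))
  expect_equal(got, (10 + 18 * 1) / 19)

  # grid-clipped: hot voxel in the corner
  vox2 <- array(1, c(9, 9, 9)); vox2[1, 1, 1] <- 10
  lab2 <- array(0L, c(9, 9, 9)); lab2[1, 1, 1] <- 1L
  pk <- suv_peak(suv_image(vox2), segmentation(lab2))
  expect_true(attr(pk, "clipped"))
  # corner keeps center + 3 face + 3 edge-diagonal voxels of the 19-voxel
  # sphere (all-positive offsets): mean = (10 + 6) / 7
  expect_equal(as.numeric(pk), (10 + 6) / 7)
})

test_that("tlg is the exact product and holds in every extraction", {
  expect_equal(tlg(100, 5), 500)
  expect_equal(tlg(0, 123), 0)
  expect_error(tlg(-1, 5), ">= 0")
  g <- make_gradient_fixture()
  fv <- extract_all(g$image, g$truth)
  expect_identical(fv[["tlg"]], fv[["mtv"]] * fv[["suv_mean"]])
})

test_that("csh_auc handles uniform, two-voxel and scaling cases", {
  ph <- plateau_sphere_phantom(uptake = 10)
  expect_gte(csh_auc(ph$image, ph$truth), 0.995)

  vox <- array(0.01, c(4, 4, 4)); vox[2, 2, 2] <- 10; vox[3, 2, 2] <- 5
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L; lab[3, 2, 2] <- 1L
  auc <- csh_auc(suv_image(vox), segmentation(lab))
  expect_equal(auc, 0.75, tolerance = 0.011)   # one trapezoid width

  # invariance under positive scaling of all SUVs
  g <- make_gradient_fixture()
  a1 <- csh_auc(g$image, g$truth)
  img2 <- suv_image(g$image$voxels * 3.7, spacing = g$image$spacing)
  expect_equal(csh_auc(img2, g$truth), a1, tolerance = 1e-12)
  expect_true(a1 > 0 && a1 <= 1)
})

test_that("glcm features match the hand-enumerated 3-voxel case", {
  # mask of 3 voxels along x with quantized levels [1, 1, 2]
  vox <- array(0, c(5, 3, 3))
  vox[2, 2, 2] <- 1; vox[3, 2, 2] <- 1; vox[4, 2, 2] <- 2
  lab <- array(0L, c(5, 3, 3)); lab[2:4, 2, 2] <- 1L
  cfg <- texture_config(n_gray_levels = 2L,
                        offsets = matrix(c(1, 0, 0), nrow = 1))
  f <- glcm_features(suv_image(vox), segmentation(lab), cfg)
  expect_equal(unname(f["entropy"]), 1.5)
  expect_equal(unname(f["energy"]), 0.375)
  expect_equal(unname(f["contrast"]), 0.5)
  expect_equal(unname(f["local_homogeneity"]), 0.75)
})

test_that("glcm features equal the brute-force oracle on random masks", {
  set.seed(21)
  for (rep in 1:3) {
    dims <- c(7, 6, 5)
    vox <- array(runif(prod(dims), 0, 10), dims)
    mask <- array(runif(prod(dims)) < 0.4, dims)
    if (sum(mask) < 2) next
    cfg <- texture_config(n_gray_levels = 8L)
    f <- glcm_features(suv_image(vox), seg_from_mask(mask), cfg)
    o <- oracle_glcm(vox, mask, 8L, cfg$offsets)
    expect_equal(as.numeric(f), unname(o), tolerance = 1e-12)
  }
})

test_that("glcm degenerate and bound properties hold", {
  ph <- plateau_sphere_phantom(uptake = 10)
  f <- glcm_features(ph$image, ph$truth)
  expect_equal(as.numeric(f), c(0, 1, 0, 1))
  expect_true(attr(f, "degenerate"))

  set.seed(5)
  g <- make_gradient_fixture()
  img <- suv_image(g$image$voxels +
                     array(abs(rnorm(20^3, 0, 0.2)), c(20, 20, 20)),
                   spacing = c(4, 4, 4))
  for (nlev in c(8L, 64L)) {
    f <- glcm_features(img, g$truth, texture_config(n_gray_levels = nlev))
    expect_lte(f[["energy"]], 1)
    expect_gt(f[["energy"]], 0)
    expect_lte(f[["entropy"]], log2(as.numeric(nlev)^2))
    expect_gte(f[["entropy"]], 0)
    expect_gte(f[["contrast"]], 0)
    expect_true(f[["local_homogeneity"]] > 0 && f[["local_homogeneity"]] <= 1)
  }
})

test_that("asphericity: sphere near 0, cube and two-sphere closed forms", {
  # 30 mm sphere at 2 mm voxels
  sp <- generate_phantom(phantom_spec(
    grid_shape = c(32, 32, 32), spacing = c(2, 2, 2),
    lesions = list(lesion_spec("sphere", c(32, 32, 32), 30, 10)),
    psf_fwhm = 0))
  expect_lt(asphericity(sp$truth), 3)

  # cube: 100 * ((6/pi)^(1/3) - 1) = 24.1% in the continuous limit;
  # two-resolution convergence with Richardson check (error ~ linear in h)
  cube_limit <- 100 * ((6 / pi)^(1 / 3) - 1)
  asp4 <- asphericity(plateau_cube_phantom(h = 4, n = 20)$truth)
  asp2 <- asphericity(plateau_cube_phantom(h = 2, n = 40)$truth)
  expect_lt(abs(asp2 - cube_limit), abs(asp4 - cube_limit))
  expect_lt(abs(2 * asp2 - asp4 - cube_limit), 2)

  # two disjoint equal spheres: 100 * (2^(1/3) - 1) = 26.0%
  two <- generate_phantom(phantom_spec(
    grid_shape = c(48, 48, 48), spacing = c(2, 2, 2),
    lesions = list(lesion_spec("sphere", c(30, 48, 48), 30, 10),
                   lesion_spec("sphere", c(70, 48, 48), 30, 10)),
    psf_fwhm = 0))
  expect_equal(asphericity(two$truth), 100 * (2^(1 / 3) - 1), tolerance = 0.2)

  # voxel-face counting overestimates the sphere surface
  expect_gt(mask_surface_area(sp$truth$labels > 0, c(2, 2, 2), "voxel"),
            1.3 * mask_surface_area(sp$truth$labels > 0, c(2, 2, 2)))
})

test_that("asphericity is translation-invariant within discretization", {
  a <- generate_phantom(phantom_spec(
    grid_shape = c(32, 32, 32), spacing = c(2, 2, 2),
    lesions = list(lesion_spec("sphere", c(32, 32, 32), 30, 10)),
    psf_fwhm = 0))
  b <- generate_phantom(phantom_spec(
    grid_shape = c(32, 32, 32), spacing = c(2, 2, 2),
    lesions = list(lesion_spec("sphere", c(35, 33, 31), 30, 10)),
    psf_fwhm = 0))
  expect_lt(abs(asphericity(a$truth) - asphericity(b$truth)), 1.5)
  # scale invariance: same shape at two grid scales
  big <- generate_phantom(phantom_spec(
    grid_shape = c(32, 32, 32), spacing = c(4, 4, 4),
    lesions = list(lesion_spec("sphere", c(64, 64, 64), 60, 10)),
    psf_fwhm = 0))
  expect_lt(abs(asphericity(a$truth) - asphericity(big$truth)), 1.5)
})

test_that("extract_all composes the per-feature oracles", {
  ph <- plateau_sphere_phantom(diameter = 40, uptake = 8, n = 24)
  fv <- extract_all(ph$image, ph$truth)
  expect_equal(fv[["suv_max"]], 8)
  expect_equal(fv[["suv_mean"]], 8)
  expect_equal(fv[["suv_peak"]], 8)
  expect_lt(fv[["asp"]], 3)
  expect_gte(fv[["csh_auc"]], 0.995)
  expect_equal(fv[["entropy"]], 0)
  expect_equal(sort(names(fv)), sort(feature_names()))

  g <- make_gradient_fixture()
  fv2 <- extract_all(g$image, g$truth)
  vals <- g$image$voxels[g$truth$labels > 0]
  expect_equal(fv2[["suv_max"]], max(vals))
  expect_equal(fv2[["mtv"]], sum(g$truth$labels > 0) * 0.064)
  o <- oracle_glcm(g$image$voxels, g$truth$labels > 0, 64L,
                   texture_config()$offsets)
  expect_equal(fv2[["entropy"]], unname(o["entropy"]), tolerance = 1e-12)
  expect_equal(fv2[["contrast"]], unname(o["contrast"]), tolerance = 1e-12)
  # invariants
  expect_lte(fv2[["suv_mean"]], fv2[["suv_max"]])
  expect_lte(fv2[["suv_peak"]], fv2[["suv_max"]])
  expect_gte(fv2[["asp"]], 0)
})
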