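test_that("fixed threshold recovers plateau phantoms exactly", {
  ph <- plateau_cube_phantom(uptake = 10, h = 4, n = 20)
  seg <- delineate_fixed(ph$image, 2.5)
  expect_equal(seg$total_mtv, ph$truth$total_mtv)
  # threshold above the lesion maximum: nothing segmented
  seg0 <- delineate_fixed(ph$image, 11)
  expect_equal(n_lesions(seg0), 0L)
  expect_equal(seg0$total_mtv, 0)
})

test_that("fixed threshold separates two lesions with correct volumes", {
  spec <- phantom_spec(grid_shape = c(32, 16, 16), spacing = c(4, 4, 4),
                       lesions = list(lesion_spec("sphere", c(32, 32, 32), 24, 10),
                                      lesion_spec("sphere", c(96, 32, 32), 16, 6)),
                       psf_fwhm = 0)
  ph <- generate_phantom(spec)
  seg <- delineate_fixed(ph$image, 2.5)
  expect_equal(n_lesions(seg), 2L)
  # volumes match ground truth per lesion (order: decreasing size)
  got <- sort(as.numeric(seg$lesion_volumes))
  want <- sort(as.numeric(ph$truth$lesion_volumes))
  expect_equal(got, want)
})

test_that("relative-max threshold equals fraction times roi maximum", {
  ph <- plateau_cube_phantom(uptake = 10, h = 4, n = 20)
  seg <- delineate_relative_max(ph$image, 0.41)
  expect_equal(attr(seg, "threshold"), 4.1)
  expect_equal(seg$total_mtv, ph$truth$total_mtv)   # 1 < 4.1 < 10 plateau
  expect_error(delineate_relative_max(ph$image, 1.2), "0, 1")
  z <- suv_image(array(0, c(8, 8, 8)))
  expect_error(delineate_relative_max(z, 0.41), "degenerate")
})

test_that("all schemes agree with the exhaustive-scan oracle on small grids", {
  set.seed(11)
  for (rep in 1:4) {
    vox <- array(runif(10 * 9 * 8, 0, 10), c(10, 9, 8))
    img <- suv_image(vox, spacing = c(4, 4, 4))
    for (thr in c(2.5, 5, 8)) {
      oracle <- oracle_threshold_label(vox, thr, min_voxels = 2L)
      seg <- delineate_fixed(img, thr)
      expect_identical(seg$labels > 0L, oracle$labels > 0L)
      sizes <- sort(as.integer(round(seg$lesion_volumes /
                                       voxel_volume_ml(seg))),
                    decreasing = TRUE)
      expect_identical(sizes, as.integer(oracle$sizes))
    }
    # relative scheme reduces to fixed at fraction * max
    fr <- 0.41
    oracle <- oracle_threshold_label(vox, fr * max(vox), min_voxels = 2L)
    segr <- delineate_relative_max(img, fr)
    expect_identical(segr$labels > 0L, oracle$labels > 0L)
  }
})

test_that("MTV is non-increasing in the threshold", {
  set.seed(3)
  vox <- array(runif(12^3, 0, 10), c(12, 12, 12))
  img <- suv_image(vox, spacing = c(4, 4, 4))
  mtvs <- vapply(seq(0.5, 9.5, by = 0.5),
                 function(t) delineate_fixed(img, t)$total_mtv, numeric(1))
  expect_true(all(diff(mtvs) <= 0))
})

test_that("background-adapted scheme reaches its closed-form fixed point", {
  # plateau lesion 10 on background 1, q = 0.39: T* = 1 + 0.39 * 9 = 4.51
  ph <- plateau_sphere_phantom(diameter = 30, uptake = 10, h = 4, n = 24)
  res <- delineate_background_adapted(ph$image, c(12, 12, 12))
  expect_equal(res$threshold, 4.51, tolerance = 1e-9)
  expect_lte(res$iterations, 3L)
  expect_true(res$converged)
  expect_identical(res$segmentation$labels, ph$truth$labels)

  # zero background: reduces to relative-max at q
  vox <- array(0, c(12, 12, 12))
  vox[5:8, 5:8, 5:8] <- 10
  img <- suv_image(vox, spacing = c(4, 4, 4))
  res0 <- delineate_background_adapted(img, c(6, 6, 6))
  expect_equal(res0$threshold, 0.39 * 10, tolerance = 1e-9)
  ref <- delineate_relative_max(img, 0.39)
  expect_identical(res0$segmentation$labels > 0L, ref$labels > 0L)
})

test_that("background-adapted volume recovery on the blurred sphere", {
  # 30 mm sphere, FWHM 7 mm, default clinical grid; regression-pinned bound
  ph <- generate_phantom(phantom_spec(
    lesions = list(lesion_spec("sphere", c(128, 128, 128), 30, 10)),
    psf_fwhm = 7))
  res <- delineate_background_adapted(ph$image, c(32, 32, 32))
  rel_err <- res$segmentation$total_mtv / ph$truth$total_mtv - 1
  expect_lt(abs(rel_err), 0.15)
})

test_that("corrections: split_subvolume recovers a missed low-uptake lesion", {
  suite <- reference_phantom_suite(psf_fwhm = 0)
  ph <- generate_phantom(suite$two_lesion)
  # BG run from a seed in the bright lesion only
  res <- delineate_background_adapted(ph$image, c(22, 32, 32))
  expect_equal(n_lesions(res$segmentation), 1L)
  # threshold sits above the second lesion's uptake (3), so it was missed
  expect_gt(res$threshold, 3)
  d <- correction_directive("split_subvolume",
                            region = list(lo = c(35, 20, 20),
                                          hi = c(60, 44, 44)))
  fixed <- apply_corrections(ph$image, res$segmentation, list(d))
  expect_equal(n_lesions(fixed), 2L)
  expect_equal(fixed$total_mtv,
               sum(res$segmentation$total_mtv,
                   ph$truth$lesion_volumes[["2"]]))
})

test_that("corrections: identity and threshold-override monotonicity", {
  ph <- plateau_cube_phantom()
  seg <- delineate_fixed(ph$image, 2.5)
  expect_identical(apply_corrections(ph$image, seg, list())$labels,
                   seg$labels)
  # raising the threshold above the lesion max removes it
  d <- correction_directive("override_threshold", target = 1L, value = 99)
  expect_warning(out <- apply_corrections(ph$image, seg, list(d)), "removed")
  expect_equal(n_lesions(out), 0L)
  # raising to an intermediate value cannot increase MTV
  d2 <- correction_directive("override_threshold", target = 1L, value = 5)
  out2 <- apply_corrections(ph$image, seg, list(d2))
  expect_lte(out2$total_mtv, seg$total_mtv)
})

test_that("total_mtv adds disjoint lesions and never double-counts", {
  lab1 <- array(0L, c(10, 10, 10)); lab1[2:4, 2:4, 2:4] <- 1L
  lab2 <- array(0L, c(10, 10, 10)); lab2[6:8, 6:8, 6:8] <- 1L
  s1 <- segmentation(lab1, spacing = c(4, 4, 4))
  s2 <- segmentation(lab2, spacing = c(4, 4, 4))
  expect_equal(total_mtv(list(s1, s2)), s1$total_mtv + s2$total_mtv)
  # identical duplicated lesion counts once
  expect_equal(total_mtv(list(s1, s1)), s1$total_mtv)
  # grid mismatch
  s3 <- segmentation(array(0L, c(9, 10, 10)), spacing = c(4, 4, 4))
  expect_error(total_mtv(list(s1, s3)), "aligned")
})

test_that("BG and t41 agree across lesion sizes; SUV2.5 diverges on low contrast", {
  suite <- reference_phantom_suite(psf_fwhm = 7)
  sizes <- c("calibration_sphere", "sphere_small", "sphere_medium",
             "sphere_large", "cube")
  bg <- t41 <- s25 <- numeric(0)
  for (nm in sizes) {
    ph <- generate_phantom(suite[[nm]])
    ctr <- round(dim(ph$image$voxels) / 2)
    bg[nm] <- delineate_background_adapted(ph$image, ctr)$segmentation$total_mtv
    t41[nm] <- delineate_relative_max(ph$image, 0.41)$total_mtv
    s25[nm] <- delineate_fixed(ph$image, 2.5)$total_mtv
  }
  expect_gt(cor(bg, t41), 0.95)
  # low-contrast fixture: second lesion peaks near SUV 3 after blur
  two <- generate_phantom(suite$two_lesion)
  mtv_25 <- delineate_fixed(two$image, 2.5)$total_mtv
  mtv_41 <- delineate_relative_max(two$image, 0.41)$total_mtv
  gt <- two$truth$total_mtv
  # absolute 2.5 threshold grossly over-segments relative to ground truth
  expect_gt(abs(mtv_25 - gt), abs(mtv_41 - gt))
})
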