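test_that("pre-processing is an identity at sigma zero and on constants", {
  ph <- clean_phantom(seed = 7)
  cfg0 <- expert_config(smoothing_sigma = 0)
  expect_identical(preprocess(ph$volume, cfg0)$voxels, ph$volume$voxels)
  const <- ct_volume(array(123, c(6, 8, 8)), c(1, 1, 1))
  sm <- preprocess(const, expert_config(smoothing_sigma = 2))
  expect_equal(sm$voxels, const$voxels, tolerance = 1e-12)
})

test_that("smoothing a point source reproduces the discrete kernel weight", {
  ns <- asNamespace("vesselseg")
  vox <- array(0, c(9, 9, 9)); vox[5, 5, 5] <- 1000
  vol <- ct_volume(vox, c(1, 1, 1), clamp = FALSE)
  sm <- preprocess(vol, expert_config(smoothing_sigma = 1))
  # oracle: separable product of normalised 1D kernels at the centre
  K <- ns$gauss_kernel_matrix(9, 1)
  expect_equal(sm$voxels[5, 5, 5], 1000 * K[5, 5]^3, tolerance = 1e-10)
})

test_that("the morphological active contour recovers a bright disk", {
  set.seed(2)
  img <- matrix(40 + rnorm(64 * 64, sd = 5), 64, 64)
  rr <- outer((1:64 - 30)^2, (1:64 - 36)^2, "+")
  img[rr <= 12^2] <- 300
  init <- matrix(FALSE, 64, 64); init[25:35, 31:41] <- TRUE
  res <- morph_acwe(img, init, iterations = 30)
  truth <- rr <= 12^2
  expect_gt(mask_dice(array(res, c(1, 64, 64)), array(truth, c(1, 64, 64))),
            0.95)
  res2 <- morph_acwe(img, init, iterations = 30)
  expect_identical(res, res2)   # fully deterministic
})

test_that("spine segmentation recovers the vertebral column", {
  ph0 <- generate_phantom(phantom_spec(seed = 5, noise_sd = 0, n_slices = 16))
  cfg <- expert_config()
  pre <- preprocess(ph0$volume, cfg)
  sp <- segment_spine(pre, cfg)
  truth <- ph0$masks$spine$voxels
  expect_equal(sum(truth == 1 & sp$voxels == 0), 0)  # mask covers the truth
  expect_gte(mask_dice(sp, ph0$masks$spine), 0.95)
})

test_that("an air-only volume yields an empty spine mask with a warning", {
  vol <- ct_volume(array(-1000, c(8, 16, 16)), c(1, 1, 1))
  expect_warning(sp <- segment_spine(vol, expert_config()), "empty")
  expect_equal(sum(sp$voxels), 0)
})

test_that("a bright anterior blob is excluded by the posterior restriction", {
  vox <- array(40, c(8, 64, 64))
  vox[, 15:25, 28:38] <- 300   # anterior lumen-like blob above threshold
  vox[, 45:55, 28:38] <- 700   # posterior bone
  vol <- ct_volume(vox, c(1, 1, 1))
  sp <- segment_spine(vol, expert_config(smoothing_sigma = 0))
  idx <- which(sp$voxels == 1, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  expect_true(all(idx[, 2] > 32))
})

test_that("lumen segmentation tracks a clean aneurysmal vessel", {
  ph <- clean_phantom(seed = 7)
  lab <- expert_labels(ph)
  prov <- attr(lab$lumen, "provenance")
  expect_equal(prov$status, "ok")
  expect_equal(prov$seed_source, "expert")
  expect_gte(mask_dice(lab$lumen, ph$masks$lumen), 0.85)
})

test_that("a straight noise-free cylinder gives constant per-slice area", {
  ph <- generate_phantom(phantom_spec(seed = 2, noise_sd = 0, bulge = FALSE,
                                      thrombus = FALSE, n_slices = 12))
  cfg <- expert_config()
  pre <- preprocess(ph$volume, cfg)
  lum <- segment_lumen(pre, segment_spine(pre, cfg), cfg)
  areas <- apply(lum$voxels, 1, sum)
  expect_true(all(areas > 0))
  # constant up to one boundary-voxel ring per slice
  perimeter <- 2 * pi * (ph$spec$lumen_radius_mm / 0.8)
  expect_lte(max(areas) - min(areas), perimeter)
})

test_that("very low contrast yields the documented lumen-not-found failure", {
  ph <- generate_phantom(phantom_spec(seed = 4, contrast_scale = 0.3,
                                      noise_sd = 30, n_slices = 10))
  cfg <- expert_config()
  pre <- preprocess(ph$volume, cfg)
  lum <- segment_lumen(pre, segment_spine(pre, cfg), cfg)
  prov <- attr(lum, "provenance")
  failed <- prov$status == "lumen-not-found"
  degraded <- mask_dice(lum, ph$masks$lumen) < 0.5
  expect_true(failed || degraded)
  if (failed) expect_equal(sum(lum$voxels), 0)
})

test_that("the thrombus snake segments a noise-free crescent accurately", {
  ph <- generate_phantom(phantom_spec(seed = 1, noise_sd = 0, n_slices = 16))
  cfg <- expert_config()
  pre <- preprocess(ph$volume, cfg)
  thr <- segment_thrombus(pre, ph$masks$lumen, cfg)
  truth <- ph$masks$thrombus$voxels
  z <- which.max(apply(truth, 1, sum))
  expect_gte(mask_dice(array(thr$voxels[z, , ], c(1, 128, 128)),
                       array(truth[z, , ], c(1, 128, 128))), 0.85)
  expect_equal(sum(thr$voxels & ph$masks$lumen$voxels), 0)  # disjoint
})

test_that("the thrombus snake requires a lumen and stays bounded without one", {
  ph <- clean_phantom(seed = 7)
  cfg <- expert_config()
  pre <- preprocess(ph$volume, cfg)
  empty <- binary_mask(array(0L, dim(pre$voxels)), "lumen", pre$spacing)
  expect_error(segment_thrombus(pre, empty, cfg), "empty lumen")
  # no thrombus in truth: detections are bounded by the dilation annulus
  ph2 <- generate_phantom(phantom_spec(seed = 6, thrombus = FALSE,
                                       n_slices = 10))
  pre2 <- preprocess(ph2$volume, cfg)
  thr2 <- segment_thrombus(pre2, ph2$masks$lumen, cfg)
  r_dil <- round(cfg$thrombus_dilation_mm / 0.8)
  annulus_bound <- pi * ((ph2$spec$lumen_radius_mm / 0.8 + r_dil)^2 -
                           (ph2$spec$lumen_radius_mm / 0.8)^2)
  expect_true(all(apply(thr2$voxels, 1, sum) <= annulus_bound))
})

test_that("a thrombus with background-identical HU terminates cleanly", {
  spec <- phantom_spec(seed = 8, n_slices = 10,
                       hu = list(background = c(40, 15), bone = c(700, 100),
                                 lumen = c(300, 30), thrombus = c(40, 15)))
  ph <- generate_phantom(spec)
  cfg <- expert_config()
  pre <- preprocess(ph$volume, cfg)
  thr <- segment_thrombus(pre, ph$masks$lumen, cfg)  # only termination is owed
  expect_true(inherits(thr, "binary_mask"))
})

test_that("lumen recovery degrades monotonically with contrast", {
  cfg <- expert_config()
  levels <- c(1.0, 0.7, 0.4)
  mean_dice <- vapply(levels, function(cs) {
    ds <- vapply(1:10, function(s) {
      ph <- generate_phantom(phantom_spec(seed = 700 + s, n_slices = 8,
                                          contrast_scale = cs,
                                          slice_shape = c(96, 96),
                                          lumen_radius_mm = 6,
                                          bulge_radius_mm = 11,
                                          thrombus_thickness_mm = 4))
      pre <- preprocess(ph$volume, cfg)
      lum <- segment_lumen(pre, segment_spine(pre, cfg), cfg)
      mask_dice(lum, ph$masks$lumen)
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(mean_dice) <= 0))
})

test_that("expert configuration round-trips through YAML with all defaults", {
  cfg <- expert_config(bone_threshold = 250)
  f <- tempfile(fileext = ".yaml")
  write_expert_config(cfg, f)
  txt <- yaml::read_yaml(f)
  expect_true(all(names(unclass(cfg)) %in% names(txt)))
  back <- read_expert_config(f)
  expect_equal(unclass(back), unclass(cfg))
})
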