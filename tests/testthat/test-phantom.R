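test_that("phantom generation is deterministic under its seed", {
  s <- phantom_spec(seed = 21, n_slices = 10)
  a <- generate_phantom(s); b <- generate_phantom(s)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$masks$lumen$voxels, b$masks$lumen$voxels)
  expect_identical(a$masks$thrombus$voxels, b$masks$thrombus$voxels)
})

test_that("noise-free phantoms hit their class means exactly", {
  ph <- generate_phantom(phantom_spec(seed = 1, noise_sd = 0, n_slices = 10))
  v <- ph$volume$voxels
  expect_true(all(v[ph$masks$lumen$voxels == 1] == 300))
  expect_true(all(v[ph$masks$spine$voxels == 1] == 700))
  expect_true(all(v[ph$masks$thrombus$voxels == 1] == 50))
  # degraded contrast scales the lumen mean towards background
  ph2 <- generate_phantom(phantom_spec(seed = 1, noise_sd = 0, n_slices = 10,
                                       contrast_scale = 0.5))
  expect_true(all(v0 <- ph2$volume$voxels[ph2$masks$lumen$voxels == 1] ==
                    40 + 0.5 * (300 - 40)))
})

test_that("ground-truth masks are disjoint, anatomically placed and adjacent", {
  ph <- clean_phantom(seed = 7)
  lum <- ph$masks$lumen$voxels; thr <- ph$masks$thrombus$voxels
  sp <- ph$masks$spine$voxels
  expect_equal(sum(lum & thr), 0)
  expect_equal(sum(sp & (lum | thr)), 0)
  # spine entirely in the posterior half of every slice
  idx <- which(sp == 1, arr.ind = TRUE)
  expect_true(all(idx[, 2] > dim(sp)[2] / 2))
  # thrombus voxels lie within one voxel of the lumen (crescent lining)
  ns <- asNamespace("vesselseg")
  expect_gt(sum(ns$dilate26(lum == 1) & thr == 1), 0)
  # inter-vertebral gaps appear once the stack spans more than one vertebra
  tall <- generate_phantom(phantom_spec(seed = 7))   # 32 slices, 32 mm
  per_slice <- apply(tall$masks$spine$voxels, 1, sum)
  expect_true(any(per_slice == 0) && any(per_slice > 0))
})

test_that("crescent thickness in voxels matches the configured mm", {
  ph <- generate_phantom(phantom_spec(seed = 2, noise_sd = 0, n_slices = 16,
                                      spacing = c(1, 1, 1),
                                      thrombus_thickness_mm = 3))
  thr <- ph$masks$thrombus$voxels; lum <- ph$masks$lumen$voxels
  z <- which.max(apply(thr, 1, sum))          # thickest crescent slice
  # brute-force distance from each thrombus voxel to the lumen surface
  tidx <- which(thr[z, , ] == 1, arr.ind = TRUE)
  lidx <- which(lum[z, , ] == 1, arr.ind = TRUE)
  dmax <- max(apply(tidx, 1, function(p)
    min(sqrt((lidx[, 1] - p[1])^2 + (lidx[, 2] - p[2])^2))))
  expect_gte(dmax, 2); expect_lte(dmax, 4.5)  # ~3 voxels along the thick axis
})

test_that("impossible geometry is a hard error", {
  expect_error(generate_phantom(phantom_spec(bulge_radius_mm = 45, seed = 1)),
               "geometric impossibility")
  expect_error(phantom_spec(spine_center = c(0.4, 0.5)), "posterior")
})

test_that("dataset generation is reproducible and jitters only what it is told", {
  specs <- phantom_spec(n_slices = 8)
  d1 <- generate_dataset(5, specs, jitter = list(lumen_radius_mm = c(6, 10)),
                         seed = 5)
  d2 <- generate_dataset(5, specs, jitter = list(lumen_radius_mm = c(6, 10)),
                         seed = 5)
  expect_identical(lapply(d1, function(p) p$volume$voxels),
                   lapply(d2, function(p) p$volume$voxels))
  radii <- vapply(d1, function(p) p$spec$lumen_radius_mm, numeric(1))
  expect_gt(length(unique(radii)), 1)
  # lumen-only jitter leaves the spine geometry untouched
  spines <- lapply(d1, function(p) p$masks$spine$voxels)
  for (i in 2:5) expect_identical(spines[[i]], spines[[1]])
  # empty jitter falls back to the base spec exactly
  d3 <- generate_dataset(2, specs, jitter = list(), seed = 5)
  expect_equal(d3[[1]]$spec$lumen_radius_mm, specs$lumen_radius_mm)
})

test_that("degraded-mode jitter scales the lumen/background contrast", {
  base <- phantom_spec(n_slices = 8)
  ami <- generate_dataset(4, base,
                          jitter = list(contrast_scale = c(0.5, 0.5),
                                        slice_mm = c(2, 3)),
                          seed = 9)
  for (p in ami) {
    v <- p$volume$voxels
    sep <- mean(v[p$masks$lumen$voxels == 1]) -
      mean(v[p$masks$lumen$voxels == 0 & p$masks$spine$voxels == 0 &
               p$masks$thrombus$voxels == 0])
    expect_equal(sep, 0.5 * (300 - 40), tolerance = 0.1 * 130)
  }
})

test_that("lowering contrast strictly lowers the expected HU separation", {
  seps <- vapply(c(1, 0.7, 0.4), function(cs) {
    p <- generate_phantom(phantom_spec(seed = 3, noise_sd = 0, n_slices = 8,
                                       contrast_scale = cs))
    mean(p$volume$voxels[p$masks$lumen$voxels == 1]) - 40
  }, numeric(1))
  expect_true(all(diff(seps) < 0))
})

test_that("dataset writing emits NIfTI plus a readable manifest", {
  out <- file.path(tempdir(), "phantom_ds")
  unlink(out, recursive = TRUE)
  d <- generate_dataset(2, phantom_spec(n_slices = 8), seed = 4,
                        out_dir = out)
  man <- utils::read.delim(file.path(out, "manifest.tsv"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$volume)))
  back <- read_nifti(man$lumen[1], as = "mask")
  expect_identical(back$voxels, d[[1]]$masks$lumen$voxels)
})
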