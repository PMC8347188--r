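# Shared phantom fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# standard desk-scale clean phantom
clean_phantom <- function(seed = 7, noise_sd = 15, n_slices = 16) {
  memo(sprintf("clean_%d_%g_%d", seed, noise_sd, n_slices),
       generate_phantom(phantom_spec(seed = seed, noise_sd = noise_sd,
                                     n_slices = n_slices)))
}

# small geometry that fits a 64 x 64 slice (for fast network tests)
small_spec <- function(seed = 1, n_slices = 10, ...) {
  phantom_spec(slice_shape = c(64, 64), n_slices = n_slices,
               lumen_radius_mm = 5, bulge_radius_mm = 8,
               thrombus_thickness_mm = 3, spine_radius_mm = 6,
               spine_center = c(0.8, 0.5), lumen_center = c(0.38, 0.5),
               seed = seed, ...)
}

# expert labels for a phantom, memoised by the phantom's seed
expert_labels <- function(ph, cfg = expert_config()) {
  key <- sprintf("labels_%d_%d", ph$spec$seed, ph$spec$n_slices)
  memo(key, {
    pre <- preprocess(ph$volume, cfg)
    spine <- segment_spine(pre, cfg)
    lumen <- segment_lumen(pre, spine, cfg)
    thrombus <- if (sum(lumen$voxels) > 0) segment_thrombus(pre, lumen, cfg)
      else binary_mask(array(0L, dim(pre$voxels)), "thrombus", pre$spacing)
    list(spine = spine, lumen = lumen, thrombus = thrombus)
  })
}

mask_dice <- function(a, b) {
  av <- if (inherits(a, "binary_mask")) a$voxels else a
  bv <- if (inherits(b, "binary_mask")) b$voxels else b
  s <- sum(av != 0) + sum(bv != 0)
  if (s == 0) return(1)
  2 * sum(av != 0 & bv != 0) / s
}
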