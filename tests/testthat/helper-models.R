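# The training-on-synthetic-labels experiment shared by the hybrid-gain
# tests: expert-labelled clean phantoms train the three binary networks,
# which are then evaluated against the expert system on degraded phantoms.
# Built once per test run (it is the expensive fixture) and memoised.

# desk-scale training profile: 128x128 slices, depth-4 trunk, base width 8
desk_unet <- function(n_out = 1, seed = 1)
  build_unet(unet_config(c(128, 128), depth = 4, base_width = 8,
                         n_out = n_out), seed = seed)

hybrid_experiment <- function(seeds = 1:3, n_ami = 10) {
  memo("hybrid_experiment", {
    ecfg <- expert_config()
    ## 1. training corpus: clean phantoms, labelled by the expert system
    phs <- generate_dataset(5, phantom_spec(n_slices = 16),
                            jitter = list(lumen_radius_mm = c(6, 10),
                                          lumen_curvature_mm = c(0, 5)),
                            seed = 100)
    slices <- list(); lmask <- list(); smask <- list()
    th_slices <- list(); th_mask <- list()
    for (ph in phs) {
      pre <- preprocess(ph$volume, ecfg)
      sp <- segment_spine(pre, ecfg)
      lm <- segment_lumen(pre, sp, ecfg)
      tm <- if (sum(lm$voxels) > 0) segment_thrombus(pre, lm, ecfg)
            else binary_mask(array(0L, dim(pre$voxels)), "thrombus",
                             pre$spacing)
      for (z in seq_len(ph$spec$n_slices)) {
        sl <- matrix(ph$volume$voxels[z, , ], 128, 128)
        slices[[length(slices) + 1L]] <- sl
        lmask[[length(lmask) + 1L]] <- matrix(lm$voxels[z, , ], 128, 128)
        smask[[length(smask) + 1L]] <- matrix(sp$voxels[z, , ], 128, 128)
        # screening proxy: train the thrombus net only on slices where the
        # expert found a sizeable thrombus
        if (sum(tm$voxels[z, , ]) > 40) {
          th_slices[[length(th_slices) + 1L]] <- sl
          th_mask[[length(th_mask) + 1L]] <- matrix(tm$voxels[z, , ],
                                                    128, 128)
        }
      }
    }
    sub <- seq(1, length(slices), by = 2)    # spine is easy; train on half

    ## 2. evaluation corpus: degraded phantoms + seed-independent expert runs
    amis <- generate_dataset(n_ami, phantom_spec(mode = "ami", n_slices = 10),
                             jitter = list(contrast_scale = c(0.35, 0.6),
                                           slice_mm = c(2, 3),
                                           lumen_radius_mm = c(6, 10)),
                             seed = 777)
    thr_slice_dice <- function(mask, truth) {
      tz <- which(apply(truth$voxels, 1, sum) > 0)
      mean(vapply(tz, function(z)
        mask_dice(mask$voxels[z, , ], truth$voxels[z, , ]), numeric(1)))
    }
    expert_eval <- lapply(amis, function(ph) {
      pre <- preprocess(ph$volume, ecfg)
      sp <- segment_spine(pre, ecfg)
      lum <- segment_lumen(pre, sp, ecfg)
      thr <- if (sum(lum$voxels) > 0) segment_thrombus(pre, lum, ecfg)
             else binary_mask(array(0L, dim(pre$voxels)), "thrombus",
                              pre$spacing)
      list(lumen_dice = mask_dice(lum, ph$masks$lumen),
           thrombus_dice = thr_slice_dice(thr, ph$masks$thrombus),
           status = attr(lum, "provenance")$status)
    })

    ## 3. per-seed training + hybrid evaluation
    runs <- lapply(seeds, function(s) {
      fl <- train_unet(desk_unet(seed = s), slices, lmask,
                       training_config(learning_rate = 1e-3, max_epochs = 5,
                                       batch_size = 4, seed = s))
      fs <- train_unet(desk_unet(seed = s), slices[sub], smask[sub],
                       training_config(learning_rate = 1e-3, max_epochs = 6,
                                       batch_size = 4, seed = s))
      ft <- train_unet(desk_unet(seed = s), th_slices, th_mask,
                       training_config(learning_rate = 1e-3, max_epochs = 12,
                                       batch_size = 4, seed = s))
      hcfg <- hybrid_config(spine_model = fs$model, lumen_model = fl$model,
                            thrombus_model = ft$model)
      per_vol <- lapply(amis, function(ph) {
        lum <- segment_lumen_hybrid(ph$volume, hcfg, expert_config())
        thr <- if (sum(lum$voxels) > 0)
            segment_thrombus_hybrid(ph$volume, lum, hcfg)
          else binary_mask(array(0L, dim(ph$volume$voxels)), "thrombus",
                           ph$volume$spacing)
        list(lumen_dice = mask_dice(lum, ph$masks$lumen),
             thrombus_dice = thr_slice_dice(thr, ph$masks$thrombus),
             seed_source = attr(lum, "provenance")$seed_source)
      })
      list(fits = list(lumen = fl, spine = fs, thrombus = ft),
           hybrid = per_vol)
    })
    list(expert = expert_eval, runs = runs, amis_n = length(amis))
  })
}
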