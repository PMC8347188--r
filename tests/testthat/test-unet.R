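# per-layer closed-form oracle, written out independently of the package's
# own counting: filters x (kernel_area x in_channels + 1), layer by layer
layerwise_count <- function(base, n_out, depth = 5) {
  w <- base * 2^(0:(depth - 1))
  total <- 0
  cin <- 1
  for (l in seq_len(depth)) {                 # encoder: two 3x3 per level
    total <- total + w[l] * (9 * cin + 1); cin <- w[l]
    total <- total + w[l] * (9 * cin + 1)
  }
  for (l in rev(seq_len(depth - 1))) {        # decoder
    total <- total + w[l] * (4 * w[l + 1] + 1)      # resize + 2x2 conv
    total <- total + w[l] * (9 * 2 * w[l] + 1)      # after skip concat
    total <- total + w[l] * (9 * w[l] + 1)
  }
  total <- total + 2 * (9 * w[1] + 1)         # penultimate 3x3 to 2 channels
  total + n_out * (2 + 1)                     # 1x1 head
}

test_that("trainable-parameter counts match the layer-by-layer arithmetic", {
  for (bw in c(4, 8, 64)) for (nout in c(1, 3)) {
    cfg <- unet_config(c(512, 512), depth = 5, base_width = bw, n_out = nout)
    expect_equal(unet_parameter_count(cfg), layerwise_count(bw, nout))
  }
  # a built model's arrays sum to the closed form
  m <- build_unet(unet_config(c(64, 64), depth = 4, base_width = 4))
  expect_equal(m$parameter_count,
               sum(vapply(m$params, length, numeric(1))))
  expect_equal(m$parameter_count, layerwise_count(4, 1, depth = 4))
})

test_that("the default architecture has 18 hidden layers by introspection", {
  m <- build_unet(unet_config(c(64, 64), depth = 5, base_width = 2))
  expect_equal(count_hidden_layers(m), 18)
})

test_that("indivisible input shapes fail with the required padding stated", {
  expect_error(unet_config(c(100, 100), depth = 5), "divisible.*112x112")
})

test_that("soft Dice loss matches hand arithmetic", {
  t <- matrix(0, 2, 2); t[1, ] <- 1
  expect_lt(dice_loss(t, t), 1e-6)                     # p = t
  expect_gt(dice_loss(1 - t, t), 1 - 1e-5)             # p = 1 - t
  p <- matrix(0.5, 2, 2)
  expect_equal(dice_loss(p, t), 1 - (2 * 1) / (2 + 2), tolerance = 1e-6)
})

test_that("backpropagation matches finite differences", {
  ns <- asNamespace("vesselseg")
  m <- build_unet(unet_config(c(16, 16), depth = 3, base_width = 2), seed = 3)
  set.seed(5)
  sl <- matrix(rnorm(256), 16, 16)
  tr <- array(as.numeric(runif(256) > 0.7), c(16, 16, 1))
  fwd <- ns$unet_forward(m, sl, cache = TRUE)
  g <- ns$unet_backward(m, fwd, ns$dice_loss_grad(fwd$prob, tr))
  eps <- 1e-6
  for (nm in c("enc1_a.W", "enc3_b.W", "up2.W", "dec1_a.W", "penult.W",
               "head.W", "enc2_a.b")) {
    k <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][k] <- m$params[[nm]][k] + eps
    mm <- m; mm$params[[nm]][k] <- m$params[[nm]][k] - eps
    num <- (dice_loss(ns$unet_forward(mp, sl), tr) -
              dice_loss(ns$unet_forward(mm, sl), tr)) / (2 * eps)
    expect_equal(g[[nm]][k], num, tolerance = 1e-4)
  }
})

test_that("thresholding follows the 0.5 rule exactly and is idempotent", {
  expect_equal(threshold_map(matrix(0.49, 3, 3)), matrix(0L, 3, 3))
  m <- matrix(c(0.5, 0.4999, 0.51, 0), 2, 2)
  th <- threshold_map(m)
  expect_equal(th, matrix(c(1L, 0L, 1L, 0L), 2, 2))   # 0.5 itself maps to 1
  expect_identical(threshold_map(th), th)
  set.seed(8)
  r <- matrix(runif(400), 20, 20)
  oracle <- matrix(as.integer(!(r < 0.5)), 20, 20)    # "lower than 0.5 -> 0"
  expect_identical(threshold_map(r), oracle)
})

test_that("multi-class maps argmax into one mask per foreground class", {
  map <- array(0, c(2, 2, 3))
  map[, , 1] <- c(0.8, 0.1, 0.2, 0.1)
  map[, , 2] <- c(0.1, 0.8, 0.3, 0.2)
  map[, , 3] <- c(0.1, 0.1, 0.5, 0.7)
  # per-pixel argmax (column-major pixels): bg, lumen, spine, spine
  cls <- multiclass_masks(map)
  expect_equal(cls$lumen, matrix(c(0L, 1L, 0L, 0L), 2, 2))
  expect_equal(cls$spine, matrix(c(0L, 0L, 1L, 1L), 2, 2))
})

test_that("the stagnation rule fires after three sub-tolerance changes", {
  hist <- c(0.50, 0.70, 0.800, 0.8005, 0.8003, 0.8004)
  expect_equal(stagnation_stop(hist, window = 3, tol = 1e-3), 6L)
  expect_true(is.na(stagnation_stop(hist[1:5], window = 3, tol = 1e-3)))
  expect_true(is.na(stagnation_stop(c(0.1, 0.2, 0.3, 0.4))))
  expect_equal(stagnation_stop(c(0.5, 0.5001, 0.5002), window = 2), 3L)
})

test_that("training is reproducible under its seed and learns a toy task", {
  set.seed(1)
  slices <- list(); masks <- list()
  for (i in 1:10) {
    ph <- generate_phantom(small_spec(seed = 50 + i, n_slices = 8))
    slices[[i]] <- matrix(ph$volume$voxels[4, , ], 64, 64)
    masks[[i]] <- matrix(ph$masks$lumen$voxels[4, , ], 64, 64)
  }
  cfg <- training_config(learning_rate = 3e-3, max_epochs = 15, batch_size = 2,
                         seed = 2)
  m <- build_unet(unet_config(c(64, 64), depth = 3, base_width = 4), seed = 2)
  f1 <- train_unet(m, slices, masks, cfg)
  f2 <- train_unet(m, slices, masks, cfg)
  expect_identical(f1$history, f2$history)
  expect_gt(tail(f1$history, 1), 0.5)
  # probability maps stay in [0, 1]
  p <- predict_unet(f1$model, slices[[1]])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("softmax probabilities sum to one per pixel", {
  m <- build_unet(unet_config(c(32, 32), depth = 3, base_width = 2, n_out = 3))
  p <- predict_unet(m, matrix(rnorm(1024), 32, 32))
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-9)
})

test_that("mismatched masks and non-finite guards are enforced", {
  m <- build_unet(unet_config(c(32, 32), depth = 3, base_width = 2))
  sl <- list(matrix(0, 32, 32))
  expect_error(train_unet(m, sl, list(array(0, c(32, 32, 3)))),
               "binary")
})

test_that("two binary classifiers match or beat the multiclass variant", {
  # the qualitative finding behind choosing two binary networks: on equal
  # training budgets the mean foreground Dice of the binary pair is at
  # least the multiclass model's (means over 3 seeds)
  set.seed(4)
  slices <- list(); lmask <- list(); smask <- list(); mmask <- list()
  for (i in 1:12) {
    ph <- generate_phantom(small_spec(seed = 80 + i, n_slices = 8))
    slices[[i]] <- matrix(ph$volume$voxels[4, , ], 64, 64)
    lmask[[i]] <- matrix(ph$masks$lumen$voxels[4, , ], 64, 64)
    smask[[i]] <- matrix(ph$masks$spine$voxels[4, , ], 64, 64)
    mk <- array(0, c(64, 64, 3))
    mk[, , 2] <- lmask[[i]]; mk[, , 3] <- smask[[i]]
    mk[, , 1] <- 1 - pmin(1, mk[, , 2] + mk[, , 3])
    mmask[[i]] <- mk
  }
  test_ph <- generate_phantom(small_spec(seed = 99, n_slices = 8))
  bin_scores <- c(); multi_scores <- c()
  for (s in 1:3) {
    tc <- training_config(learning_rate = 2e-3, max_epochs = 20,
                          batch_size = 2, seed = s)
    fl <- train_unet(build_unet(unet_config(c(64, 64), 3, 4, 1), seed = s),
                     slices, lmask, tc)
    fs <- train_unet(build_unet(unet_config(c(64, 64), 3, 4, 1), seed = s),
                     slices, smask, tc)
    fm <- train_unet(build_unet(unet_config(c(64, 64), 3, 4, 3), seed = s),
                     slices, mmask, tc)
    dl <- mask_dice(threshold_map(predict_unet(fl$model, test_ph$volume)),
                    test_ph$masks$lumen$voxels)
    ds <- mask_dice(threshold_map(predict_unet(fs$model, test_ph$volume)),
                    test_ph$masks$spine$voxels)
    pm <- predict_unet(fm$model, test_ph$volume)
    dml <- dms <- c()
    for (z in 1:8) {
      cls <- multiclass_masks(pm[z, , , ])
      dml <- c(dml, mask_dice(cls$lumen, test_ph$masks$lumen$voxels[z, , ]))
      dms <- c(dms, mask_dice(cls$spine, test_ph$masks$spine$voxels[z, , ]))
    }
    bin_scores <- c(bin_scores, mean(c(dl, ds)))
    multi_scores <- c(multi_scores, mean(c(dml, dms)))
  }
  expect_gte(mean(bin_scores), mean(multi_scores))
})

test_that("model checkpoints round-trip", {
  m <- build_unet(unet_config(c(32, 32), depth = 3, base_width = 2), seed = 9)
  f <- tempfile(fileext = ".rds")
  save_unet(m, f)
  back <- load_unet(f)
  expect_identical(back$params, m$params)
  sl <- matrix(rnorm(1024), 32, 32)
  expect_identical(predict_unet(back, sl), predict_unet(m, sl))
})
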