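# Symmetric convolutional encoder-decoder ("U-Net") for per-slice
# segmentation, built natively on the ops in nn-ops.R.  The architecture is
# the classical variant whose decoder upsamples by nearest-neighbour resize
# followed by a 2x2 convolution, with skip concatenation, a penultimate 3x3
# convolution to 2 channels and a final 1x1 head; there is no batch
# normalisation.  At depth 5 and base width 64 this trunk has exactly
# 31,031,685 trainable parameters with a 1-channel sigmoid head and
# 31,031,691 with a 3-channel softmax head.

#' U-Net configuration
#'
#' @param input_shape `(rows, columns)` of one input slice; each must be
#'   divisible by `2^(depth - 1)`.
#' @param depth number of encoder levels including the bottleneck
#'   (default 5).
#' @param base_width filters at the first level (default 64; the desk-scale
#'   profile uses 8).
#' @param n_out output channels: 1 for a binary sigmoid head, 3 for a
#'   softmax head over background / lumen / spine.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(input_shape = c(512, 512), depth = 5,
                        base_width = 64, n_out = 1) {
  stopifnot(depth >= 2, base_width >= 1, n_out %in% c(1, 3))
  div <- 2^(depth - 1)
  if (any(input_shape %% div != 0))
    stop(sprintf(
      "input_shape (%s) must be divisible by 2^(depth-1) = %d; pad to (%s)",
      paste(input_shape, collapse = "x"), div,
      paste(ceiling(input_shape / div) * div, collapse = "x")))
  structure(list(input_shape = as.integer(input_shape),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 n_out = as.integer(n_out)),
            class = "unet_config")
}

# Per-layer descriptors (name, kernel, in/out channels, activation, role)
#' @keywords internal
unet_layer_specs <- function(cfg) {
  D <- cfg$depth
  w <- cfg$base_width * 2^(seq_len(D) - 1L)
  specs <- list()
  add <- function(name, k, cin, cout, act, role)
    specs[[length(specs) + 1L]] <<- list(name = name, k = k, cin = cin,
                                         cout = cout, activation = act,
                                         role = role)
  for (l in seq_len(D)) {
    cin <- if (l == 1L) 1L else w[l - 1L]
    add(sprintf("enc%d_a", l), 3L, cin, w[l], "relu", "trunk")
    add(sprintf("enc%d_b", l), 3L, w[l], w[l], "relu", "trunk")
  }
  for (l in rev(seq_len(D - 1L))) {
    add(sprintf("up%d", l), 2L, w[l + 1L], w[l], "relu", "upsample")
    add(sprintf("dec%d_a", l), 3L, 2L * w[l], w[l], "relu", "trunk")
    add(sprintf("dec%d_b", l), 3L, w[l], w[l], "relu", "trunk")
  }
  add("penult", 3L, w[1L], 2L, "relu", "fuse")
  add("head", 1L, 2L, cfg$n_out,
      if (cfg$n_out == 1L) "sigmoid" else "softmax", "head")
  specs
}

#' Trainable-parameter count of a U-Net configuration
#'
#' Closed form: each convolution contributes
#' `filters * (kernel_area * in_channels + 1)`.
#'
#' @param cfg a [unet_config()].
#' @return integer parameter count.
#' @export
unet_parameter_count <- function(cfg) {
  sum(vapply(unet_layer_specs(cfg),
             function(s) s$cout * (s$k^2 * s$cin + 1), numeric(1)))
}

#' Build a U-Net model
#'
#' Allocates He-initialised weights for every layer of the configured
#' architecture and reports the trainable-parameter count (the sum of all
#' weight and bias array lengths, which for the default full-scale
#' configuration reproduces the 31,031,685 / 31,031,691 binary/multiclass
#' counts).
#'
#' @param cfg a [unet_config()].
#' @param seed RNG seed for the weight initialisation.
#' @return object of class `unet_model`: `cfg`, `layers` (introspectable
#'   descriptors), `params` (named weight/bias arrays), and
#'   `parameter_count`.
#' @export
build_unet <- function(cfg, seed = 1L) {
  specs <- unet_layer_specs(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (s in specs) {
      fan_in <- s$k^2 * s$cin
      p[[paste0(s$name, ".W")]] <-
        matrix(stats::rnorm(fan_in * s$cout, sd = sqrt(2 / fan_in)),
               fan_in, s$cout)
      p[[paste0(s$name, ".b")]] <- numeric(s$cout)
    }
    p
  })
  count <- sum(vapply(params, length, numeric(1)))
  structure(list(cfg = cfg, layers = specs, params = params,
                 parameter_count = count, normalization = "zscore"),
            class = "unet_model")
}

#' Hidden-layer count by introspection
#'
#' Counts the 3x3 feature-extraction convolutions of the trunk (two per
#' encoder level including the bottleneck, two per decoder level), the
#' counting under which the default depth-5 architecture has 18 hidden
#' layers.  Upsampling 2x2 convolutions, the 2-channel fusion convolution
#' and the 1x1 head are architectural plumbing and are not counted.
#'
#' @param model a `unet_model`.
#' @return integer.
#' @export
count_hidden_layers <- function(model) {
  sum(vapply(model$layers, function(s) s$role == "trunk", logical(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base width %d, %d-channel %s head\n",
              x$cfg$depth, x$cfg$base_width, x$cfg$n_out,
              if (x$cfg$n_out == 1) "sigmoid" else "softmax"))
  cat(sprintf("  input %dx%d, %d trainable parameters, %d hidden layers\n",
              x$cfg$input_shape[1], x$cfg$input_shape[2],
              x$parameter_count, count_hidden_layers(x)))
  invisible(x)
}

#' @keywords internal
normalize_slice <- function(sl) {
  s <- stats::sd(sl)
  if (!is.finite(s) || s < 1e-6) s <- 1
  (sl - mean(sl)) / s
}

# Full forward pass; cache = TRUE retains every intermediate for backprop.
#' @keywords internal
unet_forward <- function(model, slice, cache = FALSE) {
  cfg <- model$cfg
  if (!all(dim(slice) == cfg$input_shape))
    stop(sprintf("slice is %s but the model expects %s",
                 paste(dim(slice), collapse = "x"),
                 paste(cfg$input_shape, collapse = "x")))
  x <- array(normalize_slice(slice), c(dim(slice), 1L))
  P <- model$params
  D <- cfg$depth
  caches <- list(); skips <- list()
  run_conv <- function(x, name, k, act) {
    pb <- if (k == 3L) 1L else 0L
    r <- conv_fwd(x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]],
                  k, pb, activation = if (act == "relu") "relu" else "linear")
    if (cache) caches[[name]] <<- r$cache
    r$out
  }
  for (l in seq_len(D)) {
    x <- run_conv(x, sprintf("enc%d_a", l), 3L, "relu")
    x <- run_conv(x, sprintf("enc%d_b", l), 3L, "relu")
    if (l < D) {
      skips[[l]] <- x
      mp <- maxpool_fwd(x)
      if (cache) caches[[sprintf("pool%d", l)]] <- mp$cache
      x <- mp$out
    }
  }
  for (l in rev(seq_len(D - 1L))) {
    x <- upsample_fwd(x)
    x <- run_conv(x, sprintf("up%d", l), 2L, "relu")
    nch <- dim(x)[3]
    x2 <- array(0, c(dim(x)[1], dim(x)[2], 2L * nch))
    x2[, , seq_len(nch)] <- skips[[l]]
    x2[, , nch + seq_len(nch)] <- x
    x <- x2
    x <- run_conv(x, sprintf("dec%d_a", l), 3L, "relu")
    x <- run_conv(x, sprintf("dec%d_b", l), 3L, "relu")
  }
  x <- run_conv(x, "penult", 3L, "relu")
  z <- run_conv(x, "head", 1L, "linear")
  prob <- if (cfg$n_out == 1L) {
    array(sigmoid(z), dim(z))
  } else softmax3(z)
  if (cache) list(prob = prob, caches = caches)
  else prob
}

# Backward pass given dL/dprob; returns gradients for every parameter.
#' @keywords internal
unet_backward <- function(model, fwd, dprob) {
  cfg <- model$cfg; P <- model$params; D <- cfg$depth
  caches <- fwd$caches
  prob <- fwd$prob
  grads <- list()
  # head activation jacobian
  if (cfg$n_out == 1L) {
    dz <- dprob * prob * (1 - prob)
  } else {
    dot <- apply(dprob * prob, c(1, 2), sum)
    dz <- prob * sweep(dprob, c(1, 2), dot, "-")
  }
  back_conv <- function(dy, name) {
    r <- conv_bwd(dy, P[[paste0(name, ".W")]], caches[[name]])
    grads[[paste0(name, ".W")]] <<- r$dW
    grads[[paste0(name, ".b")]] <<- r$db
    r$dx
  }
  dx <- back_conv(dz, "head")
  dx <- back_conv(dx, "penult")
  dskips <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {
    dx <- back_conv(dx, sprintf("dec%d_b", l))
    dx <- back_conv(dx, sprintf("dec%d_a", l))
    nch <- dim(dx)[3] / 2L
    dskips[[l]] <- dx[, , seq_len(nch), drop = FALSE]
    dx <- dx[, , nch + seq_len(nch), drop = FALSE]
    dx <- back_conv(dx, sprintf("up%d", l))
    dx <- upsample_bwd(dx)
  }
  for (l in seq(D, 1L)) {
    if (l < D) {
      dx <- maxpool_bwd(dx, caches[[sprintf("pool%d", l)]])
      dx <- dx + dskips[[l]]
    }
    dx <- back_conv(dx, sprintf("enc%d_b", l))
    dx <- back_conv(dx, sprintf("enc%d_a", l))
  }
  grads
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1e-6`
#' (fixed); for multi-channel inputs the channel-mean soft Dice is used.
#'
#' @param prob probability map (matrix or `(H, W, C)` array), values in
#'   \[0, 1\].
#' @param truth binary mask of the same shape.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob, truth) {
  eps <- 1e-6
  p <- as.array(prob); t <- as.array(truth)
  if (!identical(dim(p), dim(t)) &&
      !identical(as.integer(dim(p)), as.integer(dim(t))))
    stop("probability map and truth have different shapes")
  if (length(dim(p)) == 2L) { dim(p) <- c(dim(p), 1L); dim(t) <- dim(p) }
  losses <- vapply(seq_len(dim(p)[3]), function(ch) {
    pc <- p[, , ch]; tc <- t[, , ch]
    1 - (2 * sum(pc * tc) + eps) / (sum(pc) + sum(tc) + eps)
  }, numeric(1))
  mean(losses)
}

#' @keywords internal
dice_loss_grad <- function(prob, truth) {
  eps <- 1e-6
  p <- prob; t <- truth
  if (length(dim(p)) == 2L) { dim(p) <- c(dim(p), 1L); dim(t) <- dim(p) }
  g <- array(0, dim(p))
  nch <- dim(p)[3]
  for (ch in seq_len(nch)) {
    pc <- p[, , ch]; tc <- t[, , ch]
    num <- 2 * sum(pc * tc) + eps
    den <- sum(pc) + sum(tc) + eps
    g[, , ch] <- -(2 * tc * den - num) / den^2 / nch
  }
  g
}

#' Predict probability maps
#'
#' Runs the network on one slice (matrix) or on every axial slice of a
#' [ct_volume()].  Each slice is standardised (zero mean, unit SD) before
#' entering the network, the same normalisation used in training.
#'
#' @param model a trained `unet_model`.
#' @param x matrix or [ct_volume()].
#' @return for a binary head: a matrix (slice input) or `(z, H, W)` array
#'   (volume input) of values in \[0, 1\]; for the softmax head one extra
#'   trailing channel dimension (background, lumen, spine), summing to 1
#'   per pixel.
#' @export
predict_unet <- function(model, x) {
  if (inherits(x, "ct_volume")) {
    d <- dim(x$voxels)
    out <- if (model$cfg$n_out == 1L) array(0, d)
           else array(0, c(d, model$cfg$n_out))
    for (z in seq_len(d[1])) {
      p <- unet_forward(model, matrix(x$voxels[z, , ], d[2], d[3]))
      if (model$cfg$n_out == 1L) out[z, , ] <- p[, , 1]
      else out[z, , , ] <- p
    }
    out
  } else {
    p <- unet_forward(model, x)
    if (model$cfg$n_out == 1L) p[, , 1] else p
  }
}

#' Threshold a probability map
#'
#' Values strictly lower than `theta` become 0, all others become 1 (so a
#' pixel at exactly 0.5 maps to 1).  Idempotent.
#'
#' @param map numeric array of probabilities.
#' @param theta threshold in (0, 1), default 0.5.
#' @return integer 0/1 array of the same shape.
#' @export
threshold_map <- function(map, theta = 0.5) {
  stopifnot(theta > 0, theta < 1)
  out <- array(0L, dim(map) %||% length(map))
  out[map >= theta] <- 1L
  if (is.matrix(map)) matrix(out, nrow(map), ncol(map)) else out
}

#' Per-class masks from a softmax probability map
#'
#' Per-pixel argmax over the channels (background first), emitting one
#' binary mask per foreground class.
#'
#' @param map `(H, W, C)` or `(z, H, W, C)` softmax output.
#' @param classes names of the foreground channels, in channel order after
#'   background.
#' @return named list of 0/1 arrays.
#' @export
multiclass_masks <- function(map, classes = c("lumen", "spine")) {
  nd <- length(dim(map))
  am <- function(a) {
    # argmax over last dim
    d <- dim(a); C <- d[nd]
    flat <- matrix(a, ncol = C)
    max.col(flat, ties.method = "first")
  }
  win <- am(map)
  d <- dim(map)[-nd]
  out <- list()
  for (i in seq_along(classes)) {
    m <- array(0L, d)
    m[win == i + 1L] <- 1L
    out[[classes[i]]] <- m
  }
  out
}

#' Save / load a trained model
#'
#' Weights and configuration in R's native serialisation format.
#'
#' @param model a `unet_model`.
#' @param path checkpoint file (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_unet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
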