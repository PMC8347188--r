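# Training: Adam on the soft-Dice loss, geometric augmentation sampled
# per epoch, a monitored hard Dice on a held-out split, and the stopping
# rule "stagnation of the monitored Dice for 3 consecutive epochs at 1e-3
# precision".  Fully reproducible under the configuration seed, including
# augmentation sampling, shuffling and weight initialisation of the model
# being trained.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default `1e-5`, suited to
#'   full-scale corpora; desk-scale experiments typically use `1e-3`).
#' @param max_epochs upper bound on epochs.
#' @param stagnation_window consecutive epochs of sub-tolerance change that
#'   trigger termination (default 3).
#' @param stagnation_tol tolerance on the monitored Dice (default `1e-3`).
#' @param batch_size minibatch size.
#' @param augment logical; apply random rotation (+/-10 deg), width/height
#'   shift (+/-5%), zoom (+/-10%) and horizontal flips to training slices.
#' @param holdout_fraction fraction of slices held out to monitor the Dice
#'   driving the stopping rule.
#' @param seed RNG seed covering shuffling and augmentation.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-5, max_epochs = 50,
                            stagnation_window = 3, stagnation_tol = 1e-3,
                            batch_size = 8, augment = TRUE,
                            holdout_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, stagnation_window >= 1, stagnation_tol > 0,
            max_epochs >= 1, batch_size >= 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 stagnation_window = stagnation_window,
                 stagnation_tol = stagnation_tol, batch_size = batch_size,
                 augment = augment, holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Dice-stagnation stopping rule
#'
#' Returns the 1-based epoch after which training stops: the first epoch
#' ending a run of `window` consecutive epoch-to-epoch changes in the
#' monitored Dice that are all below `tol` in absolute value; `NA` if the
#' history never stagnates.
#'
#' @param history numeric vector of per-epoch monitored Dice values.
#' @param window consecutive sub-tolerance changes required (default 3).
#' @param tol absolute change threshold (default `1e-3`).
#' @return integer epoch index or `NA`.
#' @export
stagnation_stop <- function(history, window = 3, tol = 1e-3) {
  if (length(history) < window + 1) return(NA_integer_)
  small <- abs(diff(history)) < tol
  run <- 0L
  for (i in seq_along(small)) {
    run <- if (small[i]) run + 1L else 0L
    if (run >= window) return(i + 1L)
  }
  NA_integer_
}

#' @keywords internal
hard_dice <- function(pred, truth) {
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred & truth) / s
}

# Monitored metric: mean hard Dice of thresholded predictions on the
# held-out slices (foreground channels only for the softmax head).
#' @keywords internal
monitor_dice <- function(model, slices, masks) {
  vals <- vapply(seq_along(slices), function(i) {
    p <- unet_forward(model, slices[[i]])
    t <- masks[[i]]
    if (model$cfg$n_out == 1L) {
      hard_dice(threshold_map(p[, , 1]) == 1L, t != 0)
    } else {
      cls <- multiclass_masks(p)
      mean(vapply(seq_along(cls), function(k)
        hard_dice(cls[[k]] == 1L, t[, , k + 1L] != 0), numeric(1)))
    }
  }, numeric(1))
  mean(vals)
}

#' Train a U-Net
#'
#' Minimises the soft-Dice loss with Adam.  For the softmax head, `masks`
#' must be `(H, W, n_out)` one-hot arrays (background channel first); for
#' the sigmoid head, plain 0/1 matrices.  Training stops at `max_epochs`
#' or when the monitored held-out Dice stagnates
#' (see [stagnation_stop()]), whichever comes first.  Non-finite losses
#' abort with diagnostics.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param slices list of input matrices matching the model input shape.
#' @param masks list of matching masks.
#' @param cfg a [training_config()].
#' @return list: `model` (trained), `history` (per-epoch monitored Dice),
#'   `stop_reason` (`"stagnation"` or `"max_epochs"`), `stopped_epoch`.
#' @export
train_unet <- function(model, slices, masks, cfg = training_config()) {
  stopifnot(inherits(model, "unet_model"), length(slices) >= 1,
            length(slices) == length(masks))
  n_out <- model$cfg$n_out
  for (i in seq_along(masks)) {
    dm <- dim(masks[[i]])
    ok <- if (n_out == 1L) length(dm) == 2L else
      (length(dm) == 3L && dm[3] == n_out)
    if (!ok) stop(sprintf(
      "mask %d does not match the %s head (got dims %s)", i,
      if (n_out == 1L) "binary" else "multi-class",
      paste(dm, collapse = "x")))
  }

  with_seed(cfg$seed, {
    n <- length(slices)
    n_hold <- if (cfg$holdout_fraction > 0 && n >= 5)
      max(1L, round(cfg$holdout_fraction * n)) else 0L
    hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    train_idx <- setdiff(seq_len(n), hold)
    if (length(train_idx) == 0) stop("holdout left no training slices")
    mon_idx <- if (n_hold > 0) hold else train_idx

    # Adam state
    m1 <- lapply(model$params, function(p) p * 0)
    m2 <- m1
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    step <- 0L
    history <- numeric(0)
    stop_reason <- "max_epochs"

    augment_pair <- function(sl, mk) {
      ang <- stats::runif(1, -10, 10)
      s_r <- stats::runif(1, -0.05, 0.05)
      s_c <- stats::runif(1, -0.05, 0.05)
      zm <- stats::runif(1, 0.9, 1.1)
      fl <- stats::runif(1) < 0.5
      sl2 <- affine_warp(sl, ang, s_r, s_c, zm, fl, "bilinear",
                         fill = min(sl))
      if (n_out == 1L) {
        mk2 <- affine_warp(mk, ang, s_r, s_c, zm, fl, "nearest", fill = 0)
      } else {
        mk2 <- array(0, dim(mk))
        for (ch in seq_len(dim(mk)[3]))
          mk2[, , ch] <- affine_warp(mk[, , ch], ang, s_r, s_c, zm, fl,
                                     "nearest", fill = as.numeric(ch == 1L))
      }
      list(sl = sl2, mk = mk2)
    }

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (batch in batches) {
        acc <- NULL
        for (i in batch) {
          pair <- if (cfg$augment) augment_pair(slices[[i]], masks[[i]])
                  else list(sl = slices[[i]], mk = masks[[i]])
          fwd <- unet_forward(model, pair$sl, cache = TRUE)
          tr <- if (n_out == 1L) {
            array(pair$mk, c(dim(pair$mk), 1L))
          } else pair$mk
          loss <- dice_loss(fwd$prob, tr)
          if (!is.finite(loss))
            stop(sprintf("non-finite loss at epoch %d (slice %d)", epoch, i))
          g <- unet_backward(model, fwd, dice_loss_grad(fwd$prob, tr))
          if (is.null(acc)) acc <- g
          else for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
        step <- step + 1L
        bs <- length(batch)
        for (nm in names(model$params)) {
          g <- acc[[nm]] / bs
          m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g
          m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g^2
          mh <- m1[[nm]] / (1 - beta1^step)
          vh <- m2[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mh / (sqrt(vh) + adam_eps)
        }
      }
      history <- c(history,
                   monitor_dice(model, slices[mon_idx], masks[mon_idx]))
      st <- stagnation_stop(history, cfg$stagnation_window,
                            cfg$stagnation_tol)
      if (!is.na(st)) { stop_reason <- "stagnation"; break }
    }
    list(model = model, history = history, stop_reason = stop_reason,
         stopped_epoch = length(history))
  })
}

#' Write a training history as delimited text
#'
#' @param history numeric vector of per-epoch monitored Dice.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.table(
    data.frame(epoch = seq_along(history), dice = history),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
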