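# Low-level neural-network operations on (H, W, C) arrays, written as
# im2col gathers plus BLAS matrix products so the heavy lifting happens in
# optimised linear algebra.  Forward functions return caches consumed by
# the matching backward functions.  All of this is plain R on purpose: the
# network sizes used here (desk-scale training, full-scale construction)
# do not need compiled code.

#' @keywords internal
conv_fwd <- function(x, Wm, b, k, pad_beg, activation = "relu") {
  d <- dim(x); H <- d[1]; W <- d[2]
  Z <- conv_gemm_cpp(x, d[1], d[2], d[3], Wm, b, k, pad_beg)
  A <- switch(activation,
              relu = pmax(Z, 0) + 0.01 * pmin(Z, 0),  # leaky: nothing dies
              linear = Z,
              stop("unknown activation"))
  dim(A) <- c(H, W, ncol(Wm))
  list(out = A,
       cache = list(x = x, Z = Z, dims = d, k = k, pad_beg = pad_beg,
                    activation = activation))
}

# The input gradient of a stride-1 convolution is itself a convolution of
# the output gradient with the spatially flipped kernel and swapped
# channel roles, so the backward pass reuses the same im2col + GEMM path
# as the forward pass (no scatter loops).
#' @keywords internal
conv_bwd <- function(dA, Wm, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  k <- cache$k; k2 <- k * k
  Cout <- ncol(Wm)
  dZ <- dA
  dim(dZ) <- c(H * W, Cout)
  if (cache$activation == "relu")
    dZ <- dZ * ifelse(cache$Z > 0, 1, 0.01)
  dW <- conv_dw_cpp(cache$x, H, W, C, dZ, k, cache$pad_beg)
  db <- colSums(dZ)
  # flipped kernel: W_back[(co-1)*k2 + flip(o), ci] = Wm[(ci-1)*k2 + o, co]
  Wb <- array(Wm, c(k2, C, Cout))
  Wb <- Wb[rev(seq_len(k2)), , , drop = FALSE]
  Wb <- aperm(Wb, c(1, 3, 2))
  dim(Wb) <- c(k2 * Cout, C)
  # the forward pad pb becomes k - 1 - pb in the backward convolution
  dx <- conv_gemm_cpp(dZ, H, W, Cout, Wb, numeric(C), k,
                      k - 1L - cache$pad_beg)
  dim(dx) <- c(H, W, C)
  list(dx = dx, dW = dW, db = db)
}

#' @keywords internal
maxpool_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("maxpool needs even spatial dims")
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  a1 <- x[io, jo, , drop = FALSE];     a2 <- x[io + 1, jo, , drop = FALSE]
  a3 <- x[io, jo + 1, , drop = FALSE]; a4 <- x[io + 1, jo + 1, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  w1 <- a1 == m
  w2 <- a2 == m & !w1
  w3 <- a3 == m & !w1 & !w2
  w4 <- a4 == m & !w1 & !w2 & !w3
  list(out = m, cache = list(w = list(w1, w2, w3, w4), dims = d))
}

#' @keywords internal
maxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  w <- cache$w
  dx[io, jo, ]         <- dy * w[[1]]
  dx[io + 1, jo, ]     <- dy * w[[2]]
  dx[io, jo + 1, ]     <- dy * w[[3]]
  dx[io + 1, jo + 1, ] <- dy * w[[4]]
  dx
}

#' @keywords internal
upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

#' @keywords internal
upsample_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  dy[io, jo, , drop = FALSE] + dy[io + 1, jo, , drop = FALSE] +
    dy[io, jo + 1, , drop = FALSE] + dy[io + 1, jo + 1, , drop = FALSE]
}

#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

#' @keywords internal
softmax3 <- function(z) {
  # z: (H, W, C); per-pixel softmax over channels
  m <- apply(z, c(1, 2), max)
  e <- exp(sweep(z, c(1, 2), m, "-"))
  s <- apply(e, c(1, 2), sum)
  sweep(e, c(1, 2), s, "/")
}

# --- affine warping for augmentation ---------------------------------------

# Rotation (degrees) + fractional shift + zoom + optional horizontal flip
# about the image centre; `interp` is "bilinear" for images and "nearest"
# for masks.  Out-of-frame samples take `fill`.
#' @keywords internal
affine_warp <- function(img, angle = 0, shift_r = 0, shift_c = 0,
                        zoom = 1, hflip = FALSE,
                        interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle * pi / 180
  gi <- rep(seq_len(nr), times = nc) - cr
  gj <- rep(seq_len(nc), each = nr) - cc
  if (hflip) gj <- -gj
  # inverse map: undo shift, then rotation, then zoom
  ui <- gi - shift_r * nr; uj <- gj - shift_c * nc
  si <- (cos(th) * ui + sin(th) * uj) / zoom + cr
  sj <- (-sin(th) * ui + cos(th) * uj) / zoom + cc
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= nr & rj >= 1 & rj <= nc
    out <- rep(fill, nr * nc)
    out[ok] <- img[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    out <- rep(fill, nr * nc)
    ok <- i0 >= 1 & i0 + 1 <= nr & j0 >= 1 & j0 + 1 <= nc
    i0k <- i0[ok]; j0k <- j0[ok]; fik <- fi[ok]; fjk <- fj[ok]
    v00 <- img[cbind(i0k, j0k)];     v10 <- img[cbind(i0k + 1, j0k)]
    v01 <- img[cbind(i0k, j0k + 1)]; v11 <- img[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - fik) * (1 - fjk) + v10 * fik * (1 - fjk) +
      v01 * (1 - fik) * fjk + v11 * fik * fjk
  }
  matrix(out, nr, nc)
}
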