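# Morphological active contour without edges (ACWE): a region-based
# Chan-Vese-type energy evolved purely by connected morphological
# operators, so there is no PDE time step, no re-initialisation and no
# numerical instability.  Each iteration (1) recomputes the two region
# means, (2) flips only contour-adjacent pixels toward the nearer mean,
# and (3) applies the median-like curvature smoothing built from sup-inf /
# inf-sup operators over four 3-pixel line segments.

# P1..P4: the four line structuring elements (horizontal, vertical, two
# diagonals) as (dr, dc) offset pairs around the centre.
.acwe_lines <- list(
  rbind(c(0, -1), c(0, 0), c(0, 1)),
  rbind(c(-1, 0), c(0, 0), c(1, 0)),
  rbind(c(-1, -1), c(0, 0), c(1, 1)),
  rbind(c(-1, 1), c(0, 0), c(1, -1)))

#' @keywords internal
.sup_inf <- function(u) {
  out <- matrix(0, nrow(u), ncol(u))
  for (L in .acwe_lines) {
    inf_l <- matrix(1, nrow(u), ncol(u))
    for (k in seq_len(nrow(L)))
      inf_l <- pmin(inf_l, shift2d(u, L[k, 1], L[k, 2], fill = 1))
    out <- pmax(out, inf_l)
  }
  out
}

#' @keywords internal
.inf_sup <- function(u) {
  out <- matrix(1, nrow(u), ncol(u))
  for (L in .acwe_lines) {
    sup_l <- matrix(0, nrow(u), ncol(u))
    for (k in seq_len(nrow(L)))
      sup_l <- pmax(sup_l, shift2d(u, L[k, 1], L[k, 2], fill = 0))
    out <- pmin(out, sup_l)
  }
  out
}

#' @keywords internal
.contour_band <- function(u) {
  # pixels where the level set has a neighbour of the other phase
  grown <- pmax(shift2d(u, 1, 0), shift2d(u, -1, 0),
                shift2d(u, 0, 1), shift2d(u, 0, -1), u)
  shrunk <- pmin(shift2d(u, 1, 0, fill = 1), shift2d(u, -1, 0, fill = 1),
                 shift2d(u, 0, 1, fill = 1), shift2d(u, 0, -1, fill = 1), u)
  grown != shrunk
}

#' Morphological active contour without edges on one slice
#'
#' Evolves a binary region from `init` on image `img` (a numeric matrix)
#' for at most `iterations` steps.  Updates are restricted to the contour
#' band, so the region grows or shrinks by at most one pixel per iteration
#' and cannot jump to disconnected bright structures.  Region means can be
#' computed over a restricted `roi` (e.g. a box around the contour) to
#' keep the outside statistics local.
#'
#' @param img numeric matrix (one axial slice).
#' @param init logical/0-1 matrix, the initial region (non-empty).
#' @param iterations maximum number of morphological steps (>= 1).
#' @param smoothing number of curvature smoothing passes per step.
#' @param lambda1,lambda2 weights of the inside/outside variance terms.
#' @param roi optional logical matrix; statistics and updates are
#'   restricted to it.
#' @param stat_exclude optional logical matrix of pixels excluded from the
#'   region-mean statistics (but still part of the region); used to stop a
#'   bright anchor (e.g. the lumen inside a thrombus snake) from drowning
#'   a faint contrast.
#' @return 0/1 integer matrix, the converged region.
#' @export
morph_acwe <- function(img, init, iterations = 50, smoothing = 1,
                       lambda1 = 1, lambda2 = 1, roi = NULL,
                       stat_exclude = NULL) {
  stopifnot(iterations >= 1)
  nr0 <- nrow(img); nc0 <- ncol(img)
  u <- matrix(as.numeric(init != 0), nr0, nc0)
  if (sum(u) == 0) stop("morph_acwe: empty initial region")
  if (is.null(roi)) roi <- matrix(TRUE, nr0, nc0)
  # evolve inside the ROI bounding box only; everything outside is frozen
  ri <- which(roi, arr.ind = TRUE)
  rr <- range(ri[, 1]); cr <- range(ri[, 2])
  crop <- rr[1] > 1 || rr[2] < nr0 || cr[1] > 1 || cr[2] < nc0
  if (crop) {
    full_u <- u
    img <- img[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    u <- u[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    roi <- roi[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    if (!is.null(stat_exclude))
      stat_exclude <- stat_exclude[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  }
  stat_ok <- if (is.null(stat_exclude)) roi else roi & !stat_exclude
  for (it in seq_len(iterations)) {
    u_prev <- u
    inside <- u > 0.5 & stat_ok
    outside <- u <= 0.5 & stat_ok
    if (!any(inside) || !any(outside)) break
    c1 <- mean(img[inside]); c2 <- mean(img[outside])
    band <- .contour_band(u) & roi
    if (any(band)) {
      f <- lambda1 * (img - c1)^2 - lambda2 * (img - c2)^2
      u_new <- u
      u_new[band & f < 0] <- 1
      u_new[band & f > 0] <- 0
      u <- u_new
    }
    if (smoothing > 0) {
      for (s in seq_len(smoothing))
        u <- if (it %% 2L == 0L) .sup_inf(.inf_sup(u)) else .inf_sup(.sup_inf(u))
    }
    if (sum(u) == 0) break
    if (it > 1 && identical(u, u_prev)) break   # converged
  }
  if (crop) {
    full_u[rr[1]:rr[2], cr[1]:cr[2]] <- u
    u <- full_u
  }
  matrix(as.integer(u > 0.5), nr0, nc0)
}
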