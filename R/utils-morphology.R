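# Low-level vectorised morphology and filtering on 2D/3D logical or numeric
# arrays.  Everything here is shift-based so it works on plain R arrays with
# no padding conventions leaking out: out-of-bounds neighbours are treated as
# background (0) for dilation and as background for erosion, i.e. the array
# border behaves like an implicit background frame.

#' @keywords internal
shift2d <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1, 1 + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1, 1 + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  out
}

#' @keywords internal
shift3d <- function(a, dz, dr, dc, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  z0 <- max(1, 1 + dz); z1 <- min(d[1], d[1] + dz)
  r0 <- max(1, 1 + dr); r1 <- min(d[2], d[2] + dr)
  c0 <- max(1, 1 + dc); c1 <- min(d[3], d[3] + dc)
  if (z0 <= z1 && r0 <= r1 && c0 <= c1)
    out[z0:z1, r0:r1, c0:c1] <-
      a[(z0:z1) - dz, (r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  out
}

# 1-voxel dilation, 26-connectivity (or 8-connectivity in 2D)
#' @keywords internal
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dr in -1:1) for (dc in -1:1) {
    if (dz == 0 && dr == 0 && dc == 0) next
    out <- out | shift3d(mask, dz, dr, dc)
  }
  out
}

#' @keywords internal
erode6 <- function(mask) {
  out <- mask
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift3d(mask, s[1], s[2], s[3])
  out
}

# Boundary voxels of a 3D mask: mask voxels with at least one 6-neighbour
# (or the array border) outside the mask.
#' @keywords internal
mask_boundary <- function(mask) mask & !erode6(mask)

# Separable box dilation/erosion with per-axis integer radii (z, row, col);
# cheap approximation of a ball used for gap closing.
#' @keywords internal
dilate_box <- function(mask, radii) {
  out <- mask
  for (ax in 1:3) {
    r <- radii[ax]
    if (r < 1) next
    acc <- out
    for (k in seq_len(r)) {
      s1 <- c(0, 0, 0); s1[ax] <- k
      s2 <- -s1
      acc <- acc | shift3d(out, s1[1], s1[2], s1[3]) |
        shift3d(out, s2[1], s2[2], s2[3])
    }
    out <- acc
  }
  out
}

# Out-of-bounds voxels are treated as foreground (fill = 1) so that a
# closing does not erode the volume border.
#' @keywords internal
erode_box <- function(mask, radii) {
  out <- mask
  for (ax in 1:3) {
    r <- radii[ax]
    if (r < 1) next
    acc <- out
    for (k in seq_len(r)) {
      s1 <- c(0, 0, 0); s1[ax] <- k
      s2 <- -s1
      acc <- acc & shift3d(out, s1[1], s1[2], s1[3], fill = 1) &
        shift3d(out, s2[1], s2[2], s2[3], fill = 1)
    }
    out <- acc
  }
  out
}

#' @keywords internal
close_box <- function(mask, radii) erode_box(dilate_box(mask, radii), radii)

# In-plane (2D, 8-connected) dilation by an approximately circular disc of
# integer radius r, via EBImage.
#' @keywords internal
dilate_disc2d <- function(m, r) {
  if (r < 1) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::dilate(m * 1, brush) > 0
}

# Gaussian smoothing of a 3D array with per-axis sigma in voxel units,
# separable 1D convolutions implemented as banded matrix products.
#' @keywords internal
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  half <- max(1L, ceiling(3 * sigma))
  off <- (-half):half
  w <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(off)) {
    src <- idx + off[j]
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w[j]
  }
  K / rowSums(K)   # renormalised at the borders
}

#' @keywords internal
gauss3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    K <- gauss_kernel_matrix(d[ax], sigma_vox[ax])
    if (is.null(K)) next
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[ax])
    m <- K %*% m
    ap <- array(m, dim = d[perm])
    a <- aperm(ap, order(perm))
  }
  a
}

# --- connected components ---------------------------------------------------

# 3D connected-component labelling, 26-connectivity: 8-connected in-plane
# labelling per slice (EBImage) followed by a union-find merge across
# adjacent slices over the nine in-plane offsets.
#' @keywords internal
label_components_3d <- function(mask) {
  d <- dim(mask)
  nz <- d[1]
  labels <- array(0L, d)
  offset <- 0L
  for (z in seq_len(nz)) {
    sl <- EBImage::bwlabel(matrix(as.numeric(mask[z, , ]), d[2], d[3]))
    sl <- matrix(as.integer(sl), d[2], d[3])
    nlab <- max(sl, 0L)
    sl[sl > 0L] <- sl[sl > 0L] + offset
    labels[z, , ] <- sl
    offset <- offset + nlab
  }
  if (offset == 0L) return(labels)
  parent <- seq_len(offset)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- as.integer(min(ra, rb))
  }
  noff <- offset + 1L
  for (z in seq_len(nz - 1L)) {
    A <- matrix(labels[z, , ], d[2], d[3])
    B <- matrix(labels[z + 1L, , ], d[2], d[3])
    if (!any(A > 0L) || !any(B > 0L)) next
    for (dr in -1:1) for (dc in -1:1) {
      Bs <- shift2d(B, dr, dc)
      sel <- A > 0L & Bs > 0L
      if (!any(sel)) next
      codes <- unique(as.numeric(A[sel]) + as.numeric(Bs[sel]) * noff)
      b <- codes %/% noff
      a <- codes - b * noff
      for (k in seq_along(codes)) union_(a[k], b[k])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]
  labels
}

# Largest connected component of a 2D logical matrix (8-connectivity);
# returns a logical matrix (all FALSE if input empty).
#' @keywords internal
largest_component_2d <- function(m) {
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
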