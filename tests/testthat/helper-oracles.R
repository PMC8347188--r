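# Independent brute-force oracles used to check the metric suite.  These
# deliberately share no code with the package implementation.

# elementwise confusion counts by explicit looping over voxels
oracle_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; t <- truth[i] != 0
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# all-pairs Hausdorff over boundary voxels (O(n^2)); boundary = mask voxel
# with a 6-neighbour (or the array border) outside the mask
oracle_boundary <- function(mask) {
  d <- dim(mask)
  pts <- NULL
  for (z in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (mask[z, r, c] == 0) next
    nb_bg <- z == 1 || z == d[1] || r == 1 || r == d[2] ||
      c == 1 || c == d[3] ||
      mask[z - 1, r, c] == 0 || mask[z + 1, r, c] == 0 ||
      mask[z, r - 1, c] == 0 || mask[z, r + 1, c] == 0 ||
      mask[z, r, c - 1] == 0 || mask[z, r, c + 1] == 0
    if (nb_bg) pts <- rbind(pts, c(z, r, c) - 1)
  }
  pts
}

oracle_hausdorff <- function(pred, truth) {
  A <- oracle_boundary(pred); B <- oracle_boundary(truth)
  if (is.null(A) || is.null(B)) return(NaN)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

random_mask_pair <- function(dims = c(4, 16, 16), p = 0.3) {
  list(pred = array(as.integer(stats::runif(prod(dims)) < p), dims),
       truth = array(as.integer(stats::runif(prod(dims)) < p), dims))
}
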