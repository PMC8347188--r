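# Segmentation evaluation: overlap-based metrics (Dice, Jaccard,
# sensitivity, specificity), the volume-based volume similarity, and the
# surface-distance-based Hausdorff distance, plus the paired-method
# comparison table.  Degenerate denominators are flagged, never silently
# dropped: an empty prediction against a non-empty truth scores 0, and two
# empty masks agree perfectly (Dice 1 by convention).

#' Voxelwise confusion counts
#'
#' @param pred,truth binary masks ([binary_mask()]), logical/integer arrays
#'   or matrices on the same grid.
#' @return named integer vector `(TP, FP, FN, TN)` summing to the total
#'   voxel count.
#' @export
confusion_counts <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$voxels else pred
  t <- if (inherits(truth, "binary_mask")) truth$voxels else truth
  check_same_grid(list(voxels = p), list(voxels = t), "pred and truth")
  p <- p != 0; t <- t != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  c(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

#' Overlap-based metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), Jaccard = TP/(TP+FP+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).  When both masks are
#' empty, Dice and Jaccard are defined as 1 (perfect agreement on absence)
#' and flagged; other degenerate denominators yield `NaN` with a flag.
#'
#' @param counts output of [confusion_counts()].
#' @return list with `dice`, `jaccard`, `sensitivity`, `specificity` and a
#'   logical vector `defined` naming which metrics had a proper denominator.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  defined <- c(dice = TRUE, jaccard = TRUE, sensitivity = TRUE,
               specificity = TRUE)
  if (tp + fp + fn == 0) {        # both masks empty
    dice <- 1; jac <- 1
    defined[c("dice", "jaccard")] <- FALSE
  } else {
    dice <- 2 * tp / (2 * tp + fp + fn)
    jac <- tp / (tp + fp + fn)
  }
  if (tp + fn == 0) { sens <- NaN; defined["sensitivity"] <- FALSE }
  else sens <- tp / (tp + fn)
  if (tn + fp == 0) { spec <- NaN; defined["specificity"] <- FALSE }
  else spec <- tn / (tn + fp)
  list(dice = dice, jaccard = jac, sensitivity = sens, specificity = spec,
       defined = defined)
}

#' Volume similarity
#'
#' `VS = 1 - |FN - FP| / (2 TP + FP + FN)`, equivalently
#' `1 - |V_pred - V_truth| / (V_pred + V_truth)`: agreement of segment
#' volumes regardless of overlap, 1 when the two volumes are equal.
#'
#' @param counts output of [confusion_counts()].
#' @return scalar in \[0, 1\], or `NaN` with attribute `defined = FALSE`
#'   when both masks are empty.
#' @export
volume_similarity <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  den <- 2 * tp + fp + fn
  if (den == 0) return(structure(NaN, defined = FALSE))
  structure(1 - abs(fn - fp) / den, defined = TRUE)
}

#' @keywords internal
boundary_points <- function(mask, spacing = c(1, 1, 1), units = "voxel") {
  m <- mask_array(mask) != 0
  b <- mask_boundary(m)
  idx <- which(b, arr.ind = TRUE)  # columns: z, row, col (1-based)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  pts <- idx - 1
  if (units == "mm") {
    # index order (z, row, col) -> physical (slice, row, col) mm
    pts[, 1] <- pts[, 1] * spacing[3]
    pts[, 2] <- pts[, 2] * spacing[1]
    pts[, 3] <- pts[, 3] * spacing[2]
  }
  pts
}

# Directed max-min distance from points A to points B, chunked so the
# cross-distance matrix never exceeds ~40 MB.
#' @keywords internal
directed_hausdorff <- function(A, B) {
  nb2 <- rowSums(B^2)
  chunk <- max(1L, floor(5e6 / nrow(B)))
  worst <- 0
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    Ac <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), nb2, "+") - 2 * Ac %*% t(B)
    worst <- max(worst, max(apply(d2, 1, min)))
    i <- j + 1L
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two masks
#'
#' Maximum over both directions of the farthest nearest-point Euclidean
#' distance, computed on boundary voxels (identical to the filled-set
#' distance for digital sets, at a fraction of the cost).  `units = "voxel"`
#' treats the grid as isotropic unit cubes; `units = "mm"` scales index
#' deltas by the mask spacing.
#'
#' @param pred,truth binary masks or 3D arrays; both must be non-empty.
#' @param units `"voxel"` (default) or `"mm"`.
#' @param spacing used when `units = "mm"` and the inputs are bare arrays.
#' @return non-negative scalar; `NaN` with attribute `defined = FALSE` if
#'   either mask is empty.
#' @export
hausdorff_distance <- function(pred, truth, units = c("voxel", "mm"),
                               spacing = NULL) {
  units <- match.arg(units)
  check_same_grid(list(voxels = mask_array(pred)),
                  list(voxels = mask_array(truth)), "pred and truth")
  if (is.null(spacing))
    spacing <- if (inherits(pred, "binary_mask")) pred$spacing else c(1, 1, 1)
  A <- boundary_points(pred, spacing, units)
  B <- boundary_points(truth, spacing, units)
  if (nrow(A) == 0 || nrow(B) == 0) return(structure(NaN, defined = FALSE))
  structure(max(directed_hausdorff(A, B), directed_hausdorff(B, A)),
            defined = TRUE)
}

#' Full metrics report for one (prediction, truth) pair
#'
#' @param pred,truth binary masks or arrays on the same grid.
#' @param units Hausdorff units, `"voxel"` or `"mm"`.
#' @param spacing spacing for `units = "mm"` on bare arrays.
#' @return object of class `metrics_report`: confusion counts plus `dice`,
#'   `jaccard`, `sensitivity`, `specificity`, `volume_similarity`,
#'   `hausdorff`, and a `defined` logical vector.
#' @export
metrics_report <- function(pred, truth, units = "voxel", spacing = NULL) {
  counts <- confusion_counts(pred, truth)
  om <- overlap_metrics(counts)
  vs <- volume_similarity(counts)
  hd <- hausdorff_distance(pred, truth, units = units, spacing = spacing)
  structure(list(
    counts = counts,
    dice = om$dice, jaccard = om$jaccard,
    sensitivity = om$sensitivity, specificity = om$specificity,
    volume_similarity = as.numeric(vs),
    hausdorff = as.numeric(hd),
    defined = c(om$defined,
                volume_similarity = attr(vs, "defined"),
                hausdorff = attr(hd, "defined"))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$counts["TP"],
              x$counts["FP"], x$counts["FN"], x$counts["TN"]))
  for (m in c("dice", "jaccard", "sensitivity", "specificity",
              "volume_similarity", "hausdorff"))
    cat(sprintf("  %-18s %.4f%s\n", m, x[[m]],
                if (!x$defined[[m]]) " (degenerate)" else ""))
  invisible(x)
}

#' Per-slice metrics for a 3D pair
#'
#' Evaluates every axial slice independently, as done when building
#' slice-level comparison tables.  Slices where truth and prediction are
#' both empty can optionally be dropped (they carry no information about
#' the structure).
#'
#' @param pred,truth binary masks on the same grid.
#' @param keep_empty keep slices with empty truth and prediction.
#' @inheritParams metrics_report
#' @return data.frame, one row per evaluated slice, columns `slice` plus
#'   the six metrics.
#' @export
slice_metrics <- function(pred, truth, units = "voxel", spacing = NULL,
                          keep_empty = FALSE) {
  p <- mask_array(pred); t <- mask_array(truth)
  check_same_grid(list(voxels = p), list(voxels = t), "pred and truth")
  if (is.null(spacing))
    spacing <- if (inherits(pred, "binary_mask")) pred$spacing else c(1, 1, 1)
  rows <- list()
  for (z in seq_len(dim(p)[1])) {
    ps <- array(p[z, , ], dim = c(1, dim(p)[2], dim(p)[3]))
    ts <- array(t[z, , ], dim = c(1, dim(p)[2], dim(p)[3]))
    if (!keep_empty && sum(ps) == 0 && sum(ts) == 0) next
    r <- metrics_report(ps, ts, units = units, spacing = spacing)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = z, dice = r$dice, jaccard = r$jaccard,
      sensitivity = r$sensitivity, specificity = r$specificity,
      volume_similarity = r$volume_similarity,
      hausdorff = r$hausdorff)
  }
  if (length(rows) == 0)
    return(data.frame(slice = integer(0), dice = numeric(0),
                      jaccard = numeric(0), sensitivity = numeric(0),
                      specificity = numeric(0),
                      volume_similarity = numeric(0),
                      hausdorff = numeric(0)))
  do.call(rbind, rows)
}

#' Paired comparison of two methods
#'
#' Takes per-slice metric tables for two methods evaluated on the same
#' slices (as produced by [slice_metrics()]) and builds, per metric, the
#' mean +/- SD, min-max, and the two-tailed paired Student's t-test p
#' value.  Degenerate pairings (zero-variance differences) are flagged:
#' when the two methods agree exactly on every slice the p value is
#' reported as 1, otherwise as `NA`.
#'
#' @param a,b data.frames from [slice_metrics()]; rows are paired by
#'   position and must refer to the same slices.
#' @param metrics which metric columns to compare.
#' @return object of class `method_comparison`: a data.frame with one row
#'   per metric and columns `mean_a, sd_a, min_a, max_a, mean_b, sd_b,
#'   min_b, max_b, t, p, degenerate`.
#' @export
compare_methods <- function(a, b,
                            metrics = c("volume_similarity", "sensitivity",
                                        "specificity", "jaccard", "dice",
                                        "hausdorff")) {
  if (nrow(a) != nrow(b))
    stop("per-slice reports have different lengths; pairing impossible")
  if (nrow(a) < 2) stop("need at least 2 paired slices")
  if (!identical(a$slice, b$slice))
    stop("slice identities differ between the two reports")
  out <- lapply(metrics, function(m) {
    x <- a[[m]]; y <- b[[m]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    d <- y - x
    degenerate <- length(d) < 2 || stats::sd(d) == 0
    if (degenerate) {
      tt <- NA_real_
      p <- if (length(d) >= 1 && all(d == 0)) 1 else NA_real_
    } else {
      ht <- stats::t.test(y, x, paired = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(metric = m,
               mean_a = mean(x), sd_a = stats::sd(x),
               min_a = min(x), max_a = max(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               min_b = min(y), max_b = max(y),
               t = tt, p = p, degenerate = degenerate)
  })
  structure(do.call(rbind, out), class = c("method_comparison", "data.frame"))
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison (paired t-test, two-tailed), A vs B\n")
  cat(sprintf("%-18s %-23s %-23s %8s\n", "Metric",
              "A mean+/-SD [min-max]", "B mean+/-SD [min-max]", "p"))
  for (i in seq_len(nrow(x))) {
    p <- if (x$degenerate[i]) {
      if (is.na(x$p[i])) "degen." else sprintf("%.4f", x$p[i])
    } else if (x$p[i] < 1e-4) "<0.0001" else sprintf("%.4f", x$p[i])
    cat(sprintf("%-18s %.4f+/-%.4f [%.2f-%.2f] %.4f+/-%.4f [%.2f-%.2f] %8s\n",
                x$metric[i], x$mean_a[i], x$sd_a[i], x$min_a[i], x$max_a[i],
                x$mean_b[i], x$sd_b[i], x$min_b[i], x$max_b[i], p))
  }
  invisible(x)
}

#' Write a comparison table as delimited text
#'
#' @param x a `method_comparison`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
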