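# The hybrid workflow: the networks localise (spine, lumen, thrombus), the
# expert system refines.  Spine pixels predicted by the network are erased
# (set to 0 HU exactly), the lumen is re-segmented by
# the expert active contour seeded from the network's lumen mask, and raw
# network thrombus predictions are cleaned by lumen-adjacency component
# filtering plus per-slice elliptic smoothing.

#' Hybrid configuration
#'
#' @param spine_model,lumen_model,thrombus_model trained `unet_model`
#'   objects or paths to checkpoints saved with [save_unet()]; only the
#'   models needed by the operation being called are required.
#' @param threshold probability threshold applied to network maps
#'   (default 0.5).
#' @param component_connectivity 3D connectivity for thrombus component
#'   filtering (26, the only supported value).
#' @param interpolation apply per-slice elliptic smoothing to the thrombus.
#' @param ellipse_floor minimum Dice between the fitted ellipse and the
#'   unsmoothed region for the ellipse to replace it (guards genuinely
#'   non-elliptic sections).
#' @return object of class `hybrid_config`.
#' @export
hybrid_config <- function(spine_model = NULL, lumen_model = NULL,
                          thrombus_model = NULL, threshold = 0.5,
                          component_connectivity = 26,
                          interpolation = TRUE, ellipse_floor = 0.6) {
  stopifnot(threshold > 0, threshold < 1)
  if (component_connectivity != 26)
    stop("only 26-connectivity is supported")
  structure(list(spine_model = spine_model, lumen_model = lumen_model,
                 thrombus_model = thrombus_model, threshold = threshold,
                 component_connectivity = component_connectivity,
                 interpolation = interpolation,
                 ellipse_floor = ellipse_floor),
            class = "hybrid_config")
}

#' @keywords internal
resolve_model <- function(m, what) {
  if (is.null(m))
    stop(sprintf("hybrid workflow needs a trained %s model; none was provided",
                 what))
  if (is.character(m)) {
    if (!file.exists(m))
      stop(sprintf("%s model checkpoint '%s' does not exist", what, m))
    m <- load_unet(m)
  }
  stopifnot(inherits(m, "unet_model"))
  m
}

#' Erase the spine from a volume
#'
#' Voxels under the spine mask are set to 0 HU (exactly 0, deliberately,
#' even though 0 HU is water-like rather than air); every other
#' voxel is untouched.
#'
#' @param volume a [ct_volume()].
#' @param spine_mask a [binary_mask()] on the same grid.
#' @return a [ct_volume()].
#' @export
erase_spine <- function(volume, spine_mask) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- mask_array(spine_mask)
  check_same_grid(list(voxels = volume$voxels), list(voxels = m),
                  "volume and spine mask")
  vox <- volume$voxels
  vox[m != 0] <- 0
  ct_volume(vox, volume$spacing, clamp = FALSE)
}

#' Hybrid lumen segmentation
#'
#' The two-stage refinement at the heart of the hybrid: per-slice network prediction of
#' spine and lumen, thresholding at `cfg$threshold`, spine-pixel erasure,
#' then the expert-system lumen segmentation on the filtered volume with
#' the network's lumen mask replacing the brightness-based seed search
#' (the seed slice is the slice holding the largest predicted lumen
#' component).  If the network finds no lumen anywhere the expert seed
#' search is the fallback; if both fail the result carries
#' `status = "lumen-not-found"`.
#'
#' @param volume a [ct_volume()] (raw, not pre-processed; pre-processing
#'   happens internally after spine erasure).
#' @param cfg a [hybrid_config()] with `spine_model` and `lumen_model`.
#' @param expert_cfg an [expert_config()].
#' @return a [binary_mask()] with a `provenance` attribute recording the
#'   seed source actually used.
#' @export
segment_lumen_hybrid <- function(volume, cfg, expert_cfg = expert_config()) {
  spine_model <- resolve_model(cfg$spine_model, "spine")
  lumen_model <- resolve_model(cfg$lumen_model, "lumen")
  n_vox <- length(volume$voxels)
  spine_prob <- predict_unet(spine_model, volume)
  spine_net <- binary_mask(threshold_map(spine_prob, cfg$threshold),
                           "spine", volume$spacing)
  # plausibility gate: neither structure fills a quarter of the abdomen;
  # a prediction that large is a degenerate network, not anatomy, and
  # erasing it would destroy the volume
  spine_plausible <- sum(spine_net$voxels) <= 0.25 * n_vox
  if (!spine_plausible)
    spine_net <- binary_mask(array(0L, dim(volume$voxels)), "spine",
                             volume$spacing)
  lumen_prob <- predict_unet(lumen_model, volume)
  lumen_net <- binary_mask(threshold_map(lumen_prob, cfg$threshold),
                           "lumen", volume$spacing)
  lumen_plausible <- sum(lumen_net$voxels) <= 0.25 * n_vox
  filtered <- erase_spine(volume, spine_net)
  pre <- preprocess(filtered, expert_cfg)
  seed <- if (lumen_plausible && sum(lumen_net$voxels) > 0) lumen_net
          else NULL
  out <- segment_lumen(pre, spine_net, expert_cfg, seed_mask = seed)
  prov <- attr(out, "provenance")
  prov$network_spine_voxels <- sum(spine_net$voxels)
  prov$network_lumen_voxels <- sum(lumen_net$voxels)
  prov$spine_plausible <- spine_plausible
  prov$lumen_plausible <- lumen_plausible
  attr(out, "provenance") <- prov
  out
}

# --- elliptic smoothing -----------------------------------------------------

#' Moment-matched ellipse fit of a 2D region
#'
#' Matches the centroid and second-order moments of the region (with the
#' 1/12 unit-square correction, so a rasterised ellipse recovers its own
#' parameters).  Parameters are quantised - centre and semi-axes to 1/8
#' pixel, orientation to ~0.7 degrees - which makes rasterise-and-refit a
#' fixed point in practice and stabilises the smoothing across slices.
#'
#' @param m logical/0-1 matrix with at least 3 foreground pixels.
#' @return list `(center, a, b, theta)` (semi-axes in pixels, `theta` in
#'   radians), or `NULL` for degenerate regions.
#' @export
fit_ellipse_moments <- function(m) {
  m <- m != 0
  if (sum(m) < 3) return(NULL)
  mom <- region_moments(m)
  e <- eigen(mom$cov, symmetric = TRUE)
  if (any(e$values <= 0)) return(NULL)
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  theta <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  q <- function(x) round(x * 8) / 8
  theta <- round(theta / (pi / 256)) * (pi / 256)
  list(center = q(mom$centroid), a = q(a), b = q(b), theta = theta)
}

#' Rasterise a filled ellipse
#'
#' @param par ellipse parameters from [fit_ellipse_moments()].
#' @param dims `(rows, columns)` of the output matrix.
#' @return logical matrix; pixels whose centre lies inside the ellipse.
#' @export
fill_ellipse <- function(par, dims) {
  r <- rep(seq_len(dims[1]), times = dims[2]) - par$center[1]
  c <- rep(seq_len(dims[2]), each = dims[1]) - par$center[2]
  u <- cos(par$theta) * r + sin(par$theta) * c
  v <- -sin(par$theta) * r + cos(par$theta) * c
  matrix((u / par$a)^2 + (v / par$b)^2 <= 1, dims[1], dims[2])
}

#' Post-process a raw thrombus mask
#'
#' Two cleaning rules: (1) every 26-connected component of the
#' raw mask whose 1-voxel dilation does not intersect the lumen is removed
#' (a crescent thrombus touches but does not overlap the lumen, hence the
#' dilation); (2) per axial slice, an ellipse is fitted by second-order
#' moment matching to the combined (kept thrombus plus lumen) region and
#' the slice thrombus is replaced by (filled ellipse minus lumen) whenever
#' the fit's Dice against the unsmoothed region reaches
#' `cfg$ellipse_floor`.  The output is always disjoint from the lumen.
#'
#' @param raw a [binary_mask()] or 3D array of raw thrombus predictions.
#' @param lumen the lumen [binary_mask()] on the same grid.
#' @param cfg a [hybrid_config()] (`interpolation = FALSE` skips step 2).
#' @return a [binary_mask()] labelled `"thrombus"`.
#' @export
postprocess_thrombus <- function(raw, lumen, cfg = hybrid_config()) {
  r <- mask_array(raw); l <- mask_array(lumen)
  check_same_grid(list(voxels = r), list(voxels = l), "raw and lumen")
  spacing <- if (inherits(lumen, "binary_mask")) lumen$spacing else c(1, 1, 1)
  if (sum(r) == 0)
    return(binary_mask(array(0L, dim(r)), "thrombus", spacing))
  lum_dil <- dilate26(l != 0)
  labels <- label_components_3d(r != 0)
  keep_labels <- sort(unique(labels[labels > 0L & lum_dil]))
  kept <- array(labels %in% keep_labels & labels > 0L, dim(r))
  if (isTRUE(cfg$interpolation)) {
    d <- dim(r)
    for (z in seq_len(d[1])) {
      thr_z <- matrix(kept[z, , ], d[2], d[3])
      if (!any(thr_z)) next
      lum_z <- matrix(l[z, , ] != 0, d[2], d[3])
      region <- thr_z | lum_z
      par <- fit_ellipse_moments(region)
      if (is.null(par)) next
      # iterate fit/rasterise to its fixed point so the smoothing is
      # idempotent (an already-elliptic section passes through unchanged)
      ell <- fill_ellipse(par, d[2:3])
      for (k in 1:4) {
        par2 <- fit_ellipse_moments(ell)
        if (is.null(par2)) break
        ell2 <- fill_ellipse(par2, d[2:3])
        if (identical(ell2, ell)) break
        ell <- ell2
      }
      if (dice2d(ell, region) >= cfg$ellipse_floor)
        kept[z, , ] <- ell & !lum_z
    }
  }
  kept <- kept & !(l != 0)
  binary_mask(kept, "thrombus", spacing)
}

#' Hybrid thrombus segmentation
#'
#' Per-slice network prediction, thresholding at `cfg$threshold`, then
#' [postprocess_thrombus()] (lumen-adjacency component filtering and
#' elliptic smoothing).
#'
#' @param volume a [ct_volume()].
#' @param lumen the segmented lumen [binary_mask()].
#' @param cfg a [hybrid_config()] with `thrombus_model`.
#' @return a [binary_mask()] labelled `"thrombus"`, disjoint from the
#'   lumen.
#' @export
segment_thrombus_hybrid <- function(volume, lumen, cfg) {
  model <- resolve_model(cfg$thrombus_model, "thrombus")
  prob <- predict_unet(model, volume)
  th <- threshold_map(prob, cfg$threshold)
  # plausibility gate as in the lumen path: a thrombus covering a quarter
  # of the volume is a degenerate prediction
  if (sum(th) > 0.25 * length(th)) th[] <- 0L
  raw <- binary_mask(th, "thrombus", volume$spacing)
  postprocess_thrombus(raw, lumen, cfg)
}
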