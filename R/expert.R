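# The feature-based expert system: Gaussian pre-processing, spine
# segmentation by bone thresholding + gap closing + posterior restriction,
# lumen segmentation by windowed seed search, morphological active contour
# refinement and slice-to-slice boundary propagation, and thrombus
# segmentation by a morphological snake initialised from the lumen.
# Everything here is deterministic: no randomness anywhere in this module.

#' Expert-system configuration
#'
#' Every tunable of the rule pipeline, with its default written out.
#' Thresholds are in Hounsfield units, physical sizes in millimetres.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in mm (isotropic in
#'   physical space; converted per axis via the voxel spacing).
#' @param bone_threshold HU above which a voxel is bone candidate.
#' @param lumen_window `(low, high)` HU window for contrast-filled lumen
#'   candidates.  May overlap the bone range; disambiguation is spatial.
#' @param seed_search_fraction fraction of the anterior-of-spine rows
#'   searched for the seed (anterior search box).
#' @param seed_min_area_mm2 minimum in-plane seed area.
#' @param seed_eccentricity_max upper bound on the moment eccentricity of
#'   an admissible seed (the aortic cross-section is roughly circular).
#' @param seed_intensity_margin minimum excess (HU) of a network-proposed
#'   seed component's mean over its slice median; the contrast-filled
#'   lumen is always bright against soft tissue, so a dim proposal is a
#'   network false positive.
#' @param acwe_iterations morphological active-contour steps for the lumen.
#' @param acwe_smoothing curvature smoothing passes per step.
#' @param propagation_overlap_min minimum Dice overlap between the
#'   propagated initialisation and the converged region for a slice to be
#'   accepted.
#' @param spine_closing_mm radius of the morphological closing that bridges
#'   inter-vertebral gaps.
#' @param thrombus_dilation_mm radius of the lumen dilation used to
#'   initialise the thrombus snake.
#' @param thrombus_acwe_iterations snake steps for the thrombus.
#' @param thrombus_window `(low, high)` HU clamp applied before the
#'   thrombus snake (soft-tissue window).
#' @param thrombus_smooth_mm extra in-plane Gaussian smoothing applied to
#'   the windowed slice before the thrombus snake; the thrombus/background
#'   contrast is an order of magnitude fainter than the lumen's, so the
#'   snake needs stronger noise suppression than the global pre-processing
#'   provides.
#' @param thrombus_min_area_mm2 minimum in-plane area of a detected
#'   thrombus component.
#' @param thrombus_min_contrast minimum excess (HU) of a detected
#'   component's mean intensity over the surrounding background; together
#'   with the area and lumen-adjacency requirements this rejects the
#'   scattered blobs the snake accretes from noise on slices with no
#'   thrombus to find.
#' @return object of class `expert_config`.
#' @export
expert_config <- function(smoothing_sigma = 0.5,
                          bone_threshold = 200,
                          lumen_window = c(150, 600),
                          seed_search_fraction = 0.9,
                          seed_min_area_mm2 = 20,
                          seed_eccentricity_max = 0.95,
                          seed_intensity_margin = 30,
                          acwe_iterations = 40,
                          acwe_smoothing = 1,
                          propagation_overlap_min = 0.5,
                          spine_closing_mm = 5,
                          thrombus_dilation_mm = 6,
                          thrombus_acwe_iterations = 40,
                          thrombus_window = c(-20, 80),
                          thrombus_smooth_mm = 0.8,
                          thrombus_min_area_mm2 = 25,
                          thrombus_min_contrast = 6) {
  if (lumen_window[1] >= lumen_window[2])
    stop("lumen_window low must be < high")
  if (acwe_iterations < 1 || thrombus_acwe_iterations < 1)
    stop("iteration counts must be >= 1")
  if (propagation_overlap_min <= 0 || propagation_overlap_min > 1)
    stop("propagation_overlap_min must be in (0, 1]")
  structure(list(
    smoothing_sigma = smoothing_sigma, bone_threshold = bone_threshold,
    lumen_window = lumen_window,
    seed_search_fraction = seed_search_fraction,
    seed_min_area_mm2 = seed_min_area_mm2,
    seed_eccentricity_max = seed_eccentricity_max,
    seed_intensity_margin = seed_intensity_margin,
    acwe_iterations = acwe_iterations, acwe_smoothing = acwe_smoothing,
    propagation_overlap_min = propagation_overlap_min,
    spine_closing_mm = spine_closing_mm,
    thrombus_dilation_mm = thrombus_dilation_mm,
    thrombus_acwe_iterations = thrombus_acwe_iterations,
    thrombus_window = thrombus_window,
    thrombus_smooth_mm = thrombus_smooth_mm,
    thrombus_min_area_mm2 = thrombus_min_area_mm2,
    thrombus_min_contrast = thrombus_min_contrast), class = "expert_config")
}

#' Write / read an expert configuration as YAML
#'
#' Every field, including defaults, is written out so each run is fully
#' auditable.
#'
#' @param cfg an [expert_config()].
#' @param path YAML file.
#' @return `path` (write) or an `expert_config` (read).
#' @export
write_expert_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_expert_config
#' @export
read_expert_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(expert_config, vals)
}

#' Pre-process a CT volume
#'
#' Gaussian smoothing with a physical sigma converted per axis via the
#' voxel spacing; the HU range is preserved and `sigma = 0` is the
#' identity.
#'
#' @param volume a [ct_volume()].
#' @param cfg an [expert_config()].
#' @return smoothed [ct_volume()].
#' @export
preprocess <- function(volume, cfg = expert_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (cfg$smoothing_sigma <= 0) return(volume)
  sig_vox <- cfg$smoothing_sigma / volume$spacing[c(3, 1, 2)]  # (z, row, col)
  out <- gauss3d(volume$voxels, sig_vox)
  ct_volume(out, volume$spacing, clamp = FALSE)
}

#' Segment the spine
#'
#' Bone thresholding, morphological closing (bridging the inter-vertebral
#' gaps so one vertebral column forms a single 3D component), and
#' restriction to 3D connected components whose centroid lies in the
#' posterior half of the slice.  Returns an empty mask with a warning when
#' nothing exceeds the bone threshold.
#'
#' @param volume a (preferably pre-processed) [ct_volume()].
#' @param cfg an [expert_config()].
#' @return a [binary_mask()] labelled `"spine"`.
#' @export
segment_spine <- function(volume, cfg = expert_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  vox <- volume$voxels
  th <- vox >= cfg$bone_threshold
  if (!any(th)) {
    warning("no voxel above the bone threshold; returning an empty spine mask")
    return(binary_mask(array(0L, dim(vox)), "spine", volume$spacing))
  }
  # anisotropic closing: the inter-vertebral gaps run along z, so the
  # bridging element is tall in z and only 1 voxel in-plane (an isotropic
  # ball would fuse the vertebral column with a nearby aneurysm)
  rz <- max(1L, as.integer(ceiling(cfg$spine_closing_mm / volume$spacing[3])))
  closed <- close_box(th, c(rz, 1L, 1L))
  labels <- label_components_3d(closed)
  nr <- dim(vox)[2]
  pos <- which(labels > 0L)
  rows <- arrayInd(pos, dim(labels))[, 2]
  centroid_row <- tapply(rows, labels[pos], mean)
  keep <- as.integer(names(centroid_row))[centroid_row > nr / 2]
  mask <- th & array(labels %in% keep, dim(vox))
  binary_mask(mask, "spine", volume$spacing)
}

#' @keywords internal
region_moments <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
  # unit-square (1/12) correction so a digitised disc matches its
  # continuous moments
  crr <- sum((idx[, 1] - mu_r)^2) / n + 1 / 12
  ccc <- sum((idx[, 2] - mu_c)^2) / n + 1 / 12
  crc <- sum((idx[, 1] - mu_r) * (idx[, 2] - mu_c)) / n
  list(n = n, centroid = c(mu_r, mu_c), cov = matrix(c(crr, crc, crc, ccc), 2))
}

#' @keywords internal
region_eccentricity <- function(m) {
  mom <- region_moments(m)
  ev <- eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(pmax(0, 1 - ev[2] / ev[1]))
}

# Admissible lumen seed in one slice: largest windowed, round-ish,
# anterior-of-spine component; ties broken by centroid distance to the
# spine midline column.
#' @keywords internal
find_seed_in_slice <- function(sl, cfg, spacing, spine_row, spine_col) {
  nr <- nrow(sl); nc <- ncol(sl)
  w <- sl >= cfg$lumen_window[1] & sl <= cfg$lumen_window[2]
  anterior_limit <- floor(spine_row)
  search_rows <- max(1, floor(spine_row - cfg$seed_search_fraction * nr)):
    anterior_limit
  keep_rows <- rep(FALSE, nr); keep_rows[search_rows] <- TRUE
  w <- w & matrix(keep_rows, nr, nc)
  if (!any(w)) return(NULL)
  lab <- EBImage::bwlabel(matrix(as.numeric(w), nr, nc))
  lab <- matrix(as.integer(lab), nr, nc)
  min_area <- cfg$seed_min_area_mm2 / (spacing[1] * spacing[2])
  best <- NULL; best_area <- -Inf; best_mid <- Inf
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    area <- sum(comp)
    if (area < min_area) next
    if (region_eccentricity(comp) > cfg$seed_eccentricity_max) next
    mid_dist <- abs(region_moments(comp)$centroid[2] - spine_col)
    if (area > best_area || (area == best_area && mid_dist < best_mid)) {
      best <- comp; best_area <- area; best_mid <- mid_dist
    }
  }
  best
}

#' @keywords internal
roi_around <- function(m, margin) {
  idx <- which(m != 0, arr.ind = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  rr <- max(1, min(idx[, 1]) - margin):min(nr, max(idx[, 1]) + margin)
  cc <- max(1, min(idx[, 2]) - margin):min(nc, max(idx[, 2]) + margin)
  out <- matrix(FALSE, nr, nc)
  out[rr, cc] <- TRUE
  out
}

#' @keywords internal
dice2d <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Segment the arterial lumen
#'
#' Three stages: (1) seed search - in the mid-volume slice (scanning
#' outward if needed), the largest bright connected region inside the
#' lumen HU window, anterior to the spine centroid and of roughly circular
#' shape, is the seed; (2) the seed is refined by a morphological active
#' contour (region-based Chan-Vese energy); (3) boundary propagation - the
#' converged contour of each slice initialises its neighbour, accepted
#' while the Dice overlap between initialisation and converged region
#' stays above `propagation_overlap_min`, proceeding in both directions.
#'
#' When a network-predicted `seed_mask` is supplied (the hybrid workflow),
#' the brightness-based seed search is replaced: the seed slice is the
#' slice holding the largest predicted component.  With no admissible seed
#' anywhere, an empty mask is returned with `status = "lumen-not-found"`.
#'
#' @param volume a pre-processed [ct_volume()].
#' @param spine a [binary_mask()] (may be empty).
#' @param cfg an [expert_config()].
#' @param seed_mask optional 3D [binary_mask()] of predicted lumen used as
#'   seed source.
#' @return a [binary_mask()] labelled `"lumen"`, with attribute
#'   `provenance`: a list with `status` (`"ok"` or `"lumen-not-found"`),
#'   `seed_source` (`"expert"` or `"network"`), and `seed_slice`.
#' @export
segment_lumen <- function(volume, spine, cfg = expert_config(),
                          seed_mask = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  vox <- volume$voxels
  d <- dim(vox); nz <- d[1]; nr <- d[2]; nc <- d[3]
  sp <- if (!is.null(spine)) mask_array(spine) else array(0L, d)
  if (sum(sp) > 0) {
    idx <- which(sp != 0, arr.ind = TRUE)
    spine_row <- mean(idx[, 2]); spine_col <- mean(idx[, 3])
  } else {
    spine_row <- 0.75 * nr; spine_col <- nc / 2
  }

  empty_result <- function() {
    m <- binary_mask(array(0L, d), "lumen", volume$spacing)
    attr(m, "provenance") <- list(status = "lumen-not-found",
                                  seed_source = NA_character_,
                                  seed_slice = NA_integer_)
    m
  }

  seed <- NULL; seed_slice <- NA_integer_; seed_source <- NA_character_
  if (!is.null(seed_mask) && sum(mask_array(seed_mask)) > 0) {
    sm <- mask_array(seed_mask) != 0
    # seed slice: the slice holding the largest predicted in-plane
    # component that is admissible as a lumen seed - sizeable, roughly
    # round, and bright against its slice background (a spurious blob on
    # soft tissue, or on the erased spine, fails the intensity margin)
    min_px <- cfg$seed_min_area_mm2 / prod(volume$spacing[1:2])
    best_area <- 0
    for (z in seq_len(nz)) {
      smz <- matrix(sm[z, , ], nr, nc)
      if (!any(smz)) next
      lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(smz),
                                                       nr, nc))), nr, nc)
      slz <- matrix(vox[z, , ], nr, nc)
      bg_level <- stats::median(slz)
      for (l in seq_len(max(lab))) {
        comp <- lab == l
        area <- sum(comp)
        if (area <= best_area || area < min_px) next
        if (region_eccentricity(comp) > cfg$seed_eccentricity_max) next
        if (mean(slz[comp]) - bg_level < cfg$seed_intensity_margin) next
        best_area <- area; seed <- comp; seed_slice <- z
      }
    }
    if (best_area > 0) seed_source <- "network"
  }
  if (is.null(seed)) {
    mid <- round(nz / 2)
    for (z in order(abs(seq_len(nz) - mid))) {
      s <- find_seed_in_slice(matrix(vox[z, , ], nr, nc), cfg,
                              volume$spacing, spine_row, spine_col)
      if (!is.null(s)) { seed <- s; seed_slice <- z; seed_source <- "expert"; break }
    }
    if (is.null(seed)) return(empty_result())
  }

  margin <- max(10L, as.integer(round(25 / min(volume$spacing[1:2]))))
  refine <- function(z, init) {
    sl <- matrix(vox[z, , ], nr, nc)
    roi <- roi_around(init, margin)
    res <- morph_acwe(sl, init, iterations = cfg$acwe_iterations,
                      smoothing = cfg$acwe_smoothing, roi = roi)
    if (sum(res) == 0) return(res)
    # keep the component continuing the propagated region
    lab <- EBImage::bwlabel(res)
    lab <- matrix(as.integer(lab), nr, nc)
    ov <- tabulate(lab[init & lab > 0], nbins = max(lab))
    if (all(ov == 0)) {
      sizes <- tabulate(lab[lab > 0])
      matrix(as.integer(lab == which.max(sizes)), nr, nc)
    } else matrix(as.integer(lab == which.max(ov)), nr, nc)
  }

  out <- array(0L, d)
  cur <- refine(seed_slice, seed)
  if (sum(cur) == 0) return(empty_result())
  out[seed_slice, , ] <- cur
  for (dir in c(1L, -1L)) {
    prev <- matrix(out[seed_slice, , ], nr, nc)
    z <- seed_slice + dir
    while (z >= 1 && z <= nz) {
      if (sum(prev) == 0) break
      res <- refine(z, prev)
      if (dice2d(res == 1, prev == 1) < cfg$propagation_overlap_min) break
      out[z, , ] <- res
      prev <- res
      z <- z + dir
    }
  }
  m <- binary_mask(out, "lumen", volume$spacing)
  attr(m, "provenance") <- list(status = "ok", seed_source = seed_source,
                                seed_slice = seed_slice)
  m
}

#' Segment the intraluminal thrombus with a morphological snake
#'
#' For every slice containing lumen, the snake region is initialised as the
#' lumen dilated by `thrombus_dilation_mm` and evolved on the soft-tissue
#' windowed slice.  The region statistics exclude the lumen pixels (whose
#' clamped brightness would otherwise drown the faint thrombus/background
#' contrast); the converged region minus the lumen is the thrombus.
#'
#' @param volume a pre-processed [ct_volume()].
#' @param lumen a non-empty [binary_mask()] of the lumen (the snake is
#'   undefined without its initialisation).
#' @param cfg an [expert_config()].
#' @return a [binary_mask()] labelled `"thrombus"`, disjoint from the
#'   lumen.
#' @export
segment_thrombus <- function(volume, lumen, cfg = expert_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  lum <- mask_array(lumen)
  if (sum(lum) == 0)
    stop("empty lumen mask: the thrombus snake has no initialisation")
  check_same_grid(list(voxels = volume$voxels), list(voxels = lum))
  d <- dim(volume$voxels); nz <- d[1]; nr <- d[2]; nc <- d[3]
  r_dil <- max(1L, as.integer(round(
    cfg$thrombus_dilation_mm / mean(volume$spacing[1:2]))))
  # partial-volume halo around the bright lumen (from the two smoothing
  # stages); its values are neither lumen nor reliable thrombus samples
  halo_px <- max(2L, as.integer(ceiling(
    (cfg$thrombus_smooth_mm + cfg$smoothing_sigma) /
      mean(volume$spacing[1:2]))) + 1L)
  sig_px <- cfg$thrombus_smooth_mm / volume$spacing[1:2]
  Kr <- gauss_kernel_matrix(nr, sig_px[1])
  Kc <- gauss_kernel_matrix(nc, sig_px[2])
  out <- array(0L, d)
  for (z in seq_len(nz)) {
    lz <- matrix(lum[z, , ] != 0, nr, nc)
    if (!any(lz)) next
    sl <- matrix(volume$voxels[z, , ], nr, nc)
    sl <- pmin(pmax(sl, cfg$thrombus_window[1]), cfg$thrombus_window[2])
    if (!is.null(Kr) && !is.null(Kc)) sl <- Kr %*% sl %*% t(Kc)
    init <- dilate_disc2d(lz, r_dil)
    roi <- roi_around(init, max(5L, r_dil))
    core <- dilate_disc2d(lz, halo_px)
    bg_ring <- roi & !init
    cand <- init & !core
    if (!any(cand) || !any(bg_ring)) next
    # robust intensity anchors: background from beyond the search annulus,
    # thrombus from the upper quantile of the annulus itself
    bg_est <- stats::median(sl[bg_ring])
    thr_est <- stats::quantile(sl[cand], 0.85, names = FALSE)
    if (thr_est - bg_est < cfg$thrombus_min_contrast) next  # nothing to find
    sl2 <- sl
    sl2[core] <- bg_est   # neutralise the halo so the snake cannot creep
                          # around the lumen on partial-volume brightness
    seed <- cand & sl >= (thr_est + bg_est) / 2
    if (!any(seed)) next
    res <- morph_acwe(sl2, seed, iterations = cfg$thrombus_acwe_iterations,
                      smoothing = cfg$acwe_smoothing, roi = roi)
    thr_px <- res == 1 & !lz & !core
    # radial completion: fill the neutralised band between a detected
    # crescent and the lumen wall
    thr_px <- thr_px | (core & !lz & dilate_disc2d(thr_px, halo_px + 1L))
    if (!any(thr_px)) next
    # component gate: sizeable, lumen-adjacent, and clearly brighter than
    # the background (judged outside the halo)
    lab <- EBImage::bwlabel(matrix(as.numeric(thr_px), nr, nc))
    lab <- matrix(as.integer(lab), nr, nc)
    lum_adj <- dilate_disc2d(lz, 1L)
    min_px <- cfg$thrombus_min_area_mm2 / prod(volume$spacing[1:2])
    kept <- matrix(FALSE, nr, nc)
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      if (sum(comp) < min_px) next
      if (!any(comp & lum_adj)) next
      smp <- comp & !core
      if (!any(smp)) next
      if (mean(sl[smp]) - bg_est < cfg$thrombus_min_contrast) next
      kept <- kept | comp
    }
    out[z, , ] <- as.integer(kept)
  }
  binary_mask(out, "thrombus", volume$spacing)
}
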