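# Synthetic abdominal CTA phantoms: a bright contrast-filled lumen tube with
# an optional aneurysmal bulge, a hypodense crescent thrombus lining the
# bulge, a posterior bony spine column with periodic inter-vertebral gaps,
# soft-tissue background and Gaussian noise.  Two regimes are emulated: a
# high-contrast thin-slice acquisition ("aaa" mode) and a degraded one with
# lower contrast, thicker slices and more noise ("ami" mode).

#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parametric description of a synthetic abdominal CTA phantom
#'
#' All geometry is in millimetres; positions are fractions of the slice
#' extent (rows increase anterior to posterior, so the spine sits at a row
#' fraction > 0.5).  `contrast_scale` multiplies the lumen-minus-background
#' HU difference: 1 emulates a well-injected thin-slice scan, values below 1
#' emulate poorly enhanced acquisitions.  `noise_sd` is the additive
#' Gaussian noise SD (in HU) for soft-tissue background; other tissue
#' classes scale proportionally to their catalogued SD, so `noise_sd = 0`
#' yields exact class means everywhere.
#'
#' @param slice_shape `(rows, columns)`; default `c(128, 128)` (desk scale;
#'   the full 512 x 512 uses the same code path).
#' @param n_slices number of axial slices (>= 8).
#' @param spacing `(row mm, column mm, slice mm)`.
#' @param lumen_center `(row fraction, column fraction)` of the straight
#'   centerline.
#' @param lumen_curvature_mm amplitude of a sinusoidal in-plane (column)
#'   bow of the centerline over the stack; 0 for a straight tube.
#' @param lumen_radius_mm baseline lumen radius.
#' @param bulge present/absent aneurysmal bulge.
#' @param bulge_radius_mm peak lumen radius inside the bulge.
#' @param bulge_span `(start, end)` as fractions of the stack.
#' @param thrombus crescent thrombus lining the bulge (posterior side).
#' @param thrombus_thickness_mm peak crescent thickness at the posterior.
#' @param spine_center `(row fraction, column fraction)` of the vertebral
#'   column (must lie in the posterior half).
#' @param spine_radius_mm vertebral body radius.
#' @param vertebra_mm,gap_mm vertebral body length and inter-vertebral gap
#'   along z, giving the periodic gaps that break naive 3D connectivity.
#' @param hu named list of `(mean, sd)` HU pairs for `background`, `bone`,
#'   `lumen`, `thrombus`.
#' @param noise_sd additive Gaussian noise SD in HU (see above).
#' @param contrast_scale multiplier in (0, 1] on the lumen-background
#'   contrast.
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @param mode `"aaa"` (defaults as given) or `"ami"`, which overrides
#'   `contrast_scale = 0.5`, slice spacing 2.5 mm and `noise_sd = 30`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(slice_shape = c(128, 128),
                         n_slices = 32,
                         spacing = c(0.8, 0.8, 1.0),
                         lumen_center = c(0.42, 0.5),
                         lumen_curvature_mm = 0,
                         lumen_radius_mm = 8,
                         bulge = TRUE,
                         bulge_radius_mm = 16,
                         bulge_span = c(0.35, 0.75),
                         thrombus = TRUE,
                         thrombus_thickness_mm = 6,
                         spine_center = c(0.78, 0.5),
                         spine_radius_mm = 12,
                         vertebra_mm = 22,
                         gap_mm = 4,
                         hu = list(background = c(40, 15),
                                   bone = c(700, 100),
                                   lumen = c(300, 30),
                                   thrombus = c(50, 15)),
                         noise_sd = 15,
                         contrast_scale = 1,
                         seed = 1L,
                         mode = c("aaa", "ami")) {
  mode <- match.arg(mode)
  if (mode == "ami") {
    contrast_scale <- 0.5
    spacing[3] <- 2.5
    noise_sd <- 30
  }
  spec <- list(slice_shape = as.integer(slice_shape),
               n_slices = as.integer(n_slices), spacing = as.numeric(spacing),
               lumen_center = lumen_center,
               lumen_curvature_mm = lumen_curvature_mm,
               lumen_radius_mm = lumen_radius_mm,
               bulge = bulge, bulge_radius_mm = bulge_radius_mm,
               bulge_span = bulge_span, thrombus = thrombus,
               thrombus_thickness_mm = thrombus_thickness_mm,
               spine_center = spine_center, spine_radius_mm = spine_radius_mm,
               vertebra_mm = vertebra_mm, gap_mm = gap_mm, hu = hu,
               noise_sd = noise_sd, contrast_scale = contrast_scale,
               seed = as.integer(seed), mode = mode)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @keywords internal
validate_phantom_spec <- function(spec) {
  if (spec$n_slices < 8) stop("n_slices must be >= 8")
  if (any(spec$spacing <= 0)) stop("spacing must be strictly positive")
  if (spec$contrast_scale <= 0 || spec$contrast_scale > 1)
    stop("contrast_scale must be in (0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$spine_center[1] <= 0.5)
    stop("spine_center row fraction must be > 0.5 (posterior half)")
  invisible(spec)
}

#' @keywords internal
bulge_profile <- function(spec) {
  z <- seq_len(spec$n_slices)
  frac <- (z - 0.5) / spec$n_slices
  bump <- numeric(spec$n_slices)
  if (spec$bulge) {
    lo <- spec$bulge_span[1]; hi <- spec$bulge_span[2]
    inside <- frac >= lo & frac <= hi
    s <- (frac[inside] - lo) / (hi - lo)
    bump[inside] <- 0.5 * (1 - cos(2 * pi * s))   # raised cosine, 0..1..0
  }
  bump
}

#' Generate one synthetic CTA phantom
#'
#' Rasterises the spec geometry into ground-truth spine/lumen/thrombus
#' masks, composes the HU volume as the per-class mean rasterisation plus
#' Gaussian noise, and clamps to the representable HU range.  Deterministic
#' for a fixed spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([ct_volume()]), `masks` (named list of
#'   [binary_mask()]: `spine`, `lumen`, `thrombus`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$slice_shape[1]; nc <- spec$slice_shape[2]
  nz <- spec$n_slices
  sr <- spec$spacing[1]; sc <- spec$spacing[2]; sz <- spec$spacing[3]
  rows_mm <- (seq_len(nr) - 0.5) * sr
  cols_mm <- (seq_len(nc) - 0.5) * sc
  extent_r <- nr * sr; extent_c <- nc * sc

  bump <- bulge_profile(spec)
  rl <- spec$lumen_radius_mm +
    (spec$bulge_radius_mm - spec$lumen_radius_mm) * bump
  thick <- if (spec$thrombus) spec$thrombus_thickness_mm * bump
           else numeric(nz)

  r0 <- spec$lumen_center[1] * extent_r
  c0 <- spec$lumen_center[2] * extent_c
  zfrac <- (seq_len(nz) - 0.5) / nz
  c0z <- c0 + spec$lumen_curvature_mm * sin(pi * zfrac)

  sp_r <- spec$spine_center[1] * extent_r
  sp_c <- spec$spine_center[2] * extent_c
  period <- spec$vertebra_mm + spec$gap_mm
  zpos <- (seq_len(nz) - 0.5) * sz
  spine_on <- (zpos %% period) < spec$vertebra_mm

  lumen <- array(0L, c(nz, nr, nc))
  thr <- array(0L, c(nz, nr, nc))
  spine <- array(0L, c(nz, nr, nc))
  dr2_rows <- function(center) (rows_mm - center)^2
  for (z in seq_len(nz)) {
    d2 <- outer(dr2_rows(r0), (cols_mm - c0z[z])^2, "+")
    lum_z <- d2 <= rl[z]^2
    lumen[z, , ] <- lum_z
    if (thick[z] > 1e-6) {
      ro <- rl[z] + thick[z] / 2
      oc_r <- r0 + thick[z] / 2
      # posterior-shifted outer ellipse, slightly wider than tall
      e <- outer((rows_mm - oc_r)^2 / ro^2,
                 (cols_mm - c0z[z])^2 / (1.1 * ro)^2, "+")
      outer_z <- e <= 1
      if (oc_r + ro > extent_r - 2 * sr || r0 - rl[z] < 2 * sr ||
          c0z[z] + 1.1 * ro > extent_c - 2 * sc ||
          c0z[z] - 1.1 * ro < 2 * sc)
        stop("geometric impossibility: aneurysmal bulge plus thrombus exceeds the slice bounds")
      thr[z, , ] <- outer_z & !lum_z
    }
    if (spine_on[z]) {
      d2s <- outer((rows_mm - sp_r)^2, (cols_mm - sp_c)^2, "+")
      spine[z, , ] <- d2s <= spec$spine_radius_mm^2
    }
  }
  if (any(spine & (lumen | thr)))
    stop("geometric impossibility: spine overlaps the vessel")
  if (any(spine[, seq_len(floor(nr / 2)), ] != 0))
    stop("geometric impossibility: spine extends into the anterior half")

  bg_mu <- spec$hu$background[1]
  lum_mu <- bg_mu + spec$contrast_scale * (spec$hu$lumen[1] - bg_mu)
  vol <- array(bg_mu, c(nz, nr, nc))
  vol[thr == 1L] <- spec$hu$thrombus[1]
  vol[lumen == 1L] <- lum_mu
  vol[spine == 1L] <- spec$hu$bone[1]

  if (spec$noise_sd > 0) {
    scale <- spec$noise_sd / spec$hu$background[2]
    sdmap <- array(spec$hu$background[2], c(nz, nr, nc))
    sdmap[thr == 1L] <- spec$hu$thrombus[2]
    sdmap[lumen == 1L] <- spec$hu$lumen[2]
    sdmap[spine == 1L] <- spec$hu$bone[2]
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(length(vol)), dim(vol))) *
      sdmap * scale
  }

  list(volume = ct_volume(vol, spec$spacing),
       masks = list(
         spine = binary_mask(spine, "spine", spec$spacing),
         lumen = binary_mask(lumen, "lumen", spec$spacing),
         thrombus = binary_mask(thr, "thrombus", spec$spacing)),
       spec = spec)
}

#' Generate a reproducible phantom dataset
#'
#' Samples `n_volumes` specs around `base_spec` from uniform jitter ranges,
#' with per-volume seeds derived from the master seed.  An empty jitter
#' list reproduces `base_spec` exactly (apart from the per-volume seed).
#'
#' @param n_volumes number of phantoms (>= 1).
#' @param base_spec a [phantom_spec()].
#' @param jitter named list of `c(min, max)` ranges over numeric spec
#'   fields (e.g. `lumen_radius_mm`, `contrast_scale`, `noise_sd`,
#'   `slice_mm` for the slice spacing, `lumen_curvature_mm`).
#' @param seed master seed.
#' @param out_dir if given, every volume and mask is written as NIfTI and a
#'   tab-delimited manifest `manifest.tsv` is written alongside.
#' @return list of phantoms (as from [generate_phantom()]); when `out_dir`
#'   is given, the manifest data.frame is attached as attribute
#'   `"manifest"`.
#' @export
generate_dataset <- function(n_volumes, base_spec, jitter = list(),
                             seed = 1L, out_dir = NULL) {
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  draws <- with_seed(seed, {
    vol_seeds <- sample.int(2^31 - 2, n_volumes)
    jit <- lapply(seq_len(n_volumes), function(i)
      vapply(jitter, function(rg) stats::runif(1, rg[1], rg[2]), numeric(1)))
    list(seeds = vol_seeds, jit = jit)
  })
  phantoms <- vector("list", n_volumes)
  rows <- list()
  for (i in seq_len(n_volumes)) {
    spec <- base_spec
    jv <- draws$jit[[i]]
    for (nm in names(jv)) {
      if (nm == "slice_mm") spec$spacing[3] <- jv[[nm]]
      else spec[[nm]] <- jv[[nm]]
    }
    spec$seed <- draws$seeds[i]
    ph <- generate_phantom(spec)
    phantoms[[i]] <- ph
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      vpath <- file.path(out_dir, sprintf("phantom_%03d.nii.gz", i))
      write_nifti(ph$volume, vpath)
      mpaths <- vapply(names(ph$masks), function(nm) {
        p <- file.path(out_dir, sprintf("phantom_%03d_%s.nii.gz", i, nm))
        write_nifti(ph$masks[[nm]], p)
        p
      }, character(1))
      rows[[i]] <- data.frame(
        volume = vpath, spine = mpaths["spine"], lumen = mpaths["lumen"],
        thrombus = mpaths["thrombus"], seed = spec$seed,
        contrast_scale = spec$contrast_scale, noise_sd = spec$noise_sd,
        slice_mm = spec$spacing[3], lumen_radius_mm = spec$lumen_radius_mm,
        mode = spec$mode)
    }
  }
  if (!is.null(out_dir)) {
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    attr(phantoms, "manifest") <- manifest
  }
  phantoms
}
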