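# Minimal single-frame CT DICOM series support: explicit-VR little-endian
# only, axial acquisitions only.  The reader refuses to guess: missing
# geometry, mixed series or unsupported transfer syntaxes are hard errors.
# This is intentionally a narrow, validating subset of the standard, not a
# general DICOM toolkit.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"

# --- encoding helpers -------------------------------------------------------

#' @keywords internal
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' @keywords internal
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' @keywords internal
.pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# One explicit-VR element.  Short-form VRs carry a 16-bit length; OW/OB/etc.
# use the reserved+32-bit form.
#' @keywords internal
dcm_element <- function(group, elem, vr, value_raw) {
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  value_raw <- .pad_even(value_raw,
                         pad = if (vr %in% c("UI", "OB")) as.raw(0L)
                               else as.raw(0x20L))
  c(.u16(group), .u16(elem), charToRaw(vr),
    if (long_vr) c(as.raw(c(0, 0)), .u32(length(value_raw)))
    else .u16(length(value_raw)),
    value_raw)
}

#' @keywords internal
dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

#' @keywords internal
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", .u16(x))

# --- writer -----------------------------------------------------------------

#' Write a CT volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per axial slice, with rescale slope 1
#' and intercept -1024 (stored integers are HU + 1024).  Intended for
#' phantoms and round-trip testing; values are rounded to integer HU.
#'
#' @param volume a [ct_volume()].
#' @param directory output directory (created if needed).
#' @param series_uid series instance UID; a fresh pseudo-UID by default.
#' @param shuffle_names write files under permuted names (used to test that
#'   reading is independent of on-disk ordering).
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(volume, directory,
                               series_uid = NULL, shuffle_names = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.3680043.9999.",
                         paste(sample.int(9999, 3), collapse = "."))
  study_uid <- paste0(series_uid, ".0")
  intercept <- -1024; slope <- 1
  name_idx <- if (shuffle_names) sample.int(d[1]) else seq_len(d[1])
  for (z in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", z)
    stored <- round((volume$voxels[z, , ] - intercept) / slope)
    dim(stored) <- d[2:3]
    # row-major pixel order: rows of the axial slice written consecutively
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    zpos <- (z - 1) * volume$spacing[3]
    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x000D, "UI", study_uid),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(z)),
      dcm_str(0x0020, 0x0032, "DS",
              sprintf("0\\0\\%.6f", zpos)),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us (0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us (0x0028, 0x0010, d[2]),
      dcm_us (0x0028, 0x0011, d[3]),
      dcm_str(0x0028, 0x0030, "DS",
              sprintf("%.6f\\%.6f", volume$spacing[1], volume$spacing[2])),
      dcm_str(0x0018, 0x0050, "DS", sprintf("%.6f", volume$spacing[3])),
      dcm_us (0x0028, 0x0100, 16L),
      dcm_us (0x0028, 0x0101, 16L),
      dcm_us (0x0028, 0x0102, 15L),
      dcm_us (0x0028, 0x0103, 1L),
      dcm_str(0x0028, 0x1052, "DS", sprintf("%d", intercept)),
      dcm_str(0x0028, 0x1053, "DS", sprintf("%d", slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    meta <- c(
      dcm_str(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
    meta <- c(dcm_element(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
    file <- file.path(directory, sprintf("slice_%04d.dcm", name_idx[z]))
    con <- file(file, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(directory)
}

# --- reader -----------------------------------------------------------------

#' @keywords internal
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path))
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  transfer_syntax <- NULL
  rd_u16 <- function(p) readBin(r[p:(p + 1L)], "integer", size = 2,
                                endian = "little", signed = FALSE)
  rd_u32 <- function(p) readBin(r[p:(p + 3L)], "integer", size = 4,
                                endian = "little")
  while (pos + 7L <= length(r)) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("'%s': implicit-VR or unsupported encoding at offset %d; only explicit-VR little-endian is supported",
                   path, pos))
    if (vr %in% long_vrs) {
      len <- rd_u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- rd_u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > length(r))
      stop(sprintf("'%s': corrupt element length at offset %d", path, pos))
    key <- sprintf("%04X,%04X", group, elem)
    value <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, value = value)
    if (key == "0002,0010")
      transfer_syntax <- trimws(rawToChar(value), whitespace = "[ \\x00]")
    pos <- vstart + len
  }
  if (is.null(transfer_syntax) || transfer_syntax != UID_EXPLICIT_LE)
    stop(sprintf("'%s': transfer syntax '%s' not supported (explicit-VR little-endian only)",
                 path, transfer_syntax %||% "missing"))
  tags
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
tag_string <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$value), whitespace = "[ \\x00]")
}

#' @keywords internal
tag_numbers <- function(tags, key) {
  s <- tag_string(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' @keywords internal
tag_u16 <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$value, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a DICOM series into a CT volume
#'
#' Reads every single-frame axial CT image in `directory`, checks that all
#' files belong to one series, sorts slices by physical position along the
#' patient axis, applies the rescale slope/intercept so voxels are in
#' Hounsfield units, and populates the spacing from the series metadata.
#' Missing pixel spacing, missing slice geometry, or mixed series
#' identifiers are hard errors; no silent defaults are applied.
#'
#' @param directory directory containing `.dcm` files (one axial slice each).
#' @return a [ct_volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE, pattern = "\\.dcm$",
                      ignore.case = TRUE)
  if (length(files) == 0)
    files <- setdiff(list.files(directory, full.names = TRUE),
                     list.dirs(directory, full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no DICOM files found in '%s'", directory))
  parsed <- lapply(files, read_dicom_file)

  series <- vapply(parsed, function(t) tag_string(t, "0020,000E") %||% "",
                   character(1))
  useries <- unique(series)
  if (length(useries) > 1L)
    stop(sprintf("mixed series identifiers in '%s': %s", directory,
                 paste(sprintf("'%s'", useries), collapse = " vs ")))

  slices <- lapply(parsed, function(tags) {
    rows <- tag_u16(tags, "0028,0010"); cols <- tag_u16(tags, "0028,0011")
    if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns tag")
    ps <- tag_numbers(tags, "0028,0030")
    if (is.null(ps) || length(ps) != 2 || any(!is.finite(ps)) || any(ps <= 0))
      stop("missing or invalid PixelSpacing (0028,0030); refusing to assume 1 mm")
    ipp <- tag_numbers(tags, "0020,0032")
    if (is.null(ipp) || length(ipp) != 3)
      stop("missing ImagePositionPatient (0020,0032); cannot order slices")
    iop <- tag_numbers(tags, "0020,0037")
    if (!is.null(iop) &&
        (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-3))
      stop("non-axial orientation is not supported")
    slope <- tag_numbers(tags, "0028,1053") %||% 1
    intercept <- tag_numbers(tags, "0028,1052") %||% 0
    bits <- tag_u16(tags, "0028,0100") %||% 16L
    signed <- (tag_u16(tags, "0028,0103") %||% 0L) == 1L
    pix <- tags[["7FE0,0010"]]
    if (is.null(pix)) stop("missing PixelData")
    if (bits != 16L) stop(sprintf("unsupported BitsAllocated %d", bits))
    stored <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = signed)
    if (!signed) stored <- ifelse(stored < 0, stored + 65536, stored)
    hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
                 byrow = TRUE)
    list(z = ipp[3], hu = hu, ps = ps)
  })

  zs <- vapply(slices, `[[`, numeric(1), "z")
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  shapes <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("slice shape is not constant across the series")
  ps <- slices[[1]]$ps
  if (length(slices) > 1L) {
    dz <- diff(zs)
    if (any(dz <= 0)) stop("duplicate or non-increasing slice positions")
    if (max(dz) - min(dz) > 0.01 * stats::median(dz))
      warning("non-uniform slice spacing; using the median")
    slice_mm <- stats::median(dz)
  } else {
    st <- tag_numbers(parsed[[1]], "0018,0050")
    if (is.null(st)) stop("single slice with no SliceThickness; spacing unknown")
    slice_mm <- st
  }
  vox <- array(0, dim = c(length(slices), nrow(slices[[1]]$hu),
                          ncol(slices[[1]]$hu)))
  for (z in seq_along(slices)) vox[z, , ] <- slices[[z]]$hu
  ct_volume(vox, spacing = c(ps[1], ps[2], slice_mm))
}
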