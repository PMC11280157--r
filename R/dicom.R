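# Minimal DICOM reader for uncompressed single-frame CT slices
# (implicit or explicit VR little endian). Only the attributes the pipeline
# needs are extracted; anything else is skipped structurally.

.dcm_tags <- list(
  rows            = c(0x0028, 0x0010),
  cols            = c(0x0028, 0x0011),
  pixel_spacing   = c(0x0028, 0x0030),
  slice_thickness = c(0x0018, 0x0050),
  position        = c(0x0020, 0x0032),
  instance        = c(0x0020, 0x0013),
  intercept       = c(0x0028, 0x1052),
  slope           = c(0x0028, 0x1053),
  bits_alloc      = c(0x0028, 0x0100),
  pixel_rep       = c(0x0028, 0x0103),
  patient_id      = c(0x0010, 0x0020),
  acq_date        = c(0x0008, 0x0022),
  pixel_data      = c(0x7FE0, 0x0010)
)

.u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
.u32 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256 * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
}

# parse one DICOM file into the named fields of .dcm_tags
.parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  if (n < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("'", path, "' is not a DICOM part-10 file (missing DICM marker)")
  off <- 132L
  explicit_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                    "LT","OB","OD","OF","OW","PN","SH","SL","SQ","SS","ST",
                    "TM","UI","UL","UN","US","UT")
  long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  out <- list()
  want <- .dcm_tags
  while (off + 8L <= n) {
    group <- .u16(raw, off); elem <- .u16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    explicit <- vr %in% explicit_vrs
    if (explicit) {
      if (vr %in% long_vrs) {
        len <- .u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, off + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, off + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length element at offset ", off,
                                " in '", path, "' (unsupported encoding)")
    body <- off + hdr
    if (body + len > n) stop("truncated DICOM element in '", path, "'")
    for (nm in names(want)) {
      tg <- want[[nm]]
      if (group == tg[1] && elem == tg[2]) {
        out[[nm]] <- if (nm == "pixel_data") raw[(body + 1L):(body + len)]
                     else rawToChar(raw[(body + 1L):(body + len)])
        if (nm %in% c("rows", "cols", "bits_alloc", "pixel_rep") &&
            !is.na(vr) && vr == "US")
          out[[nm]] <- as.character(.u16(raw, body))
        if (nm %in% c("rows", "cols", "bits_alloc", "pixel_rep") && is.na(vr))
          out[[nm]] <- as.character(.u16(raw, body))
        break
      }
    }
    off <- body + len
  }
  out
}

.dcm_num <- function(x) as.numeric(strsplit(trimws(x), "\\\\")[[1]])

# position of subsequence `pat` inside raw vector `x`, NA if absent
.find_raw <- function(x, pat) {
  starts <- which(x == pat[1])
  for (s in starts) {
    if (s + length(pat) - 1L <= length(x) &&
        identical(x[s:(s + length(pat) - 1L)], pat)) return(s)
  }
  NA_integer_
}

#' Read a DICOM series as a CT volume
#'
#' Parses every DICOM file in `path` (uncompressed little endian), rescales
#' stored values to HU via RescaleSlope/RescaleIntercept, clamps to
#' \[-1024, 3071\] and stacks the slices sorted by ascending
#' ImagePositionPatient z (ties broken by InstanceNumber).
#'
#' @param path directory containing the slice files.
#' @param subject_id optional override; defaults to the series PatientID.
#' @param acquisition_date optional override; defaults to AcquisitionDate.
#' @return a [ct_volume].
#' @export
read_dicom_series <- function(path, subject_id = NULL,
                              acquisition_date = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", path)
  parsed <- lapply(files, .parse_dicom)

  need <- c("rows", "cols", "pixel_spacing", "slice_thickness", "pixel_data")
  for (p in seq_along(parsed)) {
    missing <- setdiff(need, names(parsed[[p]]))
    if (length(missing))
      stop("DICOM file '", files[p], "' lacks required attribute(s): ",
           paste(missing, collapse = ", "))
  }
  rows <- as.integer(parsed[[1]]$rows); cols <- as.integer(parsed[[1]]$cols)
  spacing <- .dcm_num(parsed[[1]]$pixel_spacing)
  thick <- .dcm_num(parsed[[1]]$slice_thickness)[1]
  for (p in parsed) {
    if (as.integer(p$rows) != rows || as.integer(p$cols) != cols ||
        any(abs(.dcm_num(p$pixel_spacing) - spacing) > 1e-6))
      stop("mixed geometry within DICOM series: slices disagree on ",
           "Rows/Columns/PixelSpacing")
  }

  zpos <- vapply(parsed, function(p)
    if (!is.null(p$position)) .dcm_num(p$position)[3] else NA_real_, 0)
  inst <- vapply(parsed, function(p)
    if (!is.null(p$instance)) .dcm_num(p$instance)[1] else NA_real_, 0)
  ord <- order(zpos, inst, na.last = TRUE)

  vox <- array(0, c(length(parsed), rows, cols))
  for (k in seq_along(ord)) {
    p <- parsed[[ord[k]]]
    bits <- if (!is.null(p$bits_alloc)) as.integer(p$bits_alloc) else 16L
    if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
    signed <- !is.null(p$pixel_rep) && as.integer(p$pixel_rep) == 1L
    vals <- readBin(p$pixel_data, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    if (!signed) vals[vals < 0] <- vals[vals < 0] + 65536
    slope <- if (!is.null(p$slope)) .dcm_num(p$slope)[1] else 1
    icept <- if (!is.null(p$intercept)) .dcm_num(p$intercept)[1] else 0
    # DICOM PixelData is row-major (column index fastest)
    vox[k, , ] <- matrix(slope * vals + icept, rows, cols, byrow = TRUE)
  }

  sid <- subject_id
  if (is.null(sid)) sid <- trimws(parsed[[1]]$patient_id)
  if (is.null(sid) || !nzchar(sid)) sid <- basename(path)
  ad <- acquisition_date
  if (is.null(ad) && !is.null(parsed[[1]]$acq_date))
    ad <- as.Date(trimws(parsed[[1]]$acq_date), format = "%Y%m%d")
  ct_volume(vox, pixel_spacing_mm = spacing, slice_thickness_mm = thick,
            subject_id = sid, acquisition_date = ad)
}

# write one uncompressed explicit-VR-little-endian CT slice; used to build
# self-contained test fixtures
.write_dicom_slice <- function(path, pixels, pixel_spacing_mm,
                               slice_thickness_mm, slope = 1,
                               intercept = -1024, z_mm = 0, instance = 1L,
                               patient_id = "anon", omit = character(0)) {
  stopifnot(is.matrix(pixels))
  el <- function(group, elem, vr, body) {
    if (is.character(body)) body <- charToRaw(body)
    if (length(body) %% 2L == 1L)
      body <- c(body, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    hdr <- c(writeBin(c(group, elem), raw(), size = 2L, endian = "little"),
             charToRaw(vr))
    if (vr %in% c("OB", "OW"))
      c(hdr, as.raw(c(0, 0)),
        writeBin(length(body), raw(), size = 4L, endian = "little"), body)
    else
      c(hdr, writeBin(length(body), raw(), size = 2L, endian = "little"), body)
  }
  us <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  px <- writeBin(as.integer(round(t(pixels))), raw(), size = 2L,
                 endian = "little")
  meta <- c(
    el(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(el(0x0002L, 0x0000L, "UL",
               writeBin(length(meta), raw(), size = 4L, endian = "little")),
            meta)
  body <- c(
    el(0x0008L, 0x0022L, "DA", format(Sys.Date(), "%Y%m%d")),
    el(0x0010L, 0x0020L, "LO", patient_id),
    el(0x0018L, 0x0050L, "DS", format(slice_thickness_mm)),
    el(0x0020L, 0x0013L, "IS", format(as.integer(instance))),
    el(0x0020L, 0x0032L, "DS", sprintf("0\\0\\%g", z_mm)),
    el(0x0028L, 0x0010L, "US", us(nrow(pixels))),
    el(0x0028L, 0x0011L, "US", us(ncol(pixels))),
    el(0x0028L, 0x0030L, "DS",
       sprintf("%g\\%g", pixel_spacing_mm[1], pixel_spacing_mm[2])),
    el(0x0028L, 0x0100L, "US", us(16L)),
    el(0x0028L, 0x0103L, "US", us(0L)),
    el(0x0028L, 0x1052L, "DS", format(intercept)),
    el(0x0028L, 0x1053L, "DS", format(slope)),
    el(0x7FE0L, 0x0010L, "OW", px))
  if ("pixel_spacing" %in% omit) {
    # drop the (0028,0030) element wholesale (test hook for metadata errors)
    body <- local({
      keep <- el(0x0028L, 0x0030L, "DS",
                 sprintf("%g\\%g", pixel_spacing_mm[1], pixel_spacing_mm[2]))
      idx <- .find_raw(body, keep)
      if (is.na(idx)) body else body[-(idx:(idx + length(keep) - 1L))]
    })
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
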