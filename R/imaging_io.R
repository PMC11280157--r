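#' CT volume container
#'
#' Bundles a 3-D grid of Hounsfield units with its acquisition geometry.
#' Axis order is fixed as (slice, row, col). Values are clamped to the
#' clinical CT support \[-1024, 3071\] HU on construction.
#'
#' @param voxels numeric 3-D array of HU values, dim = (slice, row, col).
#' @param pixel_spacing_mm length-2 positive numeric, in-plane (row, col)
#'   spacing in millimetres.
#' @param slice_thickness_mm positive scalar, slice thickness in millimetres.
#' @param subject_id character scalar identifying the subject.
#' @param acquisition_date optional `Date` (or string coercible to one) used
#'   for pairing with pulmonary function tests.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                      subject_id = "unknown", acquisition_date = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (slice, row, col)")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("`pixel_spacing_mm` must be two strictly positive numbers")
  slice_thickness_mm <- as.numeric(slice_thickness_mm)
  if (length(slice_thickness_mm) != 1L || !is.finite(slice_thickness_mm) ||
      slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be a strictly positive scalar")
  if (!is.null(acquisition_date)) acquisition_date <- as.Date(acquisition_date)
  structure(list(
    voxels = clamp_hu(voxels),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    subject_id = as.character(subject_id),
    acquisition_date = acquisition_date
  ), class = "ct_volume")
}

#' Clamp values to the CT Hounsfield support
#'
#' @param x numeric vector or array.
#' @return `x` with every value clamped to \[-1024, 3071\]. Idempotent.
#' @export
clamp_hu <- function(x) {
  x[x < .HU_MIN] <- .HU_MIN
  x[x > .HU_MAX] <- .HU_MAX
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> subject %s: %d slice(s) of %dx%d\n",
              x$subject_id, d[1], d[2], d[3]))
  cat(sprintf("  spacing %.3f x %.3f mm, thickness %.2f mm, HU in [%d, %d]\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

#' Segmentation mask container
#'
#' A binary or multi-class label volume on the voxel grid of its source CT.
#' Multi-class labels are 0 = background, 1 = pectoralis, 2 = erector
#' spinae, 3 = intercostal.
#'
#' @param voxels integer 3-D array, dim = (slice, row, col).
#' @param mode `"binary"` or `"multiclass"`.
#' @param pixel_spacing_mm,slice_thickness_mm optional geometry carried over
#'   from the source CT (used when writing NIfTI).
#' @return an object of class `muscle_mask`.
#' @export
muscle_mask <- function(voxels, mode = c("binary", "multiclass"),
                        pixel_spacing_mm = c(1, 1), slice_thickness_mm = 1) {
  mode <- match.arg(mode)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (slice, row, col)")
  v <- as.integer(round(voxels))
  dim(v) <- dim(voxels)
  if (mode == "binary") {
    v[v != 0L] <- 1L
  } else {
    bad <- setdiff(unique(as.vector(v)), 0:3)
    if (length(bad))
      stop("multiclass mask contains labels outside {0,1,2,3}: ",
           paste(sort(bad), collapse = ", "))
  }
  structure(list(voxels = v, mode = mode,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<muscle_mask> %s, %d slice(s) of %dx%d, %d foreground voxel(s)\n",
              x$mode, d[1], d[2], d[3], sum(x$voxels != 0L)))
  invisible(x)
}

.stop_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

# ---------------------------------------------------------------------------
# NIfTI: stored as (row, col, slice) with pixdim = (row_mm, col_mm, thick_mm)

.nifti_to_src <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L) stop("expected a 3-D NIfTI volume")
  aperm(a, c(3L, 1L, 2L))
}

.src_to_nifti <- function(voxels, pixel_spacing_mm, slice_thickness_mm) {
  img <- RNifti::asNifti(aperm(voxels, c(2L, 3L, 1L)))
  RNifti::pixdim(img) <- c(pixel_spacing_mm[1], pixel_spacing_mm[2],
                           slice_thickness_mm)
  img
}

.read_nifti_ct <- function(path, subject_id, acquisition_date) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header of '", path, "' lacks positive pixdim spacing")
  ct_volume(.nifti_to_src(img), pixel_spacing_mm = pd[1:2],
            slice_thickness_mm = pd[3], subject_id = subject_id,
            acquisition_date = acquisition_date)
}

#' Read a CT volume
#'
#' Reads a thoracic CT from a NIfTI file or a directory holding a DICOM
#' series. Stored values are rescaled to Hounsfield units using the
#' format's slope/intercept metadata, clamped to \[-1024, 3071\], and
#' slices are ordered by ascending anatomical (z) position.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom_series"`.
#' @param subject_id subject identifier; for DICOM, defaults to PatientID
#'   when present.
#' @param acquisition_date optional acquisition date override.
#' @return a [ct_volume].
#' @export
read_ct <- function(path, format = c("auto", "nifti", "dicom_series"),
                    subject_id = NULL, acquisition_date = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("no such file: ", path)
    sid <- if (is.null(subject_id))
      sub("\\.nii(\\.gz)?$", "", basename(path)) else subject_id
    .read_nifti_ct(path, sid, acquisition_date)
  } else {
    read_dicom_series(path, subject_id = subject_id,
                      acquisition_date = acquisition_date)
  }
}

#' Read a segmentation mask
#'
#' Reads a binary or multi-class muscle mask from NIfTI or a multi-page
#' TIFF stack. In binary mode any nonzero stored value maps to 1 (so the
#' common 0/255 TIFF dialect is accepted); in multiclass mode stored values
#' must already be in {0,1,2,3}.
#'
#' @param path `.nii`/`.nii.gz` or `.tif`/`.tiff` file.
#' @param mode `"binary"` or `"multiclass"`.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff_stack"`.
#' @return a [muscle_mask].
#' @export
read_mask <- function(path, mode = c("binary", "multiclass"),
                      format = c("auto", "nifti", "tiff_stack")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    v <- .nifti_to_src(img)
    sp <- if (length(pd) >= 3L && all(pd[1:3] > 0)) pd else c(1, 1, 1)
    muscle_mask(v, mode, pixel_spacing_mm = sp[1:2], slice_thickness_mm = sp[3])
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    v <- array(0L, c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) v[i, , ] <- as.integer(pages[[i]])
    muscle_mask(v, mode)
  }
}

#' Write a segmentation mask
#'
#' Writes a [muscle_mask] so that [read_mask] round-trips it
#' voxel-identically. NIfTI carries the voxel spacing in its header; TIFF
#' stacks use 8-bit pages (binary masks become the 0/255 dialect).
#'
#' @param mask a [muscle_mask].
#' @param path output file; extension selects the format under `"auto"`.
#' @param format `"auto"`, `"nifti"` or `"tiff_stack"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "tiff_stack")) {
  stopifnot(inherits(mask, "muscle_mask"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  if (format == "nifti") {
    img <- .src_to_nifti(mask$voxels, mask$pixel_spacing_mm,
                         mask$slice_thickness_mm)
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    vals <- mask$voxels
    if (mask$mode == "binary") vals <- vals * 255L
    pages <- lapply(seq_len(dim(vals)[1]),
                    function(s) matrix(vals[s, , ] / 255, dim(vals)[2],
                                       dim(vals)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a CT volume as NIfTI
#'
#' @param ct a [ct_volume].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- .src_to_nifti(ct$voxels, ct$pixel_spacing_mm, ct$slice_thickness_mm)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
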