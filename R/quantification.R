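#' Muscle volume from a mask
#'
#' Voxel-count volume: `n_voxels * row_spacing * col_spacing *
#' slice_thickness / 1000`, in cubic centimetres.
#'
#' @param mask a binary [muscle_mask], or a logical/0-1 array of voxels of
#'   one class.
#' @param pixel_spacing_mm in-plane (row, col) spacing; defaults to the
#'   mask's own geometry when a [muscle_mask] is given.
#' @param slice_thickness_mm slice thickness in mm.
#' @return volume in cc (>= 0).
#' @export
muscle_volume_cc <- function(mask, pixel_spacing_mm = NULL,
                             slice_thickness_mm = NULL) {
  if (inherits(mask, "muscle_mask")) {
    if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- mask$pixel_spacing_mm
    if (is.null(slice_thickness_mm))
      slice_thickness_mm <- mask$slice_thickness_mm
    mask <- mask$voxels
  }
  if (is.null(pixel_spacing_mm) || is.null(slice_thickness_mm))
    stop("voxel geometry (pixel spacing, slice thickness) is required")
  n <- sum(mask != 0)
  n * pixel_spacing_mm[1] * pixel_spacing_mm[2] * slice_thickness_mm / 1000
}

#' Muscle density from a mask and its source CT
#'
#' Arithmetic mean of the CT's clamped HU values over the masked voxels,
#' with no windowing and no HU-range exclusion. An empty mask has no
#' defined mean: `NA` is returned with a warning.
#'
#' @param mask a binary [muscle_mask] or logical/0-1 array selecting the
#'   voxels of one class.
#' @param ct the source [ct_volume].
#' @return mean HU, or `NA_real_` for an empty class.
#' @export
muscle_density_hu <- function(mask, ct) {
  stopifnot(inherits(ct, "ct_volume"))
  vox <- if (inherits(mask, "muscle_mask")) mask$voxels else mask
  .stop_geometry(vox, ct$voxels)
  sel <- vox != 0
  if (!any(sel)) {
    warning("empty mask: density undefined, returning NA")
    return(NA_real_)
  }
  mean(ct$voxels[sel])
}

#' Per-subject muscle metrics
#'
#' Volume (cc) and density (mean HU) for each muscle class of a
#' multi-class mask, plus whole-muscle totals: the whole-muscle volume is
#' the exact sum of the class volumes and the whole-muscle density the
#' voxel-count-weighted mean of the class densities.
#'
#' @param mask a multiclass [muscle_mask].
#' @param ct the source [ct_volume].
#' @param subject_id,sex,age_years subject metadata carried into the
#'   result (default from the CT).
#' @return a `muscle_metrics` list with one `volume_cc`/`density_hu` pair
#'   per class and for `whole_muscle`.
#' @export
muscle_metrics <- function(mask, ct, subject_id = ct$subject_id, sex = NA,
                           age_years = NA) {
  stopifnot(inherits(mask, "muscle_mask"), inherits(ct, "ct_volume"))
  if (mask$mode != "multiclass") stop("muscle_metrics needs a multiclass mask")
  .stop_geometry(mask$voxels, ct$voxels)
  sp <- ct$pixel_spacing_mm
  th <- ct$slice_thickness_mm
  out <- list(subject_id = subject_id, sex = sex, age_years = age_years)
  counts <- numeric(3)
  dens <- numeric(3)
  for (k in 1:3) {
    sel <- mask$voxels == k
    counts[k] <- sum(sel)
    out[[paste0(.MUSCLE_CLASSES[k], "_volume_cc")]] <-
      muscle_volume_cc(sel, sp, th)
    dens[k] <- if (counts[k] > 0) mean(ct$voxels[sel]) else NA_real_
    if (counts[k] == 0)
      warning("class '", .MUSCLE_CLASSES[k], "' empty for subject ",
              subject_id, "; density reported as NA")
    out[[paste0(.MUSCLE_CLASSES[k], "_density_hu")]] <- dens[k]
  }
  out$whole_muscle_volume_cc <-
    sum(vapply(.MUSCLE_CLASSES,
               function(cl) out[[paste0(cl, "_volume_cc")]], 0))
  out$whole_muscle_density_hu <- if (sum(counts) > 0)
    sum(dens * counts, na.rm = TRUE) / sum(counts) else NA_real_
  structure(out, class = "muscle_metrics")
}

#' @export
print.muscle_metrics <- function(x, ...) {
  cat(sprintf("<muscle_metrics> subject %s\n", x$subject_id))
  for (cl in c(.MUSCLE_CLASSES, "whole_muscle"))
    cat(sprintf("  %-15s %8.2f cc  %7.2f HU\n", cl,
                x[[paste0(cl, "_volume_cc")]], x[[paste0(cl, "_density_hu")]]))
  invisible(x)
}

#' Metrics list to data frame
#'
#' @param metrics list of `muscle_metrics`.
#' @return a data frame with one row per subject (the CSV schema of the
#'   quantification output).
#' @export
metrics_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m)
    as.data.frame(unclass(m), stringsAsFactors = FALSE)))
}

#' Cohort summary by sex or age decade
#'
#' Group means and sample standard deviations (SD = 0 for n = 1) of every
#' volume and density field. Age decades are \[40,50), \[50,60), \[60,70),
#' \[70,80\]; subjects outside 40--80 fall into open-ended `<40` / `>80`
#' bins and are flagged.
#'
#' @param metrics list of `muscle_metrics` or a [metrics_table] data
#'   frame.
#' @param group_by `"sex"` or `"age_decade"`.
#' @return a data frame: one row per group with `n` and `mean`/`sd`
#'   columns per field. Subjects missing the grouping key are excluded
#'   with a message.
#' @export
cohort_summary <- function(metrics, group_by = c("sex", "age_decade")) {
  group_by <- match.arg(group_by)
  df <- if (is.data.frame(metrics)) metrics else metrics_table(metrics)
  if (!nrow(df)) stop("empty metrics list")
  key <- if (group_by == "sex") as.character(df$sex) else {
    age <- df$age_years
    cut_lab <- rep(NA_character_, length(age))
    ok <- !is.na(age)
    cut_lab[ok & age < 40] <- "<40"
    cut_lab[ok & age >= 40 & age < 50] <- "40-49"
    cut_lab[ok & age >= 50 & age < 60] <- "50-59"
    cut_lab[ok & age >= 60 & age < 70] <- "60-69"
    cut_lab[ok & age >= 70 & age <= 80] <- "70-80"
    cut_lab[ok & age > 80] <- ">80"
    if (any(cut_lab %in% c("<40", ">80"), na.rm = TRUE))
      message("subjects outside the 40-80 age range placed in open-ended bins")
    cut_lab
  }
  drop <- is.na(key)
  if (any(drop))
    message(sum(drop), " subject(s) missing the grouping key were excluded")
  df <- df[!drop, , drop = FALSE]
  key <- key[!drop]
  fields <- grep("_(volume_cc|density_hu)$", names(df), value = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(ix) {
    row <- data.frame(group = key[ix[1]], n = length(ix))
    for (f in fields) {
      v <- df[[f]][ix]
      row[[paste0(f, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(f, "_sd")]] <- if (length(ix) > 1L) sd(v, na.rm = TRUE) else 0
    }
    row
  }))
  rownames(out) <- NULL
  out
}
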