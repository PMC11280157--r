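#' Convert network scores to a mask
#'
#' Binary heads: score >= 0.5 is foreground (ties go to foreground).
#' Softmax heads: per-pixel argmax over the class maps, ties to the lowest
#' class index.
#'
#' @param scores array of per-pixel scores as produced by
#'   [aunet_forward]: dim (H, W, 1, N) for binary, (H, W, K, N) for
#'   multiclass (a 3-D (H, W, K) single image is accepted).
#' @param mode `"binary"` or `"multiclass"`.
#' @return a [muscle_mask] with voxels of dim (N, H, W).
#' @export
threshold_scores <- function(scores, mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  d <- dim(scores)
  if (length(d) == 3L) {
    dim(scores) <- c(d, 1L)
    d <- dim(scores)
  }
  if (length(d) != 4L) stop("scores must have dim (H, W, K, N)")
  if (mode == "binary") {
    lab <- (scores[, , 1L, , drop = FALSE] >= 0.5) * 1L
    vox <- aperm(array(lab, d[c(1, 2, 4)]), c(3, 1, 2))
    muscle_mask(vox, "binary")
  } else {
    K <- d[3]
    lab <- array(1L, d[c(1, 2, 4)])
    best <- scores[, , 1L, , drop = FALSE]
    for (k in 2:K) {
      cur <- scores[, , k, , drop = FALSE]
      upd <- cur > best          # strict: ties keep the lower class index
      lab[upd] <- k
      best[upd] <- cur[upd]
    }
    vox <- aperm(lab - 1L, c(3, 1, 2))
    muscle_mask(vox, "multiclass")
  }
}

#' Remove small connected components
#'
#' Slice-wise connected-component noise filtering of a binary mask: every
#' foreground component with fewer than `min_size_px` pixels is set to
#' background; components at or above the threshold are untouched.
#' Idempotent, and never increases the foreground.
#'
#' @param mask a binary [muscle_mask] (or 0/1 3-D array).
#' @param min_size_px minimum surviving component size in pixels
#'   (default 10 at 512x512).
#' @param connectivity 4 or 8 (neighbourhood used within each slice).
#' @return the filtered mask, same type as the input.
#' @export
remove_small_components <- function(mask, min_size_px = 10L,
                                    connectivity = 8L) {
  if (min_size_px < 0L) stop("min_size_px must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  was_mask <- inherits(mask, "muscle_mask")
  vox <- if (was_mask) mask$voxels else mask
  if (min_size_px > 0L) {
    for (s in seq_len(dim(vox)[1])) {
      sl <- matrix(as.integer(vox[s, , ] != 0), dim(vox)[2], dim(vox)[3])
      lab <- .cpp_label_components(sl, as.integer(connectivity))
      if (max(lab) > 0L) {
        sizes <- tabulate(lab)
        kill <- which(sizes < min_size_px)
        if (length(kill)) {
          sl[lab %in% kill] <- 0L
          vox[s, , ] <- sl
        }
      }
    }
  }
  if (was_mask) {
    mask$voxels <- vox
    mask
  } else vox
}

#' Merge per-class masks under the anatomical priority rule
#'
#' Combines three binary masks (pectoralis, erector spinae, intercostal)
#' into one multi-class mask. Overlaps involving the intercostal muscles
#' yield to the pectoralis or erector spinae; the full priority is the
#' total order pectoralis > erector spinae > intercostal, so a pixel
#' claimed by several classes always receives the highest-priority one.
#' Unclaimed pixels are background.
#'
#' @param pectoralis,erector_spinae,intercostal binary [muscle_mask]
#'   objects (or 0/1 arrays) on a common grid.
#' @return a multiclass [muscle_mask].
#' @export
resolve_class_priority <- function(pectoralis, erector_spinae, intercostal) {
  v <- lapply(list(pectoralis, erector_spinae, intercostal), function(m)
    if (inherits(m, "muscle_mask")) m$voxels else m)
  .stop_geometry(v[[1]], v[[2]])
  .stop_geometry(v[[1]], v[[3]])
  out <- array(0L, dim(v[[1]]))
  out[v[[3]] != 0L] <- 3L
  out[v[[2]] != 0L] <- 2L
  out[v[[1]] != 0L] <- 1L
  sp <- if (inherits(pectoralis, "muscle_mask"))
    list(pectoralis$pixel_spacing_mm, pectoralis$slice_thickness_mm)
  else list(c(1, 1), 1)
  muscle_mask(out, "multiclass", sp[[1]], sp[[2]])
}
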