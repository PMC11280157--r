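#' Linear Hounsfield-unit window
#'
#' Maps HU values to \[0, 1\]: everything at or below `lo_hu` becomes 0,
#' everything at or above `hi_hu` becomes 1, with a linear ramp in between.
#' This is the radiological window/level operation used to build the
#' network input channels.
#'
#' @param x a [ct_volume], or a numeric array/vector of HU values.
#' @param lo_hu,hi_hu window bounds in HU, `lo_hu < hi_hu`.
#' @return numeric array of the same shape with values in \[0, 1\].
#' @examples
#' hu_window(c(-250, -50, 150), -250, 150)  # 0, 0.5, 1
#' @export
hu_window <- function(x, lo_hu, hi_hu) {
  if (!is.numeric(lo_hu) || !is.numeric(hi_hu) || lo_hu >= hi_hu)
    stop("window requires lo_hu < hi_hu")
  v <- if (inherits(x, "ct_volume")) x$voxels else x
  out <- (v - lo_hu) / (hi_hu - lo_hu)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# default window set; overridable via a YAML config (see read_window_config)
.default_windows <- function() list(
  full    = c(-1024, 3071),  # whole clinical HU range
  muscle  = c(-250, 150),    # muscle + fat band
  sub_fat = c(-1024, -250)   # below the muscle/fat band (lung/air side)
)

#' Read a window configuration from YAML
#'
#' The file may override any of the channels `full`, `muscle`, `sub_fat`,
#' each a mapping with keys `lo_hu` and `hi_hu`.
#'
#' @param path YAML file path.
#' @return named list of length-2 numeric windows.
#' @export
read_window_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  win <- .default_windows()
  for (nm in intersect(names(cfg), names(win))) {
    w <- cfg[[nm]]
    if (is.null(w$lo_hu) || is.null(w$hi_hu) || w$lo_hu >= w$hi_hu)
      stop("window '", nm, "' needs lo_hu < hi_hu")
    win[[nm]] <- c(w$lo_hu, w$hi_hu)
  }
  win
}

.new_windowed_stack <- function(channels, window_set_id) {
  structure(list(channels = channels, window_set_id = window_set_id),
            class = "windowed_stack")
}

#' @export
print.windowed_stack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<windowed_stack> %s: %d slice(s) of %dx%d, 3 channels\n",
              x$window_set_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Three-channel input for the segmentation stages
#'
#' Builds the windowed stack fed to the muscle-tissue and
#' respiratory-muscle segmentation networks: channel 1 is the full
#' clinical range (-1024, 3071) HU, channel 2 the muscle/fat band
#' (-250, 150) HU, channel 3 the band below muscle and fat
#' (-1024, -250) HU.
#'
#' @param ct a [ct_volume].
#' @param windows optional window list as from [read_window_config].
#' @return a `windowed_stack` with channels of dim (slice, row, col, 3).
#' @export
segmentation_input <- function(ct, windows = .default_windows()) {
  stopifnot(inherits(ct, "ct_volume"))
  d <- dim(ct$voxels)
  ch <- array(0, c(d, 3L))
  ch[, , , 1L] <- hu_window(ct$voxels, windows$full[1], windows$full[2])
  ch[, , , 2L] <- hu_window(ct$voxels, windows$muscle[1], windows$muscle[2])
  ch[, , , 3L] <- hu_window(ct$voxels, windows$sub_fat[1], windows$sub_fat[2])
  .new_windowed_stack(ch, "segmentation_input")
}

#' Three-channel input for the classification stage
#'
#' Channel 1 is the (binary) respiratory-muscle mask, channel 2 the
#' muscle/fat window (-250, 150) HU, channel 3 the full-range window.
#'
#' @param ct a [ct_volume].
#' @param respiratory_mask a binary [muscle_mask] on the same grid
#'   (predicted by the segmentation stage, or ground truth during training).
#' @param windows optional window list as from [read_window_config].
#' @return a `windowed_stack` with channels of dim (slice, row, col, 3).
#' @export
classification_input <- function(ct, respiratory_mask,
                                 windows = .default_windows()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(respiratory_mask, "muscle_mask"))
  .stop_geometry(ct$voxels, respiratory_mask$voxels)
  d <- dim(ct$voxels)
  ch <- array(0, c(d, 3L))
  ch[, , , 1L] <- as.numeric(respiratory_mask$voxels != 0L)
  ch[, , , 2L] <- hu_window(ct$voxels, windows$muscle[1], windows$muscle[2])
  ch[, , , 3L] <- hu_window(ct$voxels, windows$full[1], windows$full[2])
  .new_windowed_stack(ch, "classification_input")
}

#' Joint geometric augmentation of an input stack and its label
#'
#' With probability `p_flip` applies a horizontal flip and with probability
#' `p_rotate` an in-plane rotation drawn uniformly from
#' \[-max_angle, max_angle\] degrees. The identical transform is applied to
#' every channel of the stack (bilinear interpolation) and to the label
#' volume (nearest neighbour), so the image/label correspondence is
#' preserved. Deterministic for a fixed `seed`.
#'
#' @param stack a `windowed_stack` (channels dim (slice, row, col, 3)).
#' @param label an integer label array of dim (slice, row, col) or a
#'   [muscle_mask].
#' @param p_flip,p_rotate transform probabilities.
#' @param max_angle rotation half-range in degrees.
#' @param seed optional integer seed for reproducible draws.
#' @return list with elements `stack` and `label`, transformed jointly.
#' @export
augment <- function(stack, label, p_flip = 0.5, p_rotate = 0.5,
                    max_angle = 10, seed = NULL) {
  stopifnot(inherits(stack, "windowed_stack"))
  lab <- if (inherits(label, "muscle_mask")) label$voxels else label
  d <- dim(stack$channels)
  if (!identical(dim(lab), d[1:3]))
    stop("stack and label geometry differ")
  if (!is.null(seed)) {
    old <- .save_rng_state(); on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  do_flip <- runif(1) < p_flip
  angle <- if (runif(1) < p_rotate) runif(1, -max_angle, max_angle) else 0
  ch <- stack$channels
  if (do_flip) {
    ch <- ch[, , rev(seq_len(d[3])), , drop = FALSE]
    lab <- lab[, , rev(seq_len(d[3])), drop = FALSE]
  }
  if (angle != 0) {
    for (s in seq_len(d[1])) {
      for (k in seq_len(d[4]))
        ch[s, , , k] <- .cpp_rotate2d(matrix(ch[s, , , k], d[2], d[3]),
                                      angle, TRUE, 0)
      lab[s, , ] <- .cpp_rotate2d(matrix(as.numeric(lab[s, , ]), d[2], d[3]),
                                  angle, FALSE, 0)
    }
    ch[ch < 0] <- 0
    ch[ch > 1] <- 1
  }
  storage.mode(lab) <- "integer"
  list(stack = .new_windowed_stack(ch, stack$window_set_id), label = lab)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
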