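#' Dice similarity coefficient
#'
#' `2 * sum(pred * truth) / (sum(pred) + sum(truth))`, optionally smoothed.
#' `pred` may be a soft probability map (training) or a hard binary mask
#' (evaluation); `truth` is binary. With `smooth = 0` and two empty masks
#' the coefficient is defined as 1 (perfect agreement on emptiness).
#'
#' @param pred,truth numeric arrays of identical shape (binary
#'   [muscle_mask] objects are accepted).
#' @param smooth small positive stabilizer added to numerator and
#'   denominator; 1 during training, 0 for exact evaluation.
#' @return the coefficient, in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth, smooth = 0) {
  p <- if (inherits(pred, "muscle_mask")) pred$voxels else pred
  t <- if (inherits(truth, "muscle_mask")) truth$voxels else truth
  if (!identical(dim(p), dim(t)))
    stop("shape mismatch between pred and truth")
  num <- 2 * sum(p * t) + smooth
  den <- sum(p) + sum(t) + smooth
  if (den == 0) return(1)
  num / den
}

#' Dice loss
#'
#' `1 - dice_coefficient(pred, truth, smooth)`; the training objective of
#' the binary segmentation stages.
#'
#' @inheritParams dice_coefficient
#' @return the loss, in \[0, 1\].
#' @export
dice_loss <- function(pred, truth, smooth = 1) {
  1 - dice_coefficient(pred, truth, smooth)
}

#' Generalized Dice score
#'
#' Multi-class Dice aggregating all classes with per-class weights:
#' `2 * sum_c w_c sum_i p_ci r_ci / sum_c w_c sum_i (p_ci + r_ci)`.
#' The default `"auto"` weighting is the squared-inverse class volume
#' `w_c = 1 / (sum_i r_ci + eps)^2`, which balances classes of very
#' different sizes. The corresponding training loss is
#' `1 - generalized_dice(...)`.
#'
#' @param pred per-class soft maps, array of dim (..., n_classes) or
#'   (H, W, n_classes, N).
#' @param truth one-hot maps of the same shape.
#' @param weights `"auto"` or a positive numeric vector of length
#'   n_classes.
#' @param eps stabilizer inside the auto weights.
#' @param smooth stabilizer added to numerator and denominator (0 for
#'   exact evaluation).
#' @return the score, in \[0, 1\].
#' @export
generalized_dice <- function(pred, truth, weights = "auto", eps = 1e-6,
                             smooth = 0) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between pred and truth")
  d <- dim(pred)
  nd <- length(d)
  cdim <- if (nd == 4L) 3L else nd      # class axis
  K <- d[cdim]
  perm <- c(setdiff(seq_len(nd), cdim), cdim)
  pm <- matrix(aperm(pred, perm), ncol = K)
  tm <- matrix(aperm(truth, perm), ncol = K)
  inter <- colSums(pm * tm)
  psum <- colSums(pm)
  tsum <- colSums(tm)
  w <- if (identical(weights, "auto")) 1 / (tsum + eps)^2 else {
    if (length(weights) != K || any(weights <= 0))
      stop("weights must be ", K, " positive numbers")
    weights
  }
  num <- 2 * sum(w * inter) + smooth
  den <- sum(w * (psum + tsum)) + smooth
  if (den == 0) return(1)
  num / den
}

#' @rdname generalized_dice
#' @export
generalized_dice_loss <- function(pred, truth, weights = "auto", eps = 1e-6,
                                  smooth = 1) {
  1 - generalized_dice(pred, truth, weights, eps, smooth)
}

# one-hot encode an integer label array over K classes (labels 0..K-1),
# returning dim c(dim(lab), K)
.one_hot <- function(lab, K) {
  oh <- array(0, c(length(lab), K))
  oh[cbind(seq_along(lab), as.integer(lab) + 1L)] <- 1
  dim(oh) <- c(dim(lab), K)
  oh
}

#' Per-class classification metrics
#'
#' Confusion-matrix metrics of a predicted multi-class mask against the
#' ground truth: per muscle class precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R), plus the Dice coefficient of the class's
#' binary masks (identical to F1 on hard masks) and overall voxel
#' accuracy. A class absent from both masks is vacuously perfect: its
#' metrics are reported as 1 with a warning.
#'
#' @param pred,truth multiclass [muscle_mask] objects or integer label
#'   arrays with values in {0,1,2,3}.
#' @return a `class_metrics` list: `per_class` (data frame with class,
#'   precision, recall, f1, dice) and `accuracy`.
#' @export
classification_metrics <- function(pred, truth) {
  p <- if (inherits(pred, "muscle_mask")) pred$voxels else pred
  t <- if (inherits(truth, "muscle_mask")) truth$voxels else truth
  if (!identical(dim(p), dim(t)))
    stop("shape mismatch between pred and truth")
  res <- data.frame(class = .MUSCLE_CLASSES, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, dice = NA_real_)
  for (k in seq_along(.MUSCLE_CLASSES)) {
    cp <- p == k
    ct <- t == k
    tp <- sum(cp & ct)
    fp <- sum(cp & !ct)
    fn <- sum(!cp & ct)
    if (tp + fp + fn == 0) {
      warning("class '", .MUSCLE_CLASSES[k],
              "' absent from both masks; metrics reported as 1")
      res[k, 2:5] <- 1
    } else {
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      res[k, "precision"] <- prec
      res[k, "recall"] <- rec
      res[k, "f1"] <- f1
      res[k, "dice"] <- 2 * tp / (2 * tp + fp + fn)
    }
  }
  structure(list(per_class = res, accuracy = mean(p == t)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Write metrics to CSV and JSON
#'
#' @param metrics_list named list of `class_metrics` (one per subject).
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return the combined data frame, invisibly.
#' @export
write_metrics <- function(metrics_list, csv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(names(metrics_list), function(id) {
    df <- metrics_list[[id]]$per_class
    df$subject_id <- id
    df$accuracy <- metrics_list[[id]]$accuracy
    df[, c("subject_id", "class", "precision", "recall", "f1", "dice",
           "accuracy")]
  }))
  if (!is.null(csv_path)) write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- list(
      n_subjects = length(metrics_list),
      mean_accuracy = mean(rows$accuracy[!duplicated(rows$subject_id)]),
      per_class = lapply(split(rows, rows$class), function(g)
        list(precision = mean(g$precision), recall = mean(g$recall),
             f1 = mean(g$f1), dice = mean(g$dice))))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(rows)
}

# gradient of the smoothed dice loss wrt the probability map (binary head)
.dice_loss_grad <- function(probs, truth, smooth = 1) {
  num <- 2 * sum(probs * truth) + smooth
  den <- sum(probs) + sum(truth) + smooth
  loss <- 1 - num / den
  dprobs <- (num - 2 * truth * den) / den^2
  list(loss = loss, dprobs = dprobs)
}

# gradient of the generalized dice loss wrt per-class probabilities;
# truth must be one-hot; weights are the squared-inverse class volumes
.gdl_grad <- function(probs, truth, eps = 1e-6, smooth = 1) {
  d <- dim(probs)
  K <- d[3]
  pm <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = K)
  tm <- matrix(aperm(truth, c(1, 2, 4, 3)), ncol = K)
  inter <- colSums(pm * tm)
  psum <- colSums(pm)
  tsum <- colSums(tm)
  w <- 1 / (tsum + eps)^2
  num <- 2 * sum(w * inter) + smooth
  den <- sum(w * (psum + tsum)) + smooth
  loss <- 1 - num / den
  # d(num)/dp_ci = 2 w_c t_ci ; d(den)/dp_ci = w_c
  wc <- .ch_bcast(w, d)
  dprobs <- -(2 * wc * truth * den - num * wc) / den^2
  list(loss = loss, dprobs = dprobs)
}
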