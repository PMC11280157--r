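#' Stage configuration
#'
#' Default hyperparameters of the three training stages: muscle-tissue
#' segmentation (100 epochs, batch 8, Dice loss), respiratory-muscle
#' segmentation (50 epochs, batch 4, Dice loss, first three encoder levels
#' frozen) and respiratory-muscle classification (50 epochs, batch 4,
#' generalized Dice loss, softmax head). All stages use Adam with initial
#' learning rate 1e-4, reduced by 70% after three epochs without
#' improvement of the training loss.
#'
#' @param stage `"tissue_seg"`, `"resp_seg"` or `"resp_cls"`.
#' @param ... overrides for any field (e.g. `epochs`, `batch_size`,
#'   `lr_init`, `freeze_levels`, `augment`, `rng_seed`).
#' @return a `stage_config` list.
#' @export
stage_config <- function(stage = c("tissue_seg", "resp_seg", "resp_cls"),
                         ...) {
  stage <- match.arg(stage)
  base <- list(stage = stage, epochs = 100L, batch_size = 8L, lr_init = 1e-4,
               plateau_patience = 3L, lr_factor = 0.3,
               split_ratio = c(0.8, 0.2), loss = "dice", freeze_levels = 0L,
               augment = TRUE, flip_prob = 0.5, rotate_prob = 0.5,
               max_angle = 10, rng_seed = 1L)
  if (stage == "resp_seg") {
    base$epochs <- 50L
    base$batch_size <- 4L
    base$freeze_levels <- 3L
  } else if (stage == "resp_cls") {
    base$epochs <- 50L
    base$batch_size <- 4L
    base$loss <- "generalized_dice"
  }
  cfg <- modifyList(base, list(...))
  if (cfg$epochs <= 0L) stop("epochs must be > 0")
  if (cfg$batch_size <= 0L) stop("batch_size must be > 0")
  if (abs(sum(cfg$split_ratio) - 1) > 1e-8)
    stop("split_ratio fractions must sum to 1")
  if (cfg$lr_factor <= 0 || cfg$lr_factor >= 1)
    stop("lr_factor must lie in (0, 1)")
  structure(cfg, class = "stage_config")
}

#' Subject-level train/test split
#'
#' Partitions subjects (never individual slices) into train and test sets,
#' deterministically under `seed`. The test size is the ratio rounded to
#' the nearest integer, with the remainder going to training.
#'
#' @param subjects character vector of subject identifiers (or a list with
#'   `subject_id` fields).
#' @param ratio length-2 train/test fractions summing to 1 (default 8:2).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_dataset <- function(subjects, ratio = c(0.8, 0.2), seed = 1L) {
  if (is.list(subjects))
    subjects <- vapply(subjects, function(s) s$subject_id, "")
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicate subject ids in split input")
  n <- length(subjects)
  if (n < 2L) stop("need at least 2 subjects to split")
  n_test <- round(n * ratio[2])
  if (n_test < 1L || n_test >= n)
    stop("split of ", n, " subjects at ", ratio[2],
         " leaves an empty partition")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  test <- sort(sample(subjects, n_test))
  list(train = setdiff(subjects, test), test = test)
}

#' Plateau learning-rate step
#'
#' Reduces the learning rate by 70% (i.e. multiplies it by 0.30) whenever
#' the loss has not improved on its running best for `patience`
#' consecutive epochs; each further full `patience` block without
#' improvement triggers another reduction. "Improvement" means a strict
#' decrease below the best seen, beyond a tolerance of 1e-8.
#'
#' @param current_lr current learning rate.
#' @param history numeric vector of per-epoch losses, oldest first,
#'   including the current epoch.
#' @param patience epochs without improvement before each reduction.
#' @param factor multiplier applied on reduction (0.30 = "reduced by 70%").
#' @param tol improvement tolerance.
#' @return the (possibly reduced) learning rate.
#' @export
lr_schedule_step <- function(current_lr, history, patience = 3L,
                             factor = 0.3, tol = 1e-8) {
  if (patience < 1L) stop("patience must be >= 1")
  n <- length(history)
  if (n == 0L) return(current_lr)
  best <- Inf
  last_improve <- 0L
  for (i in seq_len(n)) {
    if (history[i] < best - tol) {
      best <- history[i]
      last_improve <- i
    }
  }
  stalled <- n - last_improve
  if (stalled > 0L && stalled %% patience == 0L) current_lr * factor
  else current_lr
}

# ---------------------------------------------------------------------------
# Adam optimizer over the model's named parameter list

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(model$params)) {
    if (model$groups[[nm]] %in% model$frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    model$params[[nm]] <- model$params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(model = model, opt = opt)
}

# ---------------------------------------------------------------------------
# sample construction: one training sample per axial slice

#' Build per-slice training samples for a stage
#'
#' Converts subject-level volumes into per-slice (input, label) pairs. For
#' the segmentation stages the input is [segmentation_input] and the label
#' the binary muscle mask; for the classification stage the input is
#' [classification_input] (using the subject's binary respiratory mask)
#' and the label the multi-class mask.
#'
#' @param subjects list of subjects, each a list with `subject_id`, `ct`
#'   (a [ct_volume]) and `mask` (a multiclass or binary [muscle_mask]).
#' @param stage `"tissue_seg"`, `"resp_seg"` or `"resp_cls"`.
#' @return list of samples, each `list(x, y, subject_id)` with `x` of dim
#'   (H, W, 3) and `y` an integer (H, W) matrix.
#' @export
build_stage_samples <- function(subjects,
                                stage = c("tissue_seg", "resp_seg",
                                          "resp_cls")) {
  stage <- match.arg(stage)
  samples <- list()
  for (sub in subjects) {
    mk <- sub$mask
    binvox <- mk$voxels
    binvox[binvox != 0L] <- 1L
    if (stage == "resp_cls") {
      if (mk$mode != "multiclass")
        stop("classification stage needs multiclass masks")
      bin <- muscle_mask(binvox, "binary", mk$pixel_spacing_mm,
                         mk$slice_thickness_mm)
      stack <- classification_input(sub$ct, bin)
      lab <- mk$voxels
    } else {
      stack <- segmentation_input(sub$ct)
      lab <- binvox
    }
    ns <- dim(stack$channels)[1]
    for (s in seq_len(ns)) {
      samples[[length(samples) + 1L]] <- list(
        x = array(stack$channels[s, , , ], dim(stack$channels)[2:4]),
        y = matrix(lab[s, , ], dim(lab)[2], dim(lab)[3]),
        subject_id = sub$subject_id)
    }
  }
  samples
}

.assemble_batch <- function(samples, idx, cfg, n_classes, augmenting) {
  d <- dim(samples[[idx[1]]]$x)
  N <- length(idx)
  x4 <- array(0, c(d[1], d[2], d[3], N))
  K <- n_classes
  y4 <- array(0, c(d[1], d[2], K, N))
  for (j in seq_along(idx)) {
    sm <- samples[[idx[j]]]
    x <- sm$x
    y <- sm$y
    if (augmenting) {
      do_flip <- runif(1) < cfg$flip_prob
      ang <- if (runif(1) < cfg$rotate_prob)
        runif(1, -cfg$max_angle, cfg$max_angle) else 0
      if (do_flip) {
        x <- x[, rev(seq_len(d[2])), , drop = FALSE]
        y <- y[, rev(seq_len(d[2])), drop = FALSE]
      }
      if (ang != 0) {
        for (k in seq_len(d[3]))
          x[, , k] <- .cpp_rotate2d(x[, , k], ang, TRUE, 0)
        x[x < 0] <- 0
        x[x > 1] <- 1
        y <- .cpp_rotate2d(y + 0, ang, FALSE, 0)
      }
    }
    x4[, , , j] <- x
    if (K == 1L) y4[, , 1L, j] <- as.numeric(y != 0)
    else y4[, , , j] <- .one_hot(matrix(as.integer(y), d[1], d[2]), K)
  }
  list(x = x4, y = y4)
}

#' Train one pipeline stage
#'
#' Runs mini-batch Adam on per-slice samples with the stage's loss (Dice
#' for binary heads, generalized Dice for the softmax head), the plateau
#' learning-rate rule, optional joint augmentation, and optional held-out
#' evaluation after every epoch. When evaluation data are supplied the
#' returned model is the best-epoch checkpoint by held-out (generalized)
#' Dice; otherwise the final state.
#'
#' @param model an `aunet_model`; for the respiratory-segmentation stage,
#'   initialize it from a tissue checkpoint and set `freeze_levels` in the
#'   config.
#' @param samples training samples from [build_stage_samples].
#' @param config a [stage_config].
#' @param eval_samples optional held-out samples for per-epoch evaluation.
#' @return list with `model` and `log` (a `train_log` data frame with
#'   epoch, loss, lr and eval metric).
#' @export
train_stage <- function(model, samples, config, eval_samples = NULL) {
  stopifnot(inherits(model, "aunet_model"), inherits(config, "stage_config"))
  binary_head <- model$config$out_mode == "binary_sigmoid"
  if (config$loss == "generalized_dice" && binary_head)
    stop("generalized dice loss requires a multiclass softmax head")
  if (config$loss == "dice" && !binary_head)
    stop("dice loss requires a binary sigmoid head")
  if (!length(samples)) stop("no training samples")
  if (config$freeze_levels > 0L)
    model <- freeze_encoder(model, config$freeze_levels)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(config$rng_seed)

  K <- model$config$n_classes
  opt <- .adam_init(model$params)
  lr <- config$lr_init
  history <- numeric(0)
  log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0),
                    eval_metric = numeric(0))
  best_metric <- -Inf
  best_model <- model
  n <- length(samples)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      bt <- .assemble_batch(samples, b, config, K, config$augment)
      fw <- .aunet_fwd(model, bt$x, training = TRUE, keep = TRUE)
      model$buffers <- fw$buffers
      if (binary_head) {
        lg <- .dice_loss_grad(fw$probs, bt$y, smooth = 1)
        dlogits <- lg$dprobs * fw$probs * (1 - fw$probs)
      } else {
        lg <- .gdl_grad(fw$probs, bt$y, smooth = 1)
        inner <- .sum_channels(lg$dprobs * fw$probs)
        dlogits <- fw$probs *
          (lg$dprobs - inner[, , rep(1L, K), , drop = FALSE])
      }
      grads <- .aunet_bwd(model, fw$cache, dlogits)
      st <- .adam_step(model, grads, opt, lr)
      model <- st$model
      opt <- st$opt
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / n
    history <- c(history, ep_loss)
    ev <- NA_real_
    if (!is.null(eval_samples)) {
      ev <- evaluate_samples(model, eval_samples)
      if (ev > best_metric) {
        best_metric <- ev
        best_model <- model
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss, lr = lr,
                                 eval_metric = ev))
    lr <- lr_schedule_step(lr, history, config$plateau_patience,
                           config$lr_factor)
  }
  out_model <- if (!is.null(eval_samples)) best_model else model
  class(log) <- c("train_log", "data.frame")
  list(model = out_model, log = log)
}

#' Evaluate a model on per-slice samples
#'
#' Pooled hard-mask (generalized) Dice over all sample pixels, computed in
#' evaluation mode with no smoothing: binary heads give the Dice
#' coefficient of the thresholded prediction, softmax heads the
#' generalized Dice of the one-hot argmax.
#'
#' @param model an `aunet_model`.
#' @param samples samples from [build_stage_samples].
#' @param batch_size forward-pass batch size.
#' @return scalar metric in \[0, 1\].
#' @export
evaluate_samples <- function(model, samples, batch_size = 8L) {
  K <- model$config$n_classes
  binary_head <- model$config$out_mode == "binary_sigmoid"
  idxs <- split(seq_along(samples),
                ceiling(seq_along(samples) / batch_size))
  inter <- numeric(max(K, 1L)); psum <- numeric(max(K, 1L))
  tsum <- numeric(max(K, 1L))
  for (b in idxs) {
    d <- dim(samples[[b[1]]]$x)
    x4 <- array(0, c(d, length(b)))
    for (j in seq_along(b)) x4[, , , j] <- samples[[b[j]]]$x
    probs <- .aunet_fwd(model, x4, training = FALSE, keep = FALSE)$probs
    for (j in seq_along(b)) {
      y <- samples[[b[j]]]$y
      if (binary_head) {
        ph <- probs[, , 1L, j] >= 0.5
        th <- y != 0
        inter[1] <- inter[1] + sum(ph & th)
        psum[1] <- psum[1] + sum(ph)
        tsum[1] <- tsum[1] + sum(th)
      } else {
        lab <- apply(probs[, , , j], c(1, 2), which.max) - 1L
        for (k in seq_len(K)) {
          ph <- lab == (k - 1L)
          th <- y == (k - 1L)
          inter[k] <- inter[k] + sum(ph & th)
          psum[k] <- psum[k] + sum(ph)
          tsum[k] <- tsum[k] + sum(th)
        }
      }
    }
  }
  if (binary_head) {
    if (psum[1] + tsum[1] == 0) return(1)
    2 * inter[1] / (psum[1] + tsum[1])
  } else {
    w <- 1 / (tsum + 1e-6)^2
    2 * sum(w * inter) / sum(w * (psum + tsum))
  }
}

#' @export
print.train_log <- function(x, ...) {
  cat(sprintf("<train_log> %d epoch(s); final loss %.4f; best eval %.4f\n",
              nrow(x), x$loss[nrow(x)],
              suppressWarnings(max(x$eval_metric, na.rm = TRUE))))
  invisible(x)
}

#' Write a training log as CSV and JSON
#'
#' @param log a `train_log`.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @return the log, invisibly.
#' @export
write_train_log <- function(log, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(as.data.frame(log), csv_path,
                                    row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(log), json_path, dataframe = "rows",
                         na = "null", digits = NA)
  invisible(log)
}

# ---------------------------------------------------------------------------
# active learning

#' One active-learning round
#'
#' Predicts binary respiratory-muscle masks (with probability maps) for a
#' batch of unlabeled subjects, passes each through the `refine` callback
#' (standing in for expert mask refinement), appends the accepted masks to
#' the labeled pool, and retrains a fresh model from scratch on the
#' enlarged pool (re-initialized, not a continuation of the incoming
#' model's weights).
#'
#' @param model the current respiratory-segmentation `aunet_model`.
#' @param labeled_pool list of labeled subjects (`subject_id`, `ct`,
#'   `mask`).
#' @param unlabeled_batch list of unlabeled subjects (`subject_id`, `ct`).
#' @param refine function `(predicted_mask, probability_map, subject) ->
#'   muscle_mask` returning the accepted mask.
#' @param config a [stage_config] for the retraining run.
#' @param base_model optional model to restart from (e.g. the tissue
#'   checkpoint); defaults to a fresh initialization with a seed folded
#'   from `config$rng_seed` and the pool size.
#' @return list with `labeled_pool` (grown) and `model` (retrained), plus
#'   the retraining `log`.
#' @export
active_learning_round <- function(model, labeled_pool, unlabeled_batch,
                                  refine, config, base_model = NULL) {
  if (!length(unlabeled_batch))
    return(list(labeled_pool = labeled_pool, model = model, log = NULL))
  for (sub in unlabeled_batch) {
    pr <- predict(model, sub$ct, input_builder = "segmentation",
                  return_scores = TRUE)
    accepted <- refine(pr$mask, pr$scores, sub)
    labeled_pool[[length(labeled_pool) + 1L]] <-
      list(subject_id = sub$subject_id, ct = sub$ct, mask = accepted)
  }
  if (is.null(base_model)) {
    init_seed <- (config$rng_seed * 1000L + length(labeled_pool)) %% 2147483647L
    base_model <- build_aunet(model$config, seed = init_seed)
  }
  samples <- build_stage_samples(labeled_pool, "resp_seg")
  tr <- train_stage(base_model, samples, config)
  list(labeled_pool = labeled_pool, model = tr$model, log = tr$log)
}

#' Run the active-learning loop to exhaustion
#'
#' Repeats [active_learning_round] on successive batches of the unlabeled
#' pool (default batch: a quarter of what remains) until no unlabeled
#' subjects are left.
#'
#' @inheritParams active_learning_round
#' @param unlabeled_pool list of unlabeled subjects.
#' @param batch_size subjects per round; default a quarter of the
#'   remaining pool (at least 1).
#' @return list with the final `labeled_pool` and `model`.
#' @export
run_active_learning <- function(model, labeled_pool, unlabeled_pool, refine,
                                config, base_model = NULL,
                                batch_size = NULL) {
  round_i <- 0L
  while (length(unlabeled_pool)) {
    round_i <- round_i + 1L
    bs <- if (is.null(batch_size))
      max(1L, length(unlabeled_pool) %/% 4L) else batch_size
    bs <- min(bs, length(unlabeled_pool))
    batch <- unlabeled_pool[seq_len(bs)]
    unlabeled_pool <- unlabeled_pool[-seq_len(bs)]
    cfg_round <- config
    cfg_round$rng_seed <- (config$rng_seed + round_i) %% 2147483647L
    res <- active_learning_round(model, labeled_pool, batch, refine,
                                 cfg_round, base_model)
    labeled_pool <- res$labeled_pool
    model <- res$model
  }
  list(labeled_pool = labeled_pool, model = model)
}
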