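#' Attention U-Net configuration
#'
#' Describes a U-shaped encoder--decoder with additive attention gates on
#' the skip connections. `depth` counts resolution levels (encoder blocks);
#' the clinical-scale network uses six, test instances typically four or
#' fewer. Channel width doubles at each level starting from
#' `base_channels`.
#'
#' @param depth integer >= 2, number of encoder (and decoder) levels.
#' @param base_channels channel width of the first level (32 for full runs,
#'   8 is enough for phantom-scale instances).
#' @param in_channels number of input channels (3 for the windowed stacks).
#' @param out_mode `"binary_sigmoid"` (one output map) or
#'   `"multiclass_softmax"` (`n_classes` maps summing to 1 per pixel).
#' @param n_classes class count for the softmax head (4 = background + 3
#'   muscle groups).
#' @return a `network_config` list.
#' @export
network_config <- function(depth = 6L, base_channels = 32L, in_channels = 3L,
                           out_mode = c("binary_sigmoid", "multiclass_softmax"),
                           n_classes = 4L) {
  out_mode <- match.arg(out_mode)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = as.integer(in_channels), out_mode = out_mode,
                 n_classes = if (out_mode == "multiclass_softmax")
                   as.integer(n_classes) else 1L),
            class = "network_config")
}

.init_conv <- function(cin, cout, k) {
  sd <- sqrt(2 / (cin * k * k))
  list(W = matrix(rnorm(cout * cin * k * k, sd = sd), cout, cin * k * k),
       b = numeric(cout))
}

#' Build an Attention U-Net
#'
#' Instantiates the network parameters: `depth` encoder blocks (two 3x3
#' convolutions with batch normalization and ReLU each, max-pool
#' downsampling, width doubling per level), a symmetric decoder (bilinear
#' upsampling + 1x1 projection), one additive attention gate per skip
#' connection, and a 1x1 head. Initialization is He-normal and
#' deterministic under `seed`.
#'
#' @param config a [network_config].
#' @param seed integer seed for parameter initialization.
#' @return an object of class `aunet_model` holding `params` (trainable),
#'   `buffers` (batch-norm running statistics), `groups` (parameter-group
#'   map used for freezing) and `frozen` (character vector of frozen
#'   groups).
#' @export
build_aunet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  depth <- config$depth
  ch <- config$base_channels * 2^(seq_len(depth) - 1L)
  params <- list()
  buffers <- list()
  groups <- character()
  add_conv <- function(prefix, cin, cout, k, group) {
    cv <- .init_conv(cin, cout, k)
    params[[paste0(prefix, "_W")]] <<- cv$W
    params[[paste0(prefix, "_b")]] <<- cv$b
    groups[paste0(prefix, "_W")] <<- group
    groups[paste0(prefix, "_b")] <<- group
  }
  add_bn <- function(prefix, c, group) {
    params[[paste0(prefix, "_gamma")]] <<- rep(1, c)
    params[[paste0(prefix, "_beta")]] <<- rep(0, c)
    groups[paste0(prefix, "_gamma")] <<- group
    groups[paste0(prefix, "_beta")] <<- group
    buffers[[paste0(prefix, "_mean")]] <<- rep(0, c)
    buffers[[paste0(prefix, "_var")]] <<- rep(1, c)
  }
  add_block <- function(prefix, cin, cout, group) {
    add_conv(paste0(prefix, "_conv1"), cin, cout, 3L, group)
    add_bn(paste0(prefix, "_bn1"), cout, group)
    add_conv(paste0(prefix, "_conv2"), cout, cout, 3L, group)
    add_bn(paste0(prefix, "_bn2"), cout, group)
  }
  for (i in seq_len(depth))
    add_block(paste0("enc", i), if (i == 1L) config$in_channels else ch[i - 1L],
              ch[i], paste0("enc", i))
  for (i in rev(seq_len(depth - 1L))) {
    add_conv(paste0("dec", i, "_up"), ch[i + 1L], ch[i], 1L, paste0("dec", i))
    fint <- max(1L, ch[i] %/% 2L)
    add_conv(paste0("att", i, "_Wg"), ch[i], fint, 1L, paste0("att", i))
    add_conv(paste0("att", i, "_Wx"), ch[i], fint, 1L, paste0("att", i))
    add_conv(paste0("att", i, "_psi"), fint, 1L, 1L, paste0("att", i))
    add_block(paste0("dec", i), 2L * ch[i], ch[i], paste0("dec", i))
  }
  add_conv("head", ch[1L], config$n_classes, 1L, "head")
  # rename attention conv param keys to the names the graph uses
  names(params) <- sub("_Wg_W$", "_Wg", names(params))
  names(params) <- sub("_Wg_b$", "_bg", names(params))
  names(params) <- sub("_Wx_W$", "_Wx", names(params))
  names(params) <- sub("_Wx_b$", "_bx", names(params))
  names(groups) <- sub("_Wg_W$", "_Wg", names(groups))
  names(groups) <- sub("_Wg_b$", "_bg", names(groups))
  names(groups) <- sub("_Wx_W$", "_Wx", names(groups))
  names(groups) <- sub("_Wx_b$", "_bx", names(groups))
  structure(list(config = config, params = params, buffers = buffers,
                 groups = groups, frozen = character(0), init_seed = seed),
            class = "aunet_model")
}

#' @export
print.aunet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<aunet_model> depth %d, base %d channels, %s head, %s parameters\n",
              x$config$depth, x$config$base_channels, x$config$out_mode,
              format(np, big.mark = ",")))
  if (length(x$frozen))
    cat("  frozen groups:", paste(x$frozen, collapse = ", "), "\n")
  invisible(x)
}

#' Forward pass of an Attention U-Net
#'
#' @param model an `aunet_model`.
#' @param x input array of dim (H, W, in_channels) for one image or
#'   (H, W, in_channels, N) for a batch, or a `windowed_stack` (whose
#'   slices become the batch).
#' @param training logical; `TRUE` uses batch statistics for the
#'   normalization layers, `FALSE` (default) the running statistics.
#' @return array of per-pixel scores with the input's spatial shape:
#'   (H, W, 1, N) sigmoid probabilities for a binary head, (H, W,
#'   n_classes, N) softmax probabilities otherwise.
#' @export
aunet_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "aunet_model"))
  x4 <- .coerce_input(model, x)
  .aunet_fwd(model, x4, training = training, keep = FALSE)$probs
}

.coerce_input <- function(model, x) {
  if (inherits(x, "windowed_stack")) {
    ch <- x$channels  # (slice, row, col, 3) -> (row, col, 3, slice)
    x <- aperm(ch, c(2L, 3L, 4L, 1L))
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L)
    stop("input must have dim (H, W, C) or (H, W, C, N)")
  x
}

#' Freeze leading encoder levels
#'
#' Marks encoder levels `1..n_levels` as frozen so that optimization steps
#' leave their parameters bitwise unchanged. Used when fine-tuning the
#' muscle-tissue network on respiratory-muscle data to preserve the
#' pre-learned low-level features.
#'
#' @param model an `aunet_model`.
#' @param n_levels number of leading encoder levels to freeze
#'   (0 = nothing frozen).
#' @return the model with updated `frozen` groups.
#' @export
freeze_encoder <- function(model, n_levels) {
  stopifnot(inherits(model, "aunet_model"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 0L || n_levels > model$config$depth)
    stop("n_levels must be in [0, ", model$config$depth, "]")
  model$frozen <- if (n_levels == 0L) character(0)
                  else paste0("enc", seq_len(n_levels))
  model
}

#' Save / load model checkpoints
#'
#' The checkpoint is an RDS file holding parameters, normalization buffers
#' and freezing state, with a JSON sidecar (`<path>.json`) recording the
#' network configuration for inspection without deserializing.
#'
#' @param model an `aunet_model`.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aunet_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "aunet_model"))
    stop("'", path, "' is not an aunet_model checkpoint")
  model
}

#' Predict segmentation masks for a CT volume
#'
#' Runs the network slice-wise in evaluation mode and thresholds the score
#' maps ([threshold_scores]): binary heads give a binary mask (score >=
#' 0.5), softmax heads a per-pixel argmax label map.
#'
#' @param object an `aunet_model`.
#' @param ct a [ct_volume].
#' @param respiratory_mask binary [muscle_mask], required when the model
#'   was trained on classification inputs.
#' @param input_builder `"segmentation"` or `"classification"`; selects the
#'   windowed-stack builder.
#' @param return_scores also return the raw probability array.
#' @param ... unused.
#' @return a [muscle_mask] (binary or multiclass per the head), or a list
#'   `(mask, scores)` when `return_scores = TRUE`.
#' @export
predict.aunet_model <- function(object, ct, respiratory_mask = NULL,
                                input_builder = c("segmentation",
                                                  "classification"),
                                return_scores = FALSE, ...) {
  input_builder <- match.arg(input_builder)
  stack <- if (input_builder == "segmentation") segmentation_input(ct)
           else classification_input(ct, respiratory_mask)
  probs <- aunet_forward(object, stack, training = FALSE)
  mode <- if (object$config$out_mode == "binary_sigmoid") "binary"
          else "multiclass"
  # (H, W, K, N) -> per-slice maps on the CT grid (slice, row, col)
  mask <- threshold_scores(probs, mode = mode)
  mask$pixel_spacing_mm <- ct$pixel_spacing_mm
  mask$slice_thickness_mm <- ct$slice_thickness_mm
  if (return_scores) list(mask = mask, scores = probs) else mask
}
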