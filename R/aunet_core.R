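# Layer primitives and the Attention U-Net forward/backward graph.
#
# Feature maps are R arrays of dim (H, W, C, N); the compiled kernels see
# them as H x W x (N*C) cubes with the channels of each sample contiguous,
# which is exactly the column-major flattening of the last two dimensions.

.as_cube <- function(x4) {
  d <- dim(x4)
  dim(x4) <- c(d[1], d[2], d[3] * d[4])
  x4
}
.as_arr4 <- function(x3, C, N) {
  d <- dim(x3)
  dim(x3) <- c(d[1], d[2], C, N)
  x3
}

# per-channel reduction and broadcast over (H, W, C, N)
.ch_sum <- function(x4) {
  d <- dim(x4)
  cs <- colSums(matrix(x4, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}
.ch_bcast <- function(v, d) array(rep(v, each = d[1] * d[2]), dim = d)

.conv_fwd <- function(x4, W, b, k, keep_cols) {
  d <- dim(x4)
  r <- .cpp_conv2d_fwd(.as_cube(x4), W, b, k, d[4], keep_cols)
  list(out = .as_arr4(r$out, nrow(W), d[4]), cols = r$cols)
}
.conv_bwd <- function(gout4, cols, W, k) {
  d <- dim(gout4)
  r <- .cpp_conv2d_bwd(.as_cube(gout4), cols, W, k, d[4])
  list(gx = .as_arr4(r$gx, ncol(W) / (k * k), d[4]),
       gW = r$gW, gb = as.numeric(r$gb))
}

.pool_fwd <- function(x4) {
  d <- dim(x4)
  r <- .cpp_maxpool2_fwd(.as_cube(x4))
  list(out = .as_arr4(r$out, d[3], d[4]), idx = r$idx, H = d[1], W = d[2])
}
.pool_bwd <- function(gout4, cache) {
  d <- dim(gout4)
  .as_arr4(.cpp_maxpool2_bwd(.as_cube(gout4), cache$idx, cache$H, cache$W),
           d[3], d[4])
}

.up_fwd <- function(x4) {
  d <- dim(x4)
  list(out = .as_arr4(.cpp_upsample2_fwd(.as_cube(x4)), d[3], d[4]),
       H = d[1], W = d[2])
}
.up_bwd <- function(gout4, cache) {
  d <- dim(gout4)
  .as_arr4(.cpp_upsample2_bwd(.as_cube(gout4), cache$H, cache$W), d[3], d[4])
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.bn_fwd <- function(x4, gamma, beta, rmean, rvar, training) {
  d <- dim(x4)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- .ch_sum(x4) / m
    xc <- x4 - .ch_bcast(mu, d)
    v <- .ch_sum(xc * xc) / m
    rmean <- (1 - .BN_MOMENTUM) * rmean + .BN_MOMENTUM * mu
    rvar <- (1 - .BN_MOMENTUM) * rvar + .BN_MOMENTUM * v
  } else {
    mu <- rmean
    v <- rvar
    xc <- x4 - .ch_bcast(mu, d)
  }
  invstd <- 1 / sqrt(v + .BN_EPS)
  xhat <- xc * .ch_bcast(invstd, d)
  out <- xhat * .ch_bcast(gamma, d) + .ch_bcast(beta, d)
  list(out = out, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar)
}

.bn_bwd <- function(gout4, cache, gamma) {
  d <- dim(gout4)
  m <- d[1] * d[2] * d[4]
  gxhat <- gout4 * .ch_bcast(gamma, d)
  s1 <- .ch_sum(gxhat)
  s2 <- .ch_sum(gxhat * cache$xhat)
  gx <- .ch_bcast(cache$invstd / m, d) *
    (m * gxhat - .ch_bcast(s1, d) - cache$xhat * .ch_bcast(s2, d))
  list(gx = gx, ggamma = .ch_sum(gout4 * cache$xhat), gbeta = .ch_sum(gout4))
}

# conv(3x3) -> BN -> ReLU, twice
.block_fwd <- function(x4, params, buffers, prefix, training, keep) {
  cache <- list()
  c1 <- .conv_fwd(x4, params[[paste0(prefix, "_conv1_W")]],
                  params[[paste0(prefix, "_conv1_b")]], 3L, keep)
  b1 <- .bn_fwd(c1$out, params[[paste0(prefix, "_bn1_gamma")]],
                params[[paste0(prefix, "_bn1_beta")]],
                buffers[[paste0(prefix, "_bn1_mean")]],
                buffers[[paste0(prefix, "_bn1_var")]], training)
  m1 <- b1$out > 0
  h <- b1$out * m1
  c2 <- .conv_fwd(h, params[[paste0(prefix, "_conv2_W")]],
                  params[[paste0(prefix, "_conv2_b")]], 3L, keep)
  b2 <- .bn_fwd(c2$out, params[[paste0(prefix, "_bn2_gamma")]],
                params[[paste0(prefix, "_bn2_beta")]],
                buffers[[paste0(prefix, "_bn2_mean")]],
                buffers[[paste0(prefix, "_bn2_var")]], training)
  m2 <- b2$out > 0
  out <- b2$out * m2
  if (training) {
    buffers[[paste0(prefix, "_bn1_mean")]] <- b1$rmean
    buffers[[paste0(prefix, "_bn1_var")]] <- b1$rvar
    buffers[[paste0(prefix, "_bn2_mean")]] <- b2$rmean
    buffers[[paste0(prefix, "_bn2_var")]] <- b2$rvar
  }
  if (keep)
    cache <- list(cols1 = c1$cols, bn1 = b1[c("xhat", "invstd")], mask1 = m1,
                  cols2 = c2$cols, bn2 = b2[c("xhat", "invstd")], mask2 = m2)
  list(out = out, cache = cache, buffers = buffers)
}

.block_bwd <- function(gout4, cache, params, prefix, grads) {
  g <- gout4 * cache$mask2
  bb2 <- .bn_bwd(g, cache$bn2, params[[paste0(prefix, "_bn2_gamma")]])
  grads[[paste0(prefix, "_bn2_gamma")]] <- bb2$ggamma
  grads[[paste0(prefix, "_bn2_beta")]] <- bb2$gbeta
  cb2 <- .conv_bwd(bb2$gx, cache$cols2, params[[paste0(prefix, "_conv2_W")]], 3L)
  grads[[paste0(prefix, "_conv2_W")]] <- cb2$gW
  grads[[paste0(prefix, "_conv2_b")]] <- cb2$gb
  g <- cb2$gx * cache$mask1
  bb1 <- .bn_bwd(g, cache$bn1, params[[paste0(prefix, "_bn1_gamma")]])
  grads[[paste0(prefix, "_bn1_gamma")]] <- bb1$ggamma
  grads[[paste0(prefix, "_bn1_beta")]] <- bb1$gbeta
  cb1 <- .conv_bwd(bb1$gx, cache$cols1, params[[paste0(prefix, "_conv1_W")]], 3L)
  grads[[paste0(prefix, "_conv1_W")]] <- cb1$gW
  grads[[paste0(prefix, "_conv1_b")]] <- cb1$gb
  list(gx = cb1$gx, grads = grads)
}

.sum_channels <- function(x4) {
  d <- dim(x4)
  acc <- x4[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (c in 2:d[3]) acc <- acc + x4[, , c, , drop = FALSE]
  acc
}

# additive attention gate: skip features x reweighted by a logistic map of
# a learned combination of x and the decoder gating signal g
.att_fwd <- function(g4, x4, params, prefix, keep) {
  a1 <- .conv_fwd(g4, params[[paste0(prefix, "_Wg")]],
                  params[[paste0(prefix, "_bg")]], 1L, keep)
  a2 <- .conv_fwd(x4, params[[paste0(prefix, "_Wx")]],
                  params[[paste0(prefix, "_bx")]], 1L, keep)
  s <- a1$out + a2$out
  mask <- s > 0
  srelu <- s * mask
  z <- .conv_fwd(srelu, params[[paste0(prefix, "_psi_W")]],
                 params[[paste0(prefix, "_psi_b")]], 1L, keep)
  alpha <- 1 / (1 + exp(-z$out))           # (H, W, 1, N)
  d <- dim(x4)
  out <- x4 * alpha[, , rep(1L, d[3]), , drop = FALSE]
  cache <- NULL
  if (keep)
    cache <- list(cols_g = a1$cols, cols_x = a2$cols, mask = mask,
                  cols_s = z$cols, alpha = alpha, x = x4)
  list(out = out, alpha = alpha, cache = cache)
}

.att_bwd <- function(gout4, cache, params, prefix, grads) {
  d <- dim(gout4)
  alpha_full <- cache$alpha[, , rep(1L, d[3]), , drop = FALSE]
  gx_direct <- gout4 * alpha_full
  galpha <- .sum_channels(gout4 * cache$x)            # (H, W, 1, N)
  gz <- galpha * cache$alpha * (1 - cache$alpha)
  pb <- .conv_bwd(gz, cache$cols_s, params[[paste0(prefix, "_psi_W")]], 1L)
  grads[[paste0(prefix, "_psi_W")]] <- pb$gW
  grads[[paste0(prefix, "_psi_b")]] <- pb$gb
  gs <- pb$gx * cache$mask
  gb1 <- .conv_bwd(gs, cache$cols_g, params[[paste0(prefix, "_Wg")]], 1L)
  grads[[paste0(prefix, "_Wg")]] <- gb1$gW
  grads[[paste0(prefix, "_bg")]] <- gb1$gb
  gb2 <- .conv_bwd(gs, cache$cols_x, params[[paste0(prefix, "_Wx")]], 1L)
  grads[[paste0(prefix, "_Wx")]] <- gb2$gW
  grads[[paste0(prefix, "_bx")]] <- gb2$gb
  list(gg = gb1$gx, gx = gx_direct + gb2$gx, grads = grads)
}

.softmax_ch <- function(z4) {
  d <- dim(z4)
  mx <- z4[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (c in 2:d[3]) mx <- pmax(mx, z4[, , c, , drop = FALSE])
  e <- exp(z4 - mx[, , rep(1L, d[3]), , drop = FALSE])
  s <- .sum_channels(e)
  e / s[, , rep(1L, d[3]), , drop = FALSE]
}

# full forward pass; x4 is (H, W, in_channels, N)
.aunet_fwd <- function(model, x4, training = FALSE, keep = FALSE) {
  cfg <- model$config
  d <- dim(x4)
  div <- 2^(cfg$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input spatial size ", d[1], "x", d[2], " is not divisible by 2^",
         cfg$depth - 1L, " = ", div, "; pad the input to a multiple of ", div)
  if (d[3] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " input channels, got ", d[3])
  p <- model$params
  buf <- model$buffers
  depth <- cfg$depth
  skips <- vector("list", depth)
  caches <- list(enc = vector("list", depth), pool = vector("list", depth),
                 dec = vector("list", depth), att = vector("list", depth),
                 up = vector("list", depth))
  h <- x4
  for (i in seq_len(depth)) {
    bl <- .block_fwd(h, p, buf, paste0("enc", i), training, keep)
    buf <- bl$buffers
    skips[[i]] <- bl$out
    caches$enc[[i]] <- bl$cache
    if (i < depth) {
      pl <- .pool_fwd(bl$out)
      caches$pool[[i]] <- pl[c("idx", "H", "W")]
      h <- pl$out
    }
  }
  f <- skips[[depth]]
  att_maps <- vector("list", depth)
  for (i in rev(seq_len(depth - 1L))) {
    upo <- .up_fwd(f)
    uc <- .conv_fwd(upo$out, p[[paste0("dec", i, "_up_W")]],
                    p[[paste0("dec", i, "_up_b")]], 1L, keep)
    at <- .att_fwd(uc$out, skips[[i]], p, paste0("att", i), keep)
    att_maps[[i]] <- at$alpha
    ci <- dim(uc$out)[3]
    dcat <- dim(uc$out)
    dcat[3] <- 2L * ci
    cat4 <- array(0, dcat)
    cat4[, , seq_len(ci), ] <- uc$out
    cat4[, , ci + seq_len(ci), ] <- at$out
    bl <- .block_fwd(cat4, p, buf, paste0("dec", i), training, keep)
    buf <- bl$buffers
    f <- bl$out
    if (keep)
      caches$up[[i]] <- list(up = upo[c("H", "W")], cols = uc$cols, ci = ci)
    caches$att[[i]] <- at$cache
    caches$dec[[i]] <- bl$cache
  }
  hc <- .conv_fwd(f, p$head_W, p$head_b, 1L, keep)
  logits <- hc$out
  probs <- if (cfg$out_mode == "binary_sigmoid") 1 / (1 + exp(-logits))
           else .softmax_ch(logits)
  list(probs = probs, logits = logits, buffers = buf,
       attention = att_maps,
       cache = if (keep) c(caches, list(head_cols = hc$cols, skips_dim = lapply(skips, dim))) else NULL)
}

# backward pass from d(loss)/d(logits); returns named gradient list
.aunet_bwd <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  depth <- cfg$depth
  grads <- list()
  hb <- .conv_bwd(dlogits, cache$head_cols, p$head_W, 1L)
  grads$head_W <- hb$gW
  grads$head_b <- hb$gb
  gf <- hb$gx
  gskip <- vector("list", depth)
  for (i in seq_len(depth - 1L)) {
    db <- .block_bwd(gf, cache$dec[[i]], p, paste0("dec", i), grads)
    grads <- db$grads
    ci <- cache$up[[i]]$ci
    gu1 <- db$gx[, , seq_len(ci), , drop = FALSE]
    ga <- db$gx[, , ci + seq_len(ci), , drop = FALSE]
    ab <- .att_bwd(ga, cache$att[[i]], p, paste0("att", i), grads)
    grads <- ab$grads
    gskip[[i]] <- ab$gx
    ub <- .conv_bwd(gu1 + ab$gg, cache$up[[i]]$cols,
                    p[[paste0("dec", i, "_up_W")]], 1L)
    grads[[paste0("dec", i, "_up_W")]] <- ub$gW
    grads[[paste0("dec", i, "_up_b")]] <- ub$gb
    gf <- .up_bwd(ub$gx, cache$up[[i]]$up)
  }
  # gf is now the gradient at the bottleneck (encoder block `depth` output)
  gh <- gf
  for (i in rev(seq_len(depth))) {
    eb <- .block_bwd(gh, cache$enc[[i]], p, paste0("enc", i), grads)
    grads <- eb$grads
    if (i > 1L)
      gh <- .pool_bwd(eb$gx, cache$pool[[i - 1L]]) + gskip[[i - 1L]]
  }
  grads
}
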