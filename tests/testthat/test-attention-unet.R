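small_cfg <- function(out_mode = "binary_sigmoid")
  network_config(depth = 3L, base_channels = 2L, out_mode = out_mode)

test_that("parameter initialization is deterministic under the seed", {
  m1 <- build_aunet(small_cfg(), seed = 7)
  m2 <- build_aunet(small_cfg(), seed = 7)
  m3 <- build_aunet(small_cfg(), seed = 8)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("forward output matches input shape and head semantics", {
  set.seed(41)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mb <- build_aunet(small_cfg(), seed = 1)
  pb <- aunet_forward(mb, x)
  expect_equal(dim(pb), c(16, 16, 1, 1))
  expect_true(all(pb > 0 & pb < 1))

  mc <- build_aunet(small_cfg("multiclass_softmax"), seed = 1)
  pc <- aunet_forward(mc, x)
  expect_equal(dim(pc), c(16, 16, 4, 1))
  sums <- apply(pc[, , , 1], c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # evaluation-mode forward is deterministic
  expect_identical(pb, aunet_forward(mb, x))
})

test_that("incompatible spatial size raises a padding error", {
  m <- build_aunet(small_cfg(), seed = 1)
  x <- array(runif(10 * 10 * 3), c(10, 10, 3))
  expect_error(aunet_forward(m, x), "divisible")
})

test_that("attention gate multiplicatively reweights the skip features", {
  ns <- asNamespace("respmuscle")
  m <- build_aunet(small_cfg(), seed = 2)
  set.seed(42)
  g <- array(runif(8 * 8 * 2 * 1), c(8, 8, 2, 1))
  x <- array(runif(8 * 8 * 2 * 1), c(8, 8, 2, 1))
  at <- ns$.att_fwd(g, x, m$params, "att1", keep = FALSE)
  expect_equal(at$out, x * at$alpha[, , c(1, 1), , drop = FALSE])
  # drive the gate closed: output goes to zero maps
  m$params$att1_psi_b <- -100
  at0 <- ns$.att_fwd(g, x, m$params, "att1", keep = FALSE)
  expect_true(max(abs(at0$out)) < 1e-20)
})

test_that("checkpoints round-trip exactly with a JSON sidecar", {
  m <- build_aunet(small_cfg(), seed = 3)
  m <- freeze_encoder(m, 2)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$params, m$params)
  expect_identical(back$frozen, m$frozen)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$depth, 3L)
  expect_equal(side$out_mode, "binary_sigmoid")
})

test_that("freeze_encoder validates its range and sets groups", {
  m <- build_aunet(small_cfg(), seed = 1)
  expect_identical(freeze_encoder(m, 0)$frozen, character(0))
  expect_identical(freeze_encoder(m, 2)$frozen, c("enc1", "enc2"))
  expect_error(freeze_encoder(m, 4), "\\[0, 3\\]")
})

test_that("backward pass matches finite-difference gradients", {
  ns <- asNamespace("respmuscle")
  for (mode in c("binary_sigmoid", "multiclass_softmax")) {
    cfg <- network_config(depth = 2, base_channels = 2, out_mode = mode)
    model <- build_aunet(cfg, seed = 5)
    set.seed(51)
    K <- model$config$n_classes
    x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    y <- if (mode == "binary_sigmoid")
      array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
    else {
      oh <- array(0, c(8, 8, K, 2))
      for (n in 1:2)
        oh[, , , n] <- ns$.one_hot(array(sample(0:3, 64, TRUE), c(8, 8)), K)
      oh
    }
    loss_of <- function(m) {
      fw <- ns$.aunet_fwd(m, x, training = TRUE, keep = FALSE)
      if (mode == "binary_sigmoid") ns$.dice_loss_grad(fw$probs, y)$loss
      else ns$.gdl_grad(fw$probs, y)$loss
    }
    fw <- ns$.aunet_fwd(model, x, training = TRUE, keep = TRUE)
    if (mode == "binary_sigmoid") {
      lg <- ns$.dice_loss_grad(fw$probs, y)
      dlogits <- lg$dprobs * fw$probs * (1 - fw$probs)
    } else {
      lg <- ns$.gdl_grad(fw$probs, y)
      inner <- ns$.sum_channels(lg$dprobs * fw$probs)
      dlogits <- fw$probs * (lg$dprobs - inner[, , rep(1L, K), , drop = FALSE])
    }
    grads <- ns$.aunet_bwd(model, fw$cache, dlogits)
    set.seed(52)
    checked <- 0L
    for (nm in sample(names(model$params), 12)) {
      i <- sample(length(model$params[[nm]]), 1)
      eps <- 1e-5
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      an <- grads[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = paste("analytic grad of", nm))
      checked <- checked + 1L
    }
    expect_equal(checked, 12L)
  }
})
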