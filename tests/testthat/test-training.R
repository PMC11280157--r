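test_that("subject-level split is deterministic, 8:2 and leak-free", {
  subs <- sprintf("S%02d", 1:10)
  sp <- split_dataset(subs, c(0.8, 0.2), seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), subs)
  expect_identical(sp, split_dataset(subs, c(0.8, 0.2), seed = 3))
  expect_false(identical(sp$test, split_dataset(subs, seed = 4)$test))
  expect_error(split_dataset("only-one"), "at least 2")
  expect_error(split_dataset(c("a", "b", "c"), c(0.99, 0.01), seed = 1),
               "empty partition")
  expect_error(split_dataset(c("a", "a", "b")), "duplicate")
})

test_that("plateau rule cuts the learning rate by 70% per stalled block", {
  # improving run: unchanged
  expect_equal(lr_schedule_step(1e-4, c(0.5, 0.4, 0.3)), 1e-4)
  # three-epoch plateau after the best: one reduction
  expect_equal(lr_schedule_step(1e-4, c(0.3, 0.31, 0.32, 0.33)), 3e-5)
  # mid-plateau epochs do not re-trigger
  expect_equal(lr_schedule_step(3e-5, c(0.3, 0.31, 0.32, 0.33, 0.34)), 3e-5)
  # a second full stalled block compounds to x0.09
  lr <- 1e-4
  hist <- c(0.3)
  for (loss in c(0.31, 0.32, 0.33, 0.34, 0.35, 0.36)) {
    hist <- c(hist, loss)
    lr <- lr_schedule_step(lr, hist)
  }
  expect_equal(lr, 1e-4 * 0.09)
  expect_error(lr_schedule_step(1e-4, 0.3, patience = 0), "patience")
})

test_that("stage configs carry the clinical-scale defaults and validate", {
  ts <- stage_config("tissue_seg")
  expect_equal(ts$epochs, 100L)
  expect_equal(ts$batch_size, 8L)
  expect_equal(ts$lr_init, 1e-4)
  expect_equal(ts$loss, "dice")
  rs <- stage_config("resp_seg")
  expect_equal(rs$epochs, 50L)
  expect_equal(rs$batch_size, 4L)
  expect_equal(rs$freeze_levels, 3L)
  rc <- stage_config("resp_cls")
  expect_equal(rc$loss, "generalized_dice")
  expect_error(stage_config("tissue_seg", epochs = 0L), "epochs")
  expect_error(stage_config("tissue_seg", split_ratio = c(0.5, 0.4)),
               "sum to 1")
})

test_that("loss/head mismatches are rejected", {
  subs <- tiny_subjects(2)
  samp <- build_stage_samples(subs, "tissue_seg")
  mc <- build_aunet(network_config(depth = 2, base_channels = 2,
                                   out_mode = "multiclass_softmax"), seed = 1)
  expect_error(train_stage(mc, samp, stage_config("tissue_seg", epochs = 1L)),
               "dice loss requires a binary")
  mb <- build_aunet(network_config(depth = 2, base_channels = 2), seed = 1)
  expect_error(train_stage(mb, samp, stage_config("resp_cls", epochs = 1L)),
               "generalized dice")
})

test_that("training reduces the loss and freezing pins encoder levels", {
  subs <- tiny_subjects(4)
  samp <- build_stage_samples(subs, "resp_seg")
  cfg <- stage_config("resp_seg", epochs = 4L, batch_size = 4L,
                      lr_init = 2e-3, freeze_levels = 2L, augment = FALSE,
                      rng_seed = 9L)
  model <- build_aunet(network_config(depth = 3, base_channels = 4), seed = 2)
  before <- model$params
  tr <- train_stage(model, samp, cfg)
  expect_lt(min(tr$log$loss), tr$log$loss[1])
  frozen <- names(model$groups)[model$groups %in% c("enc1", "enc2")]
  for (nm in frozen)
    expect_identical(tr$model$params[[nm]], before[[nm]])
  thawed <- names(model$groups)[model$groups == "enc3"]
  expect_false(identical(tr$model$params[thawed], before[thawed]))
  # learning-rate trace is non-increasing
  expect_true(all(diff(tr$log$lr) <= 0))
})

test_that("slices of a subject never straddle the split", {
  subs <- tiny_subjects(5)
  samp <- build_stage_samples(subs, "tissue_seg")
  sp <- split_dataset(subs, c(0.8, 0.2), seed = 1)
  ids <- vapply(samp, function(s) s$subject_id, "")
  in_test <- ids %in% sp$test
  expect_true(all(tapply(in_test, ids, function(v) all(v) || !any(v))))
})

test_that("active learning grows the pool and retrains from scratch", {
  subs <- tiny_subjects(6)
  labeled <- subs[1:4]
  unlabeled <- lapply(subs[5:6], function(s)
    list(subject_id = s$subject_id, ct = s$ct))
  cfg <- stage_config("resp_seg", epochs = 1L, batch_size = 4L,
                      freeze_levels = 0L, augment = FALSE, rng_seed = 3L)
  model <- build_aunet(network_config(depth = 2, base_channels = 2), seed = 4)
  truth_of <- function(id) {
    m <- Filter(function(s) s$subject_id == id, subs)[[1]]$mask
    v <- m$voxels; v[v != 0L] <- 1L
    muscle_mask(v, "binary", m$pixel_spacing_mm, m$slice_thickness_mm)
  }
  refine <- function(pred, probs, subject) truth_of(subject$subject_id)
  res <- active_learning_round(model, labeled, unlabeled, refine, cfg)
  expect_length(res$labeled_pool, 6)
  # refined masks are the oracle ground truth
  expect_identical(res$labeled_pool[[5]]$mask$voxels,
                   truth_of(subs[[5]]$subject_id)$voxels)
  # retrained weights are not a continuation of the incoming model
  expect_false(identical(res$model$params$enc1_conv1_W,
                         model$params$enc1_conv1_W))
  # empty batch is a no-op
  noop <- active_learning_round(model, labeled, list(), refine, cfg)
  expect_identical(noop$model, model)
  expect_length(noop$labeled_pool, 4)
})
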