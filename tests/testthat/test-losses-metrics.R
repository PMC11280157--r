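test_that("dice coefficient matches enumerated set overlaps", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 0, 0, 1, 1, 0, 0)  # |A| = |B| = 4, overlap 2
  dim(a) <- dim(b) <- c(2, 4)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_loss(a, b, smooth = 0), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  disj <- 1 - a
  expect_equal(dice_coefficient(a, disj), 0)
  expect_equal(dice_loss(a, a, smooth = 0), 0)
  expect_error(dice_coefficient(a, c(1, 0)), "shape")
})

test_that("dice is symmetric on hard masks and the loss is its complement", {
  set.seed(61)
  for (i in 1:20) {
    a <- array(rbinom(64, 1, 0.5), c(8, 8))
    b <- array(rbinom(64, 1, 0.5), c(8, 8))
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_equal(dice_loss(a, b, smooth = 0), 1 - dice_coefficient(a, b))
  }
})

test_that("generalized dice agrees with a brute-force per-pixel oracle", {
  # two-class toy: class A 4 px predicted exactly, class B 2 px missed
  truth <- array(0, c(4, 4, 2))
  truth[1:2, 1:2, 1] <- 1
  truth[3, 3:4, 2] <- 1
  pred <- array(0, c(4, 4, 2))
  pred[1:2, 1:2, 1] <- 1
  expect_equal(generalized_dice(pred, truth),
               oracle_generalized_dice(pred, truth), tolerance = 1e-12)
  expect_equal(generalized_dice(truth, truth), 1, tolerance = 1e-9)
  expect_equal(generalized_dice_loss(truth, truth, smooth = 0), 0,
               tolerance = 1e-9)

  set.seed(62)
  for (i in 1:25) {
    K <- sample(2:4, 1)
    lab <- array(sample(0:(K - 1), 64, TRUE), c(8, 8))
    p <- array(runif(64 * K), c(8, 8, K))
    oh <- array(0, c(8, 8, K))
    for (k in 1:K) oh[, , k] <- lab == (k - 1)
    expect_equal(generalized_dice(p, oh), oracle_generalized_dice(p, oh),
                 tolerance = 1e-12)
  }
})

test_that("one-class generalized dice with uniform weight reduces to dice", {
  set.seed(63)
  p <- array(runif(64), c(8, 8, 1))
  t <- array(rbinom(64, 1, 0.5), c(8, 8, 1))
  expect_equal(generalized_dice(p, t, weights = 1),
               dice_coefficient(p[, , 1], t[, , 1]), tolerance = 1e-12)
})

test_that("classification metrics match hand-computed confusion cases", {
  truth <- array(0L, c(1, 4, 4))
  truth[1, 1, 1:2] <- 1L
  pred <- truth
  pred[1, 2, 1:2] <- 1L  # 2 TP, 2 FP: precision 0.5, recall 1
  suppressWarnings(cm <- classification_metrics(pred, truth))
  row <- cm$per_class[cm$per_class$class == "pectoralis", ]
  expect_equal(row$precision, 0.5)
  expect_equal(row$recall, 1)
  expect_equal(row$f1, 2 / 3)
  expect_equal(row$f1, row$dice)  # 2TP/(2TP+FP+FN) identity

  suppressWarnings(perfect <- classification_metrics(truth, truth))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class[1, 2:5] == 1))
  # classes absent from both masks are vacuously perfect, with a warning each
  w <- capture_warnings(classification_metrics(truth, truth))
  expect_length(w, 2)  # erector spinae and intercostal are absent
  expect_true(all(grepl("absent", w)))
})

test_that("all metrics agree with the confusion-matrix oracle on random masks", {
  set.seed(64)
  for (i in 1:300) {
    pred <- array(sample(0:3, 64, TRUE, prob = c(0.5, 0.2, 0.2, 0.1)), c(1, 8, 8))
    truth <- array(sample(0:3, 64, TRUE, prob = c(0.5, 0.2, 0.2, 0.1)), c(1, 8, 8))
    cm <- suppressWarnings(classification_metrics(pred, truth))
    for (k in 1:3) {
      o <- oracle_binary_metrics(as.numeric(pred == k), as.numeric(truth == k))
      row <- cm$per_class[k, ]
      if (o$tp + o$fp + o$fn == 0) {
        expect_equal(unlist(row[2:5]), c(precision = 1, recall = 1, f1 = 1,
                                         dice = 1))
      } else {
        expect_equal(row$precision, o$precision, tolerance = 1e-10)
        expect_equal(row$recall, o$recall, tolerance = 1e-10)
        expect_equal(row$dice, o$dice, tolerance = 1e-10)
      }
    }
    expect_equal(cm$accuracy, mean(pred == truth), tolerance = 1e-12)
  }
})

test_that("metrics export writes per-subject CSV rows and a JSON summary", {
  truth <- array(sample(0:3, 32, TRUE), c(2, 4, 4))
  ml <- list(S1 = suppressWarnings(classification_metrics(truth, truth)))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  rows <- write_metrics(ml, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_equal(nrow(read.csv(csv)), 3)
  expect_equal(jsonlite::read_json(js)$n_subjects, 1L)
})
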