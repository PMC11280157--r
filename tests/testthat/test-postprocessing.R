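test_that("score thresholding follows the declared tie rules", {
  low <- array(0.4, c(4, 4, 1, 2))
  expect_true(all(threshold_scores(low, "binary")$voxels == 0L))
  tie <- array(0.5, c(4, 4, 1, 1))
  expect_true(all(threshold_scores(tie, "binary")$voxels == 1L))

  oh <- array(0, c(2, 2, 4, 1))
  lab <- matrix(c(0, 1, 2, 3), 2, 2)
  for (k in 1:4) oh[, , k, 1] <- lab == (k - 1)
  out <- threshold_scores(oh, "multiclass")
  expect_equal(matrix(out$voxels[1, , ], 2, 2), lab)

  even <- array(0.25, c(2, 2, 4, 1))  # all-tied argmax: lowest class wins
  expect_true(all(threshold_scores(even, "multiclass")$voxels == 0L))
})

test_that("small components are removed by size with the boundary kept", {
  sl <- matrix(0L, 32, 32)
  sl[1, 1:3] <- 1L               # size 3
  sl[5:9, 1:10] <- 1L            # size 50
  sl[15:26, 11:20] <- 1L         # size 120
  mask <- muscle_mask(array(sl, c(1, 32, 32)), "binary")
  out <- remove_small_components(mask, 10L)
  lab <- oracle_components(matrix(out$voxels[1, , ], 32, 32))
  expect_equal(max(lab), 2)
  expect_equal(sum(out$voxels), 170)
  # exact-threshold component is retained ("below a certain size")
  at <- muscle_mask(array(c(rep(1L, 10), rep(0L, 22)) , c(1, 4, 8)), "binary")
  expect_equal(sum(remove_small_components(at, 10L)$voxels), 10)
  # min size 0 is the identity
  expect_identical(remove_small_components(mask, 0L)$voxels, mask$voxels)
})

test_that("component filtering is idempotent, monotone and matches the oracle", {
  set.seed(71)
  for (conn in c(4L, 8L)) {
    for (i in 1:20) {
      sl <- matrix(rbinom(16 * 16, 1, 0.35), 16, 16)
      mask <- array(sl, c(1, 16, 16))
      out <- remove_small_components(mask, 4L, connectivity = conn)
      expect_true(sum(out) <= sum(mask))
      expect_identical(remove_small_components(out, 4L, connectivity = conn),
                       out)
      # against the brute-force flood-fill oracle
      lab <- oracle_components(sl, conn)
      keep <- which(tabulate(lab) >= 4L)
      ref <- array(as.integer(matrix(lab %in% keep & sl == 1, 16, 16)),
                   c(1, 16, 16))
      expect_identical(out, ref)
    }
  }
})

test_that("class priority resolves overlaps toward pectoralis then erector", {
  d <- c(1, 4, 4)
  pect <- array(0L, d); esp <- array(0L, d); ic <- array(0L, d)
  pect[1, 1, 1] <- 1L
  esp[1, 2, 2] <- 1L
  ic[1, 3, 3] <- 1L
  out <- resolve_class_priority(pect, esp, ic)
  expect_equal(out$voxels[1, 1, 1], 1L)
  expect_equal(out$voxels[1, 2, 2], 2L)
  expect_equal(out$voxels[1, 3, 3], 3L)
  expect_equal(sum(out$voxels != 0L), 3)

  # intercostal overlapping pectoralis yields pectoralis
  ic[1, 1, 1] <- 1L
  expect_equal(resolve_class_priority(pect, esp, ic)$voxels[1, 1, 1], 1L)
  # intercostal overlapping erector spinae yields erector spinae
  ic[1, 2, 2] <- 1L
  expect_equal(resolve_class_priority(pect, esp, ic)$voxels[1, 2, 2], 2L)
  # a pixel claimed by all three goes to pectoralis (total order)
  esp[1, 1, 1] <- 1L
  expect_equal(resolve_class_priority(pect, esp, ic)$voxels[1, 1, 1], 1L)

  expect_error(resolve_class_priority(pect, esp, array(0L, c(1, 3, 3))),
               "geometry")
})

test_that("priority output labels are legal and every label was claimed", {
  set.seed(72)
  for (i in 1:10) {
    d <- c(2, 6, 6)
    ms <- lapply(1:3, function(k) array(rbinom(prod(d), 1, 0.3), d))
    out <- resolve_class_priority(ms[[1]], ms[[2]], ms[[3]])
    expect_true(all(out$voxels %in% 0:3))
    claimed <- ms[[1]] | ms[[2]] | ms[[3]]
    expect_true(all((out$voxels != 0) == claimed))
  }
})
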