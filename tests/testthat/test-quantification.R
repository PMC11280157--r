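test_that("volume is the voxel count times the voxel size in cc", {
  vox <- array(0L, c(10, 10, 10))
  expect_equal(muscle_volume_cc(vox, c(0.7, 0.7), 3), 0)
  vox[seq_len(1000)] <- 1L
  expect_equal(muscle_volume_cc(vox, c(0.7, 0.7), 3), 1.47)
  expect_equal(muscle_volume_cc(vox, c(0.7, 0.7), 6),
               2 * muscle_volume_cc(vox, c(0.7, 0.7), 3))
  # exact linearity in the count
  vox2 <- array(0L, c(10, 10, 10)); vox2[seq_len(500)] <- 1L
  expect_equal(muscle_volume_cc(vox2, c(0.7, 0.7), 3),
               muscle_volume_cc(vox, c(0.7, 0.7), 3) / 2)
})

test_that("density is the plain mean HU over masked voxels", {
  ct <- tiny_ct(hu = 50)
  full <- muscle_mask(array(1L, dim(ct$voxels)), "binary")
  expect_equal(muscle_density_hu(full, ct), 50)

  ct2 <- tiny_ct(hu = 0)
  ct2$voxels[1, 1, 1] <- 40
  ct2$voxels[1, 1, 2] <- 60
  two <- array(0L, dim(ct2$voxels)); two[1, 1, 1:2] <- 1L
  expect_equal(muscle_density_hu(two, ct2), 50)

  empty <- muscle_mask(array(0L, dim(ct$voxels)), "binary")
  expect_warning(d <- muscle_density_hu(empty, ct), "empty")
  expect_true(is.na(d))
})

test_that("whole-muscle metrics are exact sums and weighted means", {
  set.seed(81)
  dims <- c(3, 10, 10)
  lab <- array(sample(0:3, prod(dims), TRUE), dims)
  hu <- array(round(runif(prod(dims), 20, 60)), dims)
  ct <- ct_volume(hu, c(0.7, 0.7), 3, subject_id = "Q1")
  m <- muscle_metrics(muscle_mask(lab, "multiclass"), ct)
  expect_identical(m$whole_muscle_volume_cc,
                   m$pectoralis_volume_cc + m$erector_spinae_volume_cc +
                     m$intercostal_volume_cc)
  counts <- vapply(1:3, function(k) sum(lab == k), 0)
  dens <- vapply(1:3, function(k) mean(hu[lab == k]), 0)
  expect_equal(m$whole_muscle_density_hu,
               sum(dens * counts) / sum(counts), tolerance = 1e-12)
  # density is invariant under any relabeling preserving class membership
  relab <- lab
  relab[lab == 1L] <- 1L  # identity relabel of the same membership
  m2 <- muscle_metrics(muscle_mask(relab, "multiclass"), ct)
  expect_equal(m2$pectoralis_density_hu, m$pectoralis_density_hu)
})

test_that("cohort summaries group correctly by sex and age decade", {
  mk <- function(id, sex, age, v) {
    out <- list(subject_id = id, sex = sex, age_years = age)
    for (cl in c("pectoralis", "erector_spinae", "intercostal")) {
      out[[paste0(cl, "_volume_cc")]] <- v
      out[[paste0(cl, "_density_hu")]] <- 45
    }
    out$whole_muscle_volume_cc <- 3 * v
    out$whole_muscle_density_hu <- 45
    structure(out, class = "muscle_metrics")
  }
  # every male volume exceeds every female volume by construction
  ms <- list(mk("a", "M", 45, 110), mk("b", "M", 55, 120),
             mk("c", "F", 65, 60), mk("d", "F", 75, 70),
             mk("e", "F", 41, 80))
  bysex <- cohort_summary(ms, "sex")
  expect_equal(bysex$n, c(3, 2))
  expect_gt(bysex$whole_muscle_volume_cc_mean[bysex$group == "M"],
            bysex$whole_muscle_volume_cc_mean[bysex$group == "F"])
  # group mean of the whole equals the sum of the class-group means
  for (g in c("M", "F")) {
    row <- bysex[bysex$group == g, ]
    expect_equal(row$whole_muscle_volume_cc_mean,
                 row$pectoralis_volume_cc_mean +
                   row$erector_spinae_volume_cc_mean +
                   row$intercostal_volume_cc_mean, tolerance = 1e-12)
  }
  # n = 1 groups report SD 0
  one <- cohort_summary(ms[1], "sex")
  expect_equal(one$whole_muscle_volume_cc_sd, 0)

  byage <- cohort_summary(ms, "age_decade")
  expect_setequal(byage$group, c("40-49", "50-59", "60-69", "70-80"))
  expect_equal(byage$n[byage$group == "40-49"], 2)

  ms_na <- c(ms, list(mk("f", NA, NA, 50)))
  expect_message(cohort_summary(ms_na, "sex"), "excluded")
})
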