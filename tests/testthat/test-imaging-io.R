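test_that("HU clamping bounds values on construction and is idempotent", {
  ct <- tiny_ct(hu = 0)
  ct$voxels[1, 1, 1] <- NA  # construction already clamped; rebuild instead
  raw <- array(c(-5000, -1024, 0, 4000), c(1, 2, 2))
  ct <- ct_volume(raw, c(0.7, 0.7), 3)
  expect_equal(as.vector(ct$voxels), c(-1024, -1024, 0, 3071))
  expect_identical(clamp_hu(ct$voxels), ct$voxels)
})

test_that("ct_volume validates geometry metadata", {
  expect_error(ct_volume(array(0, c(1, 4, 4)), c(-1, 1), 3), "positive")
  expect_error(ct_volume(array(0, c(1, 4, 4)), c(1, 1), 0), "positive")
  expect_error(ct_volume(matrix(0, 4, 4), c(1, 1), 1), "3-D")
})

test_that("NIfTI CT and masks round-trip voxel- and metadata-identically", {
  set.seed(11)
  for (rep in 1:3) {
    dims <- c(sample(2:4, 1), 8L, 8L)
    ct <- ct_volume(array(round(runif(prod(dims), -1000, 2000)), dims),
                    c(0.7, 0.8), 3, subject_id = "S1")
    f <- tempfile(fileext = ".nii.gz")
    write_ct(ct, f)
    back <- read_ct(f, subject_id = "S1")
    expect_equal(back$voxels, ct$voxels)
    expect_equal(back$pixel_spacing_mm, ct$pixel_spacing_mm, tolerance = 1e-6)
    expect_equal(back$slice_thickness_mm, ct$slice_thickness_mm,
                 tolerance = 1e-6)

    mk <- muscle_mask(array(sample(0:3, prod(dims), TRUE), dims),
                      "multiclass", c(0.7, 0.8), 3)
    fm <- tempfile(fileext = ".nii.gz")
    write_mask(mk, fm)
    back <- read_mask(fm, "multiclass")
    expect_identical(back$voxels, mk$voxels)
  }
})

test_that("TIFF stacks round-trip and binary mode maps 0/255 to 0/1", {
  set.seed(12)
  dims <- c(3L, 6L, 6L)
  bin <- muscle_mask(array(rbinom(prod(dims), 1, 0.4), dims), "binary")
  f <- tempfile(fileext = ".tif")
  write_mask(bin, f)  # written as the 0/255 dialect
  back <- read_mask(f, "binary")
  expect_identical(back$voxels, bin$voxels)
  expect_setequal(unique(as.vector(back$voxels)), c(0L, 1L))

  mc <- muscle_mask(array(sample(0:3, prod(dims), TRUE), dims), "multiclass")
  fm <- tempfile(fileext = ".tif")
  write_mask(mc, fm)
  expect_identical(read_mask(fm, "multiclass")$voxels, mc$voxels)
})

test_that("mask mode contracts hold", {
  expect_error(muscle_mask(array(7L, c(1, 2, 2)), "multiclass"), "7")
  z <- muscle_mask(array(0L, c(1, 2, 2)), "binary")
  expect_true(all(z$voxels == 0L))
  v <- muscle_mask(array(255L, c(1, 2, 2)), "binary")
  expect_true(all(v$voxels == 1L))
})

test_that("DICOM series read applies rescale, clamps and orders slices", {
  ns <- asNamespace("respmuscle")
  d <- tempfile(); dir.create(d)
  # slice at z=3 written first: stored 1024 with intercept -1024 -> HU 0
  px0 <- matrix(1024, 8, 8)
  px1 <- matrix(c(rep(1024, 63), 5024), 8, 8)  # one voxel at HU 4000
  ns$.write_dicom_slice(file.path(d, "b.dcm"), px0, c(0.7, 0.7), 3,
                        z_mm = 3, instance = 2L, patient_id = "PX")
  ns$.write_dicom_slice(file.path(d, "a.dcm"), px1, c(0.7, 0.7), 3,
                        z_mm = 0, instance = 1L, patient_id = "PX")
  ct <- read_ct(d, format = "dicom_series")
  expect_equal(dim(ct$voxels), c(2L, 8L, 8L))
  expect_equal(ct$subject_id, "PX")
  # ascending z: slice 1 is the z=0 file despite later directory order
  expect_equal(ct$voxels[1, 8, 8], 3071)    # 4000 HU clamped
  expect_true(all(ct$voxels[2, , ] == 0))   # slope*1024 - 1024
  expect_equal(ct$pixel_spacing_mm, c(0.7, 0.7))
})

test_that("DICOM errors name missing attributes and mixed geometry", {
  ns <- asNamespace("respmuscle")
  d <- tempfile(); dir.create(d)
  ns$.write_dicom_slice(file.path(d, "a.dcm"), matrix(0, 4, 4), c(1, 1), 3,
                        omit = "pixel_spacing")
  expect_error(read_ct(d, format = "dicom_series"), "pixel_spacing")

  d2 <- tempfile(); dir.create(d2)
  ns$.write_dicom_slice(file.path(d2, "a.dcm"), matrix(0, 4, 4), c(1, 1), 3)
  ns$.write_dicom_slice(file.path(d2, "b.dcm"), matrix(0, 6, 6), c(1, 1), 3,
                        z_mm = 3)
  expect_error(read_ct(d2, format = "dicom_series"), "mixed geometry")
})
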