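test_that("scalar_volume validates its invariants", {
  expect_error(scalar_volume(matrix(1, 2, 2)), "3-D")
  expect_error(vol3(c(1, NA, rep(1, 62))), "non-finite")
  expect_error(vol3(rep(1.5, 64), kind = "probability"), "outside")
  expect_error(vol3(rep(1.5, 64), kind = "label"), "integers")
  expect_error(scalar_volume(array(1, c(2, 2, 2)),
                             voxel_size_mm = c(1, -1, 1)), "positive")
  v <- vol3(runif(64), kind = "probability")
  expect_s3_class(v, "scalar_volume")
  expect_identical(dim(v), c(4L, 4L, 4L))
})

test_that("binary_mask counts voxels and keeps shape", {
  m <- binary_mask(array(c(TRUE, FALSE), dim = c(4, 4, 4)))
  expect_equal(m$voxel_count, 32)
  expect_identical(m$source_shape, c(4L, 4L, 4L))
  v <- vol3(1:64)
  expect_length(masked_values <- v$data[m$data], 32)
})

test_that("NIfTI round-trip preserves data and geometry", {
  set.seed(11)
  aff <- diag(c(2.3, 2.3, 4.0, 1))
  aff[1:3, 4] <- c(-50, -60, -30)
  v <- scalar_volume(array(rnorm(6 * 5 * 4), dim = c(6, 5, 4)),
                     voxel_size_mm = c(2.3, 2.3, 4.0), affine = aff,
                     kind = "suv")
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(v, path)
    r <- read_nifti(path, kind = "suv")
    expect_equal(r$data, v$data, tolerance = 1e-6)        # float32 storage
    expect_equal(r$voxel_size_mm, v$voxel_size_mm, tolerance = 1e-6)
    expect_equal(r$affine, v$affine, tolerance = 1e-4)
    unlink(path)
  }
})

test_that("label volumes round-trip as uint8 exactly", {
  lv <- vol3(sample(0:7, 64, replace = TRUE), kind = "label")
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(lv, path)
  r <- read_nifti(path, kind = "label")
  expect_identical(r$data, lv$data)
  unlink(path)
})

test_that("masks are written as uint8 NIfTI", {
  m <- binary_mask(array(c(TRUE, FALSE), dim = c(4, 4, 4)))
  path <- tempfile(fileext = ".nii")
  write_nifti(m, path, voxel_size_mm = c(1, 1, 1))
  r <- read_nifti(path, kind = "label")
  expect_equal(sum(r$data), 32)
  # uint8 datatype => 352-byte header + 64 bytes of data
  expect_equal(file.info(path)$size, 352 + 64)
  unlink(path)
})

test_that("reader applies scl_slope/scl_inter and rejects bad files", {
  # hand-build an int16 NIfTI with slope 0.01, intercept 1
  path <- tempfile(fileext = ".nii")
  con <- file(path, "wb")
  writeBin(348L, con, 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(3, 2, 2, 2, 1, 1, 1, 1)), con, 2)   # dim
  writeBin(numeric(3), con, 4); writeBin(0L, con, 2)
  writeBin(4L, con, 2); writeBin(16L, con, 2); writeBin(0L, con, 2)
  writeBin(c(1, 1, 1, 1, 0, 0, 0, 0), con, 4)               # pixdim
  writeBin(352, con, 4)
  writeBin(0.01, con, 4); writeBin(1, con, 4)               # slope, inter
  writeBin(raw(2 + 2 + 8 + 8 + 8 + 104), con)   # slice_end..aux_file
  writeBin(as.integer(c(0, 0)), con, 2)                     # qform, sform
  writeBin(numeric(6), con, 4)
  writeBin(numeric(12), con, 4)                             # srows
  writeBin(raw(16), con)
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  writeBin(raw(4), con)
  writeBin(as.integer(c(0, 50, 100, 150, 200, 250, 300, 350)), con, 2)
  close(con)
  v <- read_nifti(path)
  expect_equal(v$data[1, 1, 1], 1.0)
  expect_equal(v$data[2, 2, 2], 1 + 3.5, tolerance = 1e-6)  # float32 slope
  unlink(path)

  expect_error(read_nifti(tempfile()), "not found")
  bad <- tempfile()
  writeBin(raw(100), bad)
  expect_error(read_nifti(bad), "truncated|not a NIfTI")
  unlink(bad)
})
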