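test_that("16-bit TIFF stacks round-trip bit-for-bit with sidecar voxel size", {
  set.seed(1)
  arr <- array(sample(0:65535, 10 * 32 * 32, replace = TRUE), c(32, 32, 10))
  vol <- grey_volume(arr, 1.4)
  path <- file.path(tempfile("vol"), "stack.tif")
  dir.create(dirname(path))
  write_volume(vol, path)
  back <- read_volume(path)
  expect_s3_class(back, "grey_volume")
  expect_identical(dim(back$data), c(32L, 32L, 10L))
  expect_equal(back$voxel_size_um, 1.4)
  expect_identical(back$data, vol$data + 0)
})

test_that("float volumes and MHD raw volumes round-trip", {
  set.seed(2)
  arr <- array(rnorm(8 * 8 * 8, 100, 30), c(8, 8, 8))
  vol <- grey_volume(arr, 0.7)
  tf <- tempfile(fileext = ".tif")
  write_volume(vol, tf)
  back <- read_volume(tf)
  # 32-bit float storage: relative precision ~1e-7 of the value range
  expect_lt(max(abs(back$data - arr)), diff(range(arr)) * 1e-6)

  mh <- tempfile(fileext = ".mhd")
  write_volume(vol, mh)
  back2 <- read_volume(mh)
  expect_identical(back2$data, arr)   # doubles, bit-exact
  expect_equal(back2$voxel_size_um, 0.7)
})

test_that("masks store as 0/255 8-bit and labels choose 16/32-bit by range", {
  m <- binary_mask(array(c(TRUE, FALSE), c(4, 4, 2)), 1.4, "bone")
  tf <- tempfile(fileext = ".tif")
  write_volume(m, tf)
  raw <- tiff::readTIFF(tf, all = TRUE, as.is = TRUE)
  expect_setequal(unique(unlist(raw)), c(0L, 255L))
  back <- read_volume(tf)
  expect_s3_class(back, "binary_mask")
  expect_identical(back$data, m$data)

  lab <- label_map(array(c(0L, 70000L), c(4, 4, 2)), 1.4)
  tf2 <- tempfile(fileext = ".tif")
  write_volume(lab, tf2)
  sidecar <- yaml::read_yaml(paste0(tools::file_path_sans_ext(tf2), ".yml"))
  expect_equal(sidecar$scale, 70000)   # stored as scaled 32-bit pages
  back2 <- read_volume(tf2)
  expect_s3_class(back2, "label_map")
  expect_identical(back2$data, lab$data)

  big <- label_map(array(c(0L, 2L^24L + 10L), c(2, 2, 2)), 1.4)
  expect_error(write_volume(big, tempfile(fileext = ".tif")), "capacity")
})

test_that("directory stacks reject inconsistent slice shapes, naming the slice", {
  dirp <- tempfile("slices")
  dir.create(dirp)
  for (k in 1:6) {
    sl <- matrix(runif(if (k == 5) 31 * 32 else 32 * 32),
                 nrow = if (k == 5) 31 else 32)
    tiff::writeTIFF(sl, file.path(dirp, sprintf("slice_%02d.tif", k)))
  }
  expect_error(read_volume(dirp, meta = list(voxel_size_um = 1.4)),
               "slice_05")
})

test_that("reading without any voxel-size metadata is a metadata error", {
  tf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4)), tf)
  expect_error(read_volume(tf), "metadata error")
  ok <- read_volume(tf, meta = list(voxel_size_um = 2))
  expect_equal(ok$voxel_size_um, 2)
})

test_that("merge_scans reproduces the two-scan acquisition geometry", {
  # two 1400-slice scans with a 200-slice (280 um / 1.4 um) overlap
  lower <- grey_volume(array(runif(4 * 4 * 1400), c(4, 4, 1400)), 1.4)
  upper <- grey_volume(array(runif(4 * 4 * 1400), c(4, 4, 1400)), 1.4)
  merged <- merge_scans(lower, upper, 200)
  expect_identical(dim(merged$data)[3], 2600L)

  # blending preserves constants
  cst <- grey_volume(array(7, c(4, 4, 30)), 1.4)
  out <- merge_scans(cst, cst, 10)
  expect_lt(max(abs(out$data - 7)), 1e-12)

  # merging a volume with a copy of its own top region is the identity
  top <- grey_volume(lower$data[, , 1201:1400, drop = FALSE], 1.4)
  rec <- merge_scans(lower, top, 200)
  expect_equal(rec$data, lower$data)

  expect_error(merge_scans(lower, upper, 0), "overlap")
  bad <- grey_volume(upper$data, 0.7)
  expect_error(merge_scans(lower, bad, 10), "unit error")
})
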