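test_that("multi-page TIFF preserves shape and integer data", {
  v <- vol3(0:47, c(3, 4, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(v, path)
  r <- read_image(path)
  expect_identical(dim(r$data), c(3L, 4L, 4L))
  expect_equal(r$data, v$data, ignore_attr = TRUE)
  # TIFF carries no spacing; the default applies
  expect_equal(r$spacing, c(2.50, 0.75, 0.75))
})

test_that("a directory of slice files is ordered lexicographically", {
  dir <- withr::local_tempdir()
  # write slices deliberately out of order; 1-voxel slices with distinct values
  for (nm in c("z002.tif", "z000.tif", "z001.tif")) {
    val <- as.integer(sub("z00(\\d).tif", "\\1", nm)) * 10L
    tiff::writeTIFF(matrix(val / 255, 1, 1), file.path(dir, nm),
                    bits.per.sample = 8L)
  }
  r <- read_image(dir)
  expect_identical(dim(r$data), c(3L, 1L, 1L))
  expect_equal(as.vector(r$data), c(0, 10, 20))
})

test_that("inconsistent slice shapes in a stack are rejected", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 2, 2), file.path(dir, "a.tif"))
  tiff::writeTIFF(matrix(0, 3, 2), file.path(dir, "b.tif"))
  expect_error(read_image(dir), "inconsistent slice shapes")
})

test_that("NIfTI round-trips data and voxel spacing", {
  v <- vol3(sample.int(4000, 60), c(3, 4, 5), spacing = c(2.5, 0.75, 0.75))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(v, path)
  r <- read_image(path)
  expect_equal(r$data, v$data, ignore_attr = TRUE)
  expect_equal(r$spacing, c(2.5, 0.75, 0.75))
})

test_that("float volumes round-trip within machine precision", {
  set.seed(7)
  vals <- runif(24)
  v <- vol3(vals, c(2, 3, 4))
  nii <- withr::local_tempfile(fileext = ".nii")
  write_image(v, nii)
  expect_equal(read_image(nii)$data, v$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_image(v, tif)
  # 32-bit float storage: relative error bounded by float machine epsilon
  expect_equal(read_image(tif)$data, v$data, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("unsupported dtypes for TIFF raise a dtype error", {
  too_big <- vol3(c(rep(0, 7), 70000), c(2, 2, 2))
  expect_error(write_image(too_big, withr::local_tempfile(fileext = ".tif")),
               "65535")
  floats <- vol3(c(rep(0.5, 7), 1.5), c(2, 2, 2))
  expect_error(write_image(floats, withr::local_tempfile(fileext = ".tif")),
               "\\[0, 1\\]")
})

test_that("zero volume writes and round-trips", {
  v <- vol3(0, c(2, 2, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(v, path)
  expect_true(file.exists(path))
  expect_equal(read_image(path)$data, v$data, ignore_attr = TRUE)
})

test_that("label volumes round-trip with the identical label set", {
  for (ext in c(".tif", ".nii")) {
    l <- labs3(sample(c(0L, 1L, 2L), 60, replace = TRUE), c(3, 4, 5))
    path <- withr::local_tempfile(fileext = ext)
    write_labels(l, path)
    r <- read_labels(path)
    expect_identical(r$data, l$data, label = ext)
    expect_identical(region_labels(r), region_labels(l))
  }
})

test_that("empty label volume round-trips with zero regions", {
  l <- labs3(0L, c(2, 3, 3))
  path <- withr::local_tempfile(fileext = ".nii")
  write_labels(l, path)
  r <- read_labels(path)
  expect_equal(count_regions(r), 0)
})

test_that("non-integer voxel values are rejected as labels", {
  v <- vol3(c(0.25, rep(0, 7)), c(2, 2, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(v, path)
  expect_error(read_labels(path), "non-integer")
})

test_that("label dtype on write is the smallest unsigned width that fits", {
  small <- labs3(c(rep(0L, 7), 200L), c(2, 2, 2))
  big <- labs3(c(rep(0L, 7), 300L), c(2, 2, 2))
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_labels(small, p1); write_labels(big, p2)
  info1 <- tiff::readTIFF(p1, payload = FALSE)
  info2 <- tiff::readTIFF(p2, payload = FALSE)
  expect_equal(info1$bits.per.sample, 8L)
  expect_equal(info2$bits.per.sample, 16L)
  expect_identical(read_labels(p2)$data, big$data)
})

test_that("mismatched image/label shapes are rejected before editing", {
  img <- vol3(0, c(2, 2, 2))
  lab <- labs3(0L, c(2, 2, 3))
  expect_error(check_pair(img, lab), "different shapes")
  expect_error(grow_region(img, lab, 1L, c(1, 1, 1)), "different shapes")
})

test_that("metadata sidecar round-trips, including unknown keys", {
  meta <- region_metadata(
    entries = list(`1` = list(modified = FALSE, done = TRUE, color = "red"),
                   `4` = list(modified = TRUE, done = FALSE)),
    extra = list(tool_note = "kept"))
  path <- withr::local_tempfile(fileext = ".json")
  write_metadata(meta, path)
  r <- read_metadata(path)
  expect_equal(r$version, 1L)
  expect_true(r$entries[["1"]]$done)
  expect_false(r$entries[["1"]]$modified)
  expect_true(r$entries[["4"]]$modified)
  expect_equal(r$entries[["1"]]$color, "red")      # unknown region key kept
  expect_equal(r$extra$tool_note, "kept")          # unknown top-level key kept
  # second round-trip is stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_metadata(r, path2)
  expect_equal(read_metadata(path2), r)
})

test_that("a missing sidecar reads as empty metadata", {
  r <- read_metadata(file.path(tempdir(), "does-not-exist.json"))
  expect_s3_class(r, "region_metadata")
  expect_length(r$entries, 0)
})

test_that("malformed JSON raises a parse error naming the file", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version": 1, "regions": {', path)
  expect_error(read_metadata(path), "malformed JSON")
})

test_that("sidecar entries for absent labels load with a stale warning", {
  labels <- labs3(c(rep(0L, 7), 2L), c(2, 2, 2))
  meta <- region_metadata(entries = list(
    `2` = list(modified = FALSE, done = TRUE),
    `9` = list(modified = TRUE, done = FALSE)))
  path <- withr::local_tempfile(fileext = ".json")
  write_metadata(meta, path)
  expect_warning(r <- read_metadata(path, labels), "stale.*9")
  expect_true(isTRUE(r$entries[["9"]]$stale))
  expect_null(r$entries[["2"]]$stale)
})
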