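test_that("scalar NRRD volumes round-trip with geometry intact", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  set.seed(4)
  v <- volume_grid(array(sample(0:4095, 64, TRUE), c(4, 4, 4)),
                   spacing = c(0.125, 0.125, 0.125), origin = c(1, -2, 3),
                   type = "uint16")
  write_nrrd(v, f)
  b <- read_nrrd(f)
  expect_identical(b$voxels, v$voxels)
  expect_identical(b$type, "uint16")
  expect_lt(max(abs(b$spacing - v$spacing)), 1e-9)
  expect_lt(max(abs(b$origin - v$origin)), 1e-9)
})

test_that("RGB NRRD volumes round-trip with 3-sample fastest axis", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  set.seed(5)
  v <- volume_grid(array(sample(0:255, 3 * 8 * 8 * 2, TRUE), c(3, 8, 8, 2)),
                   spacing = c(0.05, 0.05, 0.15))
  write_nrrd(v, f)
  b <- read_nrrd(f)
  expect_true(b$rgb)
  expect_identical(b$voxels, v$voxels)
  expect_lt(max(abs(b$spacing - v$spacing)), 1e-9)
  # header declares the colour axis
  hdr <- readLines(f, n = 12, warn = FALSE)
  expect_true(any(grepl("kinds: RGB-color domain domain domain", hdr)))
})

test_that("invalid volumes and unsupported encodings are rejected", {
  expect_error(volume_grid(array(0L, c(0, 4, 4)), c(1, 1, 1)), "empty")
  expect_error(volume_grid(array(0L, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  f <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: unsigned char", "dimension: 3",
               "sizes: 2 2 2", "encoding: bzip2", ""), f)
  expect_error(read_nrrd(f), "unsupported NRRD encoding")
  writeLines(c("NRRD0004", "type: block", "dimension: 3",
               "sizes: 2 2 2", "encoding: raw", ""), f)
  expect_error(read_nrrd(f), "unsupported NRRD type")
})

test_that("written NRRD is readable by an independent implementation", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  set.seed(6)
  v <- volume_grid(array(sample(0:255, 5 * 6 * 7, TRUE), c(5, 6, 7)),
                   spacing = c(0.05, 0.1, 0.15), origin = c(0.5, 0, -1))
  write_nrrd(v, f)
  script <- paste(
    "import SimpleITK as sitk, sys",
    "img = sitk.ReadImage(sys.argv[1])",
    "a = sitk.GetArrayFromImage(img)",
    "print(list(img.GetSize()), list(img.GetSpacing()), int(a.sum()))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script), shQuote(f)),
                 stdout = TRUE, stderr = TRUE)
  expect_match(paste(out, collapse = " "),
               "\\[5, 6, 7\\] \\[0.05, 0.1, 0.15\\]")
  expect_match(paste(out, collapse = " "),
               as.character(sum(v$voxels)))
})
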