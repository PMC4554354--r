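test_that("fc_image enforces its container invariants", {
  ch <- list(matrix(0L, 4, 4), matrix(1L, 4, 4))
  img <- fc_image(ch, bit_depth = 8L)
  expect_s3_class(img, "fc_image")
  expect_identical(img$roles, list(roi = 1L, foci1 = 2L))

  expect_error(fc_image(list(matrix(0L, 4, 4), matrix(0L, 5, 4))),
               "identical dimensions")
  expect_error(fc_image(list(matrix(300L, 2, 2)), bit_depth = 8L),
               "bit depth")
  expect_error(fc_image(ch, roles = list(roi = 1L, foci1 = 1L)), "distinct")
  expect_error(fc_image(ch, roles = list(roi = 1L, foci1 = 6L)), "out of range")
  expect_error(fc_image(ch, roles = list(roi = 1L)), "foci1")
  expect_error(fc_image(ch, roles = list(roi = 1L, foci1 = 2L, extra = 2L)),
               "at most three")
})

test_that("inversion complements pixels and is an involution", {
  img8 <- fc_image(list(matrix(c(0L, 255L, 17L, 100L), 2, 2),
                        matrix(0L, 2, 2)), bit_depth = 8L)
  inv <- fc_invert(img8)
  expect_identical(inv$channels[[1]][1, 1], 255L)
  expect_identical(inv$channels[[1]][2, 1], 0L)
  expect_identical(fc_invert(inv)$channels, img8$channels)

  img16 <- fc_image(list(matrix(65535L, 2, 2), matrix(0L, 2, 2)))
  expect_identical(fc_invert(img16)$channels[[1]][1, 1], 0L)
})

test_that("inversion of a light-background image restores bright maxima", {
  g <- fc_generate_image(fc_synth_spec(image_size = c(96, 96), n_nuclei = 1,
                                       foci_per_nucleus = 3, noise_sigma = 0,
                                       light_background = TRUE, seed = 5))
  dark <- fc_invert(g$image)
  px <- which(g$truth$labels == 1L)
  f <- fc_find_maxima(fc_channel(dark, "foci1"), px, 50)
  expect_setequal(paste(f$x, f$y), paste(g$truth$foci_1$x, g$truth$foci_1$y))
})

test_that("TIFF round trip is bit-exact, multichannel and 8/16-bit", {
  for (bd in c(8L, 16L)) {
    maxv <- 2L^bd - 1L
    set.seed(bd)
    ch <- list(matrix(sample.int(maxv + 1L, 64, TRUE) - 1L, 8, 8),
               matrix(sample.int(maxv + 1L, 64, TRUE) - 1L, 8, 8))
    img <- fc_image(ch, bit_depth = bd)
    f <- withr::local_tempfile(fileext = ".tif")
    fc_write_image(img, f)
    back <- fc_read_image(f, fc_assignment())
    expect_identical(back$channels, img$channels)
    expect_identical(back$bit_depth, bd)
  }
})

test_that("PNG input decodes with its declared bit depth", {
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  m <- matrix(c(0, 128, 17, 255) / 255, 2, 2)
  png::writePNG(m, f1)
  png::writePNG(m, f2)
  dec <- fc_read_image(c(f1, f2), fc_assignment(mode = "per_channel_files"))
  expect_identical(dec$bit_depth, 8L)
  expect_identical(dec$channels[[1]], matrix(c(0L, 128L, 17L, 255L), 2, 2))
})

test_that("loading errors are informative", {
  expect_error(fc_read_image("no/such/file.tif"), "not found")
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), f) # RGB
  expect_error(fc_read_image(f), "color")
  f2 <- withr::local_tempfile(fileext = ".tif")
  fc_write_image(fc_image(list(matrix(0L, 4, 4), matrix(0L, 4, 4))), f2)
  expect_error(fc_read_image(f2, fc_assignment(roi_channel = 1, foci1_channel = 6)),
               "out of range")
  fa <- withr::local_tempfile(fileext = ".tif")
  fb <- withr::local_tempfile(fileext = ".tif")
  fc_write_image(matrix(0L, 4, 4), fa)
  fc_write_image(matrix(0L, 5, 4), fb)
  expect_error(fc_read_image(c(fa, fb), fc_assignment(mode = "per_channel_files")),
               "mismatched")
})

test_that("batch enumeration recurses, sorts, and reports incomplete groups", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "b"))
  fc_write_image(matrix(0L, 4, 4), file.path(root, "b", "2.tif"))
  fc_write_image(matrix(0L, 4, 4), file.path(root, "a1.tif"))
  inp <- fc_list_inputs(root, fc_assignment())
  expect_identical(basename(inp$group), c("a1.tif", "2.tif"))
  expect_identical(inp$group, sort(inp$group, method = "radix"))
  # stable across runs
  expect_identical(fc_list_inputs(root, fc_assignment()), inp)

  empty <- withr::local_tempdir()
  expect_warning(e <- fc_list_inputs(empty, fc_assignment()), "no analyzable")
  expect_identical(nrow(e), 0L)

  pc <- withr::local_tempdir()
  fc_write_image(matrix(0L, 4, 4), file.path(pc, "x_c0.tif"))
  fc_write_image(matrix(0L, 4, 4), file.path(pc, "y_c0.tif"))
  fc_write_image(matrix(0L, 4, 4), file.path(pc, "y_c1.tif"))
  got <- fc_list_inputs(pc, fc_assignment(mode = "per_channel_files"))
  expect_identical(basename(got$group), "y.tif")
  expect_identical(length(got$paths[[1]]), 2L)
  skipped <- attr(got, "skipped")
  expect_identical(basename(skipped$group), "x.tif")
  expect_match(skipped$reason, "incomplete")
})
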