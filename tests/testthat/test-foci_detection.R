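all_px <- function(n) which(matrix(TRUE, n, n))

test_that("prominence maxima behave on canonical small rasters", {
  # constant ROI: no strict peak
  expect_identical(nrow(fc_find_maxima(matrix(5L, 8, 8), all_px(8), 3)), 0L)

  # isolated single-pixel peak
  r <- matrix(0L, 9, 9); r[4, 6] <- 200L
  f <- fc_find_maxima(r, all_px(9), 10)
  expect_identical(nrow(f), 1L)
  expect_identical(c(f$x, f$y), c(5L, 3L)) # 0-based (x=col-1, y=row-1)
  expect_identical(f$peak_intensity, 200)

  # two peaks joined by a ridge: merged at high tolerance, split at low
  r2 <- matrix(0L, 5, 11)
  r2[3, ] <- c(0L, 100L, 200L, 160L, 150L, 145L, 148L, 150L, 150L, 100L, 0L)
  hi <- fc_find_maxima(r2, which(r2 > -1L), 20)
  expect_identical(nrow(hi), 1L)
  expect_identical(hi$peak_intensity, 200)
  lo <- fc_find_maxima(r2, which(r2 > -1L), 4)
  expect_identical(nrow(lo), 2L)

  # plateau: one focus at the plateau centroid pixel
  r3 <- matrix(0L, 7, 7); r3[3:4, 3:4] <- 80L
  f3 <- fc_find_maxima(r3, all_px(7), 5)
  expect_identical(nrow(f3), 1L)
  expect_true(f3$x %in% 2:3 && f3$y %in% 2:3)
})

test_that("maxima agree with the brute-force prominence oracle on random rasters", {
  for (s in 1:30) {
    r <- random_raster(s, 20, 40)
    nl <- withr::with_seed(s + 999L, sample(c(0, 1, 3, 7, 15), 1))
    # random ROI: a central blob
    px <- which(disk_mask(7, 2)[1:19, 1:19] | matrix(FALSE, 19, 19))
    r <- r[1:19, 1:19]
    got <- fc_find_maxima(r, px, nl)
    want <- oracle_find_maxima(r, px, nl)
    expect_identical(nrow(got), nrow(want))
    expect_setequal(paste(got$x, got$y, got$peak_intensity),
                    paste(want$x, want$y, want$peak))
  }
})

test_that("cutoff retains foci at or above the floor, preserving order", {
  f <- tibble::tibble(x = 1:3, y = 1:3, peak_intensity = c(120, 80, 200))
  expect_identical(fc_apply_cutoff(f, 100)$peak_intensity, c(120, 200))
  expect_identical(fc_apply_cutoff(f, 0), f)
  expect_identical(fc_apply_cutoff(f, NULL), f)
  expect_identical(nrow(fc_apply_cutoff(f, 1e5)), 0L)
  expect_identical(fc_apply_cutoff(f, 120)$peak_intensity, c(120, 200)) # >= rule
})

test_that("per-ROI detection tags foci and respects ROI boundaries", {
  g <- fc_generate_image(fc_synth_spec(image_size = c(200, 200), n_nuclei = 2,
                                       foci_per_nucleus = c(3, 0), seed = 9))
  rois <- fc_segment(g$image, fc_seg_params(min_area = 100))
  # cutoff above the nucleus pedestal suppresses the foci-free nucleus'
  # global noise maximum
  foci <- fc_detect_foci(g$image, rois,
                         fc_foci_params(noise_level_1 = 100, cutoff_1 = 2100))
  counts <- table(factor(foci$roi_id, levels = rois$roi_id))
  expect_identical(sort(as.integer(counts)), c(0L, 3L))
  # all detections lie inside their ROI's pixel set
  dimr <- attr(rois, "raster_dim")
  for (i in seq_len(nrow(foci))) {
    px <- rois$pixels[rois$roi_id == foci$roi_id[i]][[1]]
    idx <- foci$x[i] * dimr[1] + foci$y[i] + 1L
    expect_true(idx %in% px)
  }

  # a bright peak outside every ROI contributes nothing
  img2 <- g$image
  ch <- img2$channels[[img2$roles$foci1]]
  ch[2, 2] <- 60000L # far from any nucleus
  img2$channels[[img2$roles$foci1]] <- ch
  foci2 <- fc_detect_foci(img2, rois,
                          fc_foci_params(noise_level_1 = 100, cutoff_1 = 2100))
  expect_identical(nrow(foci2), nrow(foci))

  # foci2 parameters without a foci2 channel is a configuration error
  expect_error(fc_detect_foci(g$image, rois,
                              fc_foci_params(noise_level_1 = 100,
                                             noise_level_2 = 50)),
               "configuration error")
})

test_that("foci counts are monotone in noise level and cutoff", {
  for (s in 1:20) {
    r <- random_raster(s, 24, 200)
    px <- all_px(24)
    nls <- c(0, 5, 20, 60, 150)
    counts <- vapply(nls, function(nl) nrow(fc_find_maxima(r, px, nl)), integer(1))
    expect_true(all(diff(counts) <= 0L))
    f0 <- fc_find_maxima(r, px, 10)
    cuts <- c(0, 50, 120, 190)
    ccounts <- vapply(cuts, function(ct) nrow(fc_apply_cutoff(f0, ct)), integer(1))
    expect_true(all(diff(ccounts) <= 0L))
  }
})

test_that("detection is shift-invariant and local to the ROI", {
  r <- random_raster(77, 20, 100)
  px <- which(disk_mask(7, 2)[1:19, 1:19]); r <- r[1:19, 1:19]
  base <- fc_find_maxima(r, px, 8)
  shifted <- fc_find_maxima(r + 37L, px, 8)
  expect_identical(base$x, shifted$x)
  expect_identical(base$y, shifted$y)
  expect_identical(shifted$peak_intensity, base$peak_intensity + 37)

  # locality: scrambling everything outside the ROI changes nothing
  r2 <- r
  outside <- setdiff(seq_along(r2), px)
  r2[outside] <- withr::with_seed(1L, sample.int(1000, length(outside), TRUE))
  after <- fc_find_maxima(r2, px, 8)
  expect_identical(base, after)
})
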