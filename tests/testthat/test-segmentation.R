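test_that("manual thresholding marks exactly the pixels >= threshold", {
  r <- matrix(c(0L, 200L, 100L, 300L), 2, 2) # [[0,100],[200,300]] row-major
  m <- fc_threshold(r, fc_seg_params(threshold_mode = "manual",
                                     manual_threshold = 150))
  expect_identical(unname(as.vector(m)), c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(attr(m, "threshold"), 150)
  # threshold value itself is foreground
  m2 <- fc_threshold(r, fc_seg_params(threshold_mode = "manual",
                                      manual_threshold = 200))
  expect_true(m2[2, 1])
  expect_error(
    fc_threshold(r, fc_seg_params(threshold_mode = "manual",
                                  manual_threshold = 1e6)),
    "value range")
})

test_that("raising a manual threshold never grows the mask", {
  for (s in 1:20) {
    r <- random_raster(s, 24, 500)
    ts <- sort(withr::with_seed(s * 7L, sample.int(480, 2)))
    m_lo <- fc_threshold(r, fc_seg_params(threshold_mode = "manual",
                                          manual_threshold = ts[1]))
    m_hi <- fc_threshold(r, fc_seg_params(threshold_mode = "manual",
                                          manual_threshold = ts[2]))
    expect_true(all(m_lo | !m_hi)) # m_hi subset of m_lo
  }
})

test_that("isodata auto threshold matches the histogram recursion and splits a bimodal raster", {
  withr::with_seed(11, {
    bg <- matrix(round(rnorm(120 * 120, 50, 5)), 120, 120)
    r <- bg
    g <- expand.grid(i = 1:120, j = 1:120)
    disks <- (g$i - 35)^2 + (g$j - 40)^2 <= 15^2 |
             (g$i - 80)^2 + (g$j - 80)^2 <= 12^2
    r[matrix(disks, 120, 120)] <- round(rnorm(sum(disks), 200, 5))
  })
  storage.mode(r) <- "integer"
  t_impl <- fc_isodata_threshold(r)
  expect_gt(t_impl, 70); expect_lt(t_impl, 180)
  # independent oracle: the same recursion computed from the integer histogram
  h <- tabulate(as.vector(r) + 1L, nbins = max(r) + 1L)
  vals <- seq_along(h) - 1
  t_or <- sum(vals * h) / sum(h)
  repeat {
    lo <- vals <= t_or
    mlo <- sum(vals[lo] * h[lo]) / sum(h[lo])
    mhi <- sum(vals[!lo] * h[!lo]) / sum(h[!lo])
    t_new <- (mlo + mhi) / 2
    if (abs(t_new - t_or) < 0.5) { t_or <- t_new; break }
    t_or <- t_new
  }
  expect_lt(abs(t_impl - t_or), 1.0)
  # auto threshold on constant raster is a degenerate image
  expect_error(fc_threshold(matrix(7L, 5, 5), fc_seg_params()), "degenerate")
  expect_error(fc_threshold(matrix(7L, 5, 5),
                            fc_seg_params(auto_method = "otsu")), "degenerate")
})

test_that("hole filling closes enclosed holes only, monotonically and idempotently", {
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE; ring[4, 4] <- FALSE
  filled <- fc_fill_holes(ring)
  expect_true(filled[4, 4])
  expect_true(all(filled[2:6, 2:6]))
  # background touching the border is not a hole
  open_c <- matrix(FALSE, 7, 7)
  open_c[2:6, 2:6] <- TRUE; open_c[1:4, 4] <- FALSE
  expect_identical(fc_fill_holes(open_c), open_c)
  # idempotent and never removes foreground
  expect_identical(fc_fill_holes(filled), filled)
  expect_true(all(filled | !ring))
  allt <- matrix(TRUE, 5, 5)
  expect_identical(fc_fill_holes(allt), allt)
})

test_that("labeling is 8-connected and deterministic", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal touch: one object
  expect_identical(max(fc_label(m)), 1L)
  m[5, 5] <- TRUE
  lab <- fc_label(m)
  expect_identical(max(lab), 2L)
  expect_identical(lab, fc_label(m))
})

test_that("watershed splits touching disks near the neck and leaves others alone", {
  # two disjoint disks: identical to plain components
  m <- matrix(FALSE, 40, 80)
  g <- expand.grid(r = 1:40, c = 1:80)
  m[matrix((g$r - 20)^2 + (g$c - 18)^2 <= 100, 40, 80)] <- TRUE
  m[matrix((g$r - 20)^2 + (g$c - 60)^2 <= 100, 40, 80)] <- TRUE
  expect_identical(max(fc_watershed_split(m)), 2L)

  # overlapping radius-15 disks, centers 24 px apart: split in two, each
  # piece's centroid within 3 px of its generating center
  h <- 60; w <- 80
  g <- expand.grid(r = 1:h, c = 1:w)
  mm <- matrix((g$r - 30)^2 + (g$c - 28)^2 <= 225 |
               (g$r - 30)^2 + (g$c - 52)^2 <= 225, h, w)
  ws <- fc_watershed_split(mm)
  expect_identical(max(ws), 2L)
  rois <- fc_extract_rois(ws, fc_seg_params(min_area = 1, exclude_edge = FALSE))
  cents <- rois[order(rois$x), c("x", "y")]
  expect_lt(sqrt((cents$x[1] - 27)^2 + (cents$y[1] - 29)^2), 3)
  expect_lt(sqrt((cents$x[2] - 51)^2 + (cents$y[2] - 29)^2), 3)
  # pixel coverage preserved
  expect_identical(ws > 0L, mm)

  # a single convex object is never fragmented
  expect_identical(max(fc_watershed_split(disk_mask(15))), 1L)
})

test_that("ROI filters drop by size, circularity and border contact with counts", {
  # three blobs with areas 10, 500, 20000
  m <- matrix(FALSE, 300, 300)
  m[10:11, 10:14] <- TRUE                      # 10 px
  m[50:69, 50:74] <- TRUE                      # 500 px
  m[100:241, 100:240] <- TRUE                  # 20022 px
  rois <- fc_extract_rois(fc_label(m),
                          fc_seg_params(min_area = 50, max_area = 10000,
                                        min_circularity = 0, exclude_edge = FALSE))
  expect_identical(nrow(rois), 1L)
  expect_identical(rois$area, 500)
  expect_identical(rois$roi_id, 1L)
  expect_identical(unname(attr(rois, "dropped")["size"]), 2L)

  # border contact
  mb <- matrix(FALSE, 20, 20); mb[1:5, 8:12] <- TRUE
  r_edge <- fc_extract_rois(fc_label(mb),
                            fc_seg_params(min_area = 1, exclude_edge = TRUE))
  expect_identical(nrow(r_edge), 0L)
  expect_identical(unname(attr(r_edge, "dropped")["edge"]), 1L)
  r_keep <- fc_extract_rois(fc_label(mb),
                            fc_seg_params(min_area = 1, exclude_edge = FALSE))
  expect_identical(nrow(r_keep), 1L)
  expect_true(r_keep$touches_border)

  # circularity separates a disk from a thin bar
  big <- matrix(FALSE, 120, 120)
  big[1:49, 1:49] <- disk_mask(20, 4) # radius-20 disk block
  big[80:84, 30:89] <- TRUE           # 5x60 bar
  rois2 <- fc_extract_rois(fc_label(big),
                           fc_seg_params(min_area = 1, min_circularity = 0.8,
                                         exclude_edge = FALSE))
  expect_identical(nrow(rois2), 1L)
  expect_gt(rois2$circularity, 0.8)
  all2 <- fc_extract_rois(fc_label(big),
                          fc_seg_params(min_area = 1, exclude_edge = FALSE))
  bar <- all2[all2$area == 300, ]
  expect_lt(bar$circularity, 0.5)
})

test_that("circularity follows its closed form, is capped, and errors on bad perimeter", {
  expect_equal(fc_circularity(pi * 10^2, 2 * pi * 10), 1.0)
  expect_equal(fc_circularity(100, 40), pi / 4)
  # scale invariance for ideal shapes: doubling linear size changes nothing
  expect_equal(fc_circularity(4 * 100, 2 * 40), fc_circularity(100, 40))
  expect_equal(fc_circularity(1e6, 10), 1.0) # capped
  expect_error(fc_circularity(10, 0), "perimeter")
})

test_that("rasterized disk circularity agrees with a boundary-walk oracle", {
  d <- disk_mask(20)
  rois <- fc_extract_rois(fc_label(d),
                          fc_seg_params(min_area = 1, exclude_edge = FALSE))
  expect_gte(rois$circularity, 0.85)
  expect_lte(rois$circularity, 1.0)
  p_or <- oracle_perimeter_convex(d)
  circ_or <- min(1, 4 * pi * rois$area / p_or^2)
  expect_gte(circ_or, 0.85)
  expect_lte(circ_or, 1.0)
  expect_lt(abs(rois$perimeter - p_or) / p_or, 0.08)
})

test_that("planted nuclei are recovered exactly with centroids on target", {
  for (k in c(1, 5)) {
    g <- fc_generate_image(fc_synth_spec(
      image_size = c(384, 384), n_nuclei = k, foci_per_nucleus = 0, seed = 20 + k))
    rois <- fc_segment(g$image, fc_seg_params(min_area = 200))
    expect_identical(nrow(rois), as.integer(k))
    tr <- g$truth$nuclei
    for (i in seq_len(k)) {
      d <- min(sqrt((rois$x - tr$cx[i])^2 + (rois$y - tr$cy[i])^2))
      expect_lt(d, 2)
    }
  }
})

test_that("segmentation is deterministic bit-for-bit", {
  g <- fc_generate_image(fc_synth_spec(image_size = c(256, 256), n_nuclei = 5,
                                       foci_per_nucleus = 0, seed = 3))
  a <- fc_segment(g$image, fc_seg_params(min_area = 100))
  b <- fc_segment(g$image, fc_seg_params(min_area = 100))
  expect_identical(a, b)
})
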