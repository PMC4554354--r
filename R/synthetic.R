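#' Specification for a synthetic multi-channel fluorescence image
#'
#' The generator emulates the assay the pipeline is built for: a
#' nuclear-stain channel with bright elliptical nuclei on a dark background
#' (or inverted, for light-background material) and one or two foci channels
#' in which Gaussian-profile puncta sit on the nuclear pedestal, with
#' additive Gaussian read-out noise. Exact ground truth (nucleus masks, focus
#' positions, colocalized pairs) is returned with every image.
#'
#' Default intensities follow an SNR design: 16-bit range, background 400,
#' nuclei 1500 counts above background, foci 250 counts above the nucleus at
#' their peak with a 1.5 px Gaussian sigma (diffraction-limited spot at high
#' magnification), and noise sigma 25 — foci 10 noise-sigma tall, nuclei
#' separable from background by any sensible threshold.
#'
#' @param image_size `(height, width)` in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_axes_range `(min, max)` semi-axis length in pixels; each
#'   nucleus draws two semi-axes and an orientation uniformly.
#' @param nucleus_intensity pedestal height above background inside a
#'   nucleus (raster units).
#' @param allow_touching if `FALSE`, nuclei are placed with disjoint,
#'   margin-separated bounding boxes (generation fails if they cannot fit);
#'   if `TRUE` placement is unconstrained and nuclei may overlap.
#' @param foci_per_nucleus integer, or vector of length `n_nuclei`.
#' @param focus_amplitude peak height of a focus above the nucleus pedestal.
#' @param focus_sigma Gaussian sigma of a focus in pixels.
#' @param min_focus_spacing minimum distance between focus centers within a
#'   nucleus and channel.
#' @param coloc_fraction fraction of channel-1 foci given a channel-2
#'   partner (`round(coloc_fraction * n)` pairs per nucleus).
#' @param coloc_offset_max maximum Euclidean offset (pixels) of a planted
#'   partner from its channel-1 focus.
#' @param decoy_min_distance minimum distance of non-partner ("decoy")
#'   channel-2 foci from every channel-1 focus.
#' @param noise_sigma additive Gaussian noise sigma (raster units).
#' @param background_level dark-background offset (raster units).
#' @param light_background invert the final rasters (bright background).
#' @param bit_depth 8 or 16.
#' @param two_channels plant a second foci channel at all.
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return list of class `fc_synth_spec`.
#' @export
fc_synth_spec <- function(image_size = c(512, 512), n_nuclei = 12,
                          nucleus_axes_range = c(18, 30),
                          nucleus_intensity = 1500, allow_touching = FALSE,
                          foci_per_nucleus = 10, focus_amplitude = 250,
                          focus_sigma = 1.5, min_focus_spacing = 6,
                          coloc_fraction = 0, coloc_offset_max = 1,
                          decoy_min_distance = 10,
                          noise_sigma = 25, background_level = 400,
                          light_background = FALSE, bit_depth = 16L,
                          two_channels = coloc_fraction > 0, seed = 1L) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("generation error: coloc_fraction must lie in [0, 1]", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("generation error: bit_depth must be 8 or 16", call. = FALSE)
  two_channels <- force(two_channels)
  structure(list(
    image_size = image_size, n_nuclei = n_nuclei,
    nucleus_axes_range = nucleus_axes_range,
    nucleus_intensity = nucleus_intensity, allow_touching = allow_touching,
    foci_per_nucleus = foci_per_nucleus, focus_amplitude = focus_amplitude,
    focus_sigma = focus_sigma, min_focus_spacing = min_focus_spacing,
    coloc_fraction = coloc_fraction, coloc_offset_max = coloc_offset_max,
    decoy_min_distance = decoy_min_distance, noise_sigma = noise_sigma,
    background_level = background_level, light_background = light_background,
    bit_depth = as.integer(bit_depth), two_channels = isTRUE(two_channels),
    seed = as.integer(seed)), class = "fc_synth_spec")
}

draw_ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  # 0-based center (cx, cy); returns 1-based matrix indices inside the ellipse
  rr <- ceiling(max(a, b))
  r0 <- max(1L, floor(cy) - rr + 1L); r1 <- min(h, ceiling(cy) + rr + 1L)
  c0 <- max(1L, floor(cx) - rr + 1L); c1 <- min(w, ceiling(cx) + rr + 1L)
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows - 1 - cy, length(rows), length(cols))
  xx <- matrix(cols - 1 - cx, length(rows), length(cols), byrow = TRUE)
  u <- (xx * cos(theta) + yy * sin(theta)) / a
  v <- (-xx * sin(theta) + yy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  loc <- which(inside, arr.ind = TRUE)
  (cols[loc[, 2]] - 1L) * h + rows[loc[, 1]]
}

place_points_in_ellipse <- function(n, cx, cy, a, b, theta, min_spacing,
                                    margin = 0.88, avoid = NULL,
                                    avoid_dist = 0, max_tries = 400) {
  # rejection-sample integer positions inside the (shrunken) ellipse keeping
  # pairwise spacing; returns a matrix [n, 2] of (x, y), possibly fewer rows
  # if the packing saturates
  xs <- numeric(0); ys <- numeric(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r <- sqrt(stats::runif(1)) * margin
      phi <- stats::runif(1, 0, 2 * pi)
      ex <- r * cos(phi) * a; ey <- r * sin(phi) * b
      x <- round(cx + ex * cos(theta) - ey * sin(theta))
      y <- round(cy + ex * sin(theta) + ey * cos(theta))
      if (length(xs) && min((xs - x)^2 + (ys - y)^2) < min_spacing^2) next
      if (!is.null(avoid) && nrow(avoid) &&
          min((avoid[, 1] - x)^2 + (avoid[, 2] - y)^2) < avoid_dist^2) next
      xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
    }
    if (!placed) break
  }
  cbind(x = xs, y = ys)
}

add_gaussian_bump <- function(raster, x, y, amplitude, sigma) {
  h <- nrow(raster); w <- ncol(raster)
  rr <- ceiling(4 * sigma)
  r0 <- max(1L, y + 1L - rr); r1 <- min(h, y + 1L + rr)
  c0 <- max(1L, x + 1L - rr); c1 <- min(w, x + 1L + rr)
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - 1 - y, length(rows), length(cols))
  dx <- matrix(cols - 1 - x, length(rows), length(cols), byrow = TRUE)
  raster[rows, cols] <- raster[rows, cols] +
    amplitude * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  raster
}

#' Generate a synthetic multi-channel image with exact ground truth
#'
#' Deterministic given `spec$seed`. Channel 1 is the nuclear stain (ellipse
#' pedestals only); channel 2 (and 3, when `two_channels`) carries the
#' nuclear pedestal plus Gaussian foci. With `noise_sigma = 0` the raster
#' maximum equals `background + nucleus_intensity + focus_amplitude` exactly
#' at a focus center.
#'
#' @param spec an [fc_synth_spec()].
#' @return list with `image` (an [fc_image], roles `roi`/`foci1`(/`foci2`))
#'   and `truth` (list: `nuclei` tibble, `foci_1`, `foci_2` tibbles,
#'   `coloc_pairs` tibble, `labels` true nucleus label matrix).
#' @export
fc_generate_image <- function(spec) {
  stopifnot(inherits(spec, "fc_synth_spec"))
  withr::with_seed(spec$seed, fc_generate_image_impl(spec))
}

fc_generate_image_impl <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  amin <- spec$nucleus_axes_range[1]; amax <- spec$nucleus_axes_range[2]
  n <- spec$n_nuclei
  margin <- 3
  nuc <- list()
  boxes <- matrix(numeric(0), 0, 4) # x0, x1, y0, y1
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in 1:400) {
      a <- stats::runif(1, amin, amax); b <- stats::runif(1, amin, amax)
      theta <- stats::runif(1, 0, pi)
      rr <- max(a, b)
      cx <- stats::runif(1, rr + margin, w - 1 - rr - margin)
      cy <- stats::runif(1, rr + margin, h - 1 - rr - margin)
      box <- c(cx - rr - margin, cx + rr + margin, cy - rr - margin, cy + rr + margin)
      if (!spec$allow_touching && nrow(boxes)) {
        clash <- boxes[, 1] <= box[2] & boxes[, 2] >= box[1] &
                 boxes[, 3] <= box[4] & boxes[, 4] >= box[3]
        if (any(clash)) next
      }
      nuc[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
      boxes <- rbind(boxes, box)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generation error: could not place ", n, " non-touching nuclei in a ",
           h, "x", w, " frame", call. = FALSE)
  }

  labels <- matrix(0L, h, w)
  for (i in seq_along(nuc)) {
    px <- draw_ellipse_mask(h, w, nuc[[i]]$cx, nuc[[i]]$cy,
                            nuc[[i]]$a, nuc[[i]]$b, nuc[[i]]$theta)
    labels[px] <- i
  }
  pedestal <- matrix(0, h, w)
  pedestal[labels > 0L] <- spec$nucleus_intensity

  nper <- spec$foci_per_nucleus
  if (length(nper) == 1L) nper <- rep(nper, length(nuc))

  f1 <- list(); f2 <- list(); pairs <- list()
  for (i in seq_along(nuc)) {
    e <- nuc[[i]]
    p1 <- place_points_in_ellipse(nper[i], e$cx, e$cy, e$a, e$b, e$theta,
                                  spec$min_focus_spacing)
    if (nrow(p1))
      f1[[i]] <- tibble::tibble(x = as.integer(p1[, 1]), y = as.integer(p1[, 2]),
                                amplitude = spec$focus_amplitude, nucleus = i)
    if (spec$two_channels) {
      npart <- round(spec$coloc_fraction * nrow(p1))
      p2x <- integer(0); p2y <- integer(0)
      if (npart > 0) {
        # partners: integer offset within the coloc radius of their channel-1 focus
        offs <- expand.grid(dx = -floor(spec$coloc_offset_max):floor(spec$coloc_offset_max),
                            dy = -floor(spec$coloc_offset_max):floor(spec$coloc_offset_max))
        offs <- offs[offs$dx^2 + offs$dy^2 <= spec$coloc_offset_max^2, ]
        pick <- sample.int(nrow(offs), npart, replace = TRUE)
        p2x <- p1[seq_len(npart), 1] + offs$dx[pick]
        p2y <- p1[seq_len(npart), 2] + offs$dy[pick]
        pairs[[i]] <- tibble::tibble(nucleus = i, i1 = seq_len(npart),
                                     i2 = seq_len(npart))
      }
      ndecoy <- nrow(p1) - npart
      if (ndecoy > 0) {
        dec <- place_points_in_ellipse(
          ndecoy, e$cx, e$cy, e$a, e$b, e$theta, spec$min_focus_spacing,
          avoid = p1, avoid_dist = spec$decoy_min_distance)
        p2x <- c(p2x, dec[, 1]); p2y <- c(p2y, dec[, 2])
      }
      if (length(p2x))
        f2[[i]] <- tibble::tibble(x = as.integer(p2x), y = as.integer(p2y),
                                  amplitude = spec$focus_amplitude, nucleus = i)
    }
  }
  bind_or_empty <- function(l) if (length(l)) dplyr::bind_rows(l) else
    tibble::tibble(x = integer(), y = integer(), amplitude = numeric(),
                   nucleus = integer())
  foci_1 <- bind_or_empty(f1)
  foci_2 <- bind_or_empty(f2)

  ch_roi <- pedestal
  ch_f1 <- pedestal
  for (k in seq_len(nrow(foci_1)))
    ch_f1 <- add_gaussian_bump(ch_f1, foci_1$x[k], foci_1$y[k],
                               foci_1$amplitude[k], spec$focus_sigma)
  chans <- list(ch_roi, ch_f1)
  if (spec$two_channels) {
    ch_f2 <- pedestal
    for (k in seq_len(nrow(foci_2)))
      ch_f2 <- add_gaussian_bump(ch_f2, foci_2$x[k], foci_2$y[k],
                                 foci_2$amplitude[k], spec$focus_sigma)
    chans <- c(chans, list(ch_f2))
  }

  maxval <- 2^spec$bit_depth - 1
  chans <- lapply(chans, function(ch) {
    ch <- ch + spec$background_level
    if (spec$noise_sigma > 0)
      ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sigma)
    ch <- round(pmin(pmax(ch, 0), maxval))
    if (spec$light_background) ch <- maxval - ch
    matrix(as.integer(ch), nrow(ch), ncol(ch))
  })

  roles <- list(roi = 1L, foci1 = 2L)
  if (spec$two_channels) roles$foci2 <- 3L
  img <- fc_image(chans, bit_depth = spec$bit_depth, roles = roles,
                  source = sprintf("synthetic_seed%d", spec$seed))
  nuclei <- tibble::tibble(
    nucleus = seq_along(nuc),
    cx = vapply(nuc, `[[`, numeric(1), "cx"),
    cy = vapply(nuc, `[[`, numeric(1), "cy"),
    a = vapply(nuc, `[[`, numeric(1), "a"),
    b = vapply(nuc, `[[`, numeric(1), "b"),
    theta = vapply(nuc, `[[`, numeric(1), "theta"))
  list(image = img,
       truth = list(nuclei = nuclei, foci_1 = foci_1, foci_2 = foci_2,
                    coloc_pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
                      tibble::tibble(nucleus = integer(), i1 = integer(),
                                     i2 = integer()),
                    labels = labels))
}

#' Generate a radiation dose series with known foci rates
#'
#' Emulates dose-response experiments where the mean foci count per nucleus
#' scales linearly with absorbed dose (published induction rates are in the
#' range of 15-19 foci per nucleus per Gray). Per dose, each nucleus' focus
#' count is drawn from a Poisson distribution with mean
#' `foci_per_gy * dose`; the counts actually planted are recorded in the
#' ground truth.
#'
#' @param doses numeric vector of doses in Gray (non-negative).
#' @param foci_per_gy induction rate (foci per nucleus per Gy).
#' @param base_spec an [fc_synth_spec()] providing geometry and intensities.
#' @param seed series seed; per-dose seeds are derived from it.
#' @return list (one element per dose) of lists with `dose`, `image`,
#'   `truth`.
#' @export
fc_dose_series <- function(doses, foci_per_gy, base_spec = fc_synth_spec(),
                           seed = base_spec$seed) {
  stopifnot(all(doses >= 0))
  out <- vector("list", length(doses))
  for (di in seq_along(doses)) {
    spec <- base_spec
    spec$seed <- (seed * 1009L + di * 7919L) %% 2147483647L
    counts <- withr::with_seed(spec$seed * 2L + 1L,
      stats::rpois(spec$n_nuclei, foci_per_gy * doses[di]))
    spec$foci_per_nucleus <- counts
    g <- fc_generate_image(spec)
    out[[di]] <- list(dose = doses[di], image = g$image, truth = g$truth)
  }
  out
}

#' Write a synthetic image and its ground truth to disk
#'
#' Writes the channels as one multi-page 16-bit TIFF and the ground truth as
#' CSV files (`<stem>_nuclei.csv`, `<stem>_foci1.csv`, `<stem>_foci2.csv`).
#'
#' @param gen result of [fc_generate_image()].
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisible character vector of written paths.
#' @export
fc_write_synthetic <- function(gen, dir, stem = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tifp <- file.path(dir, paste0(stem, ".tif"))
  fc_write_image(gen$image, tifp)
  np <- file.path(dir, paste0(stem, "_nuclei.csv"))
  readr::write_csv(gen$truth$nuclei, np)
  f1p <- file.path(dir, paste0(stem, "_foci1.csv"))
  readr::write_csv(gen$truth$foci_1, f1p)
  paths <- c(tifp, np, f1p)
  if (nrow(gen$truth$foci_2)) {
    f2p <- file.path(dir, paste0(stem, "_foci2.csv"))
    readr::write_csv(gen$truth$foci_2, f2p)
    paths <- c(paths, f2p)
  }
  invisible(paths)
}
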