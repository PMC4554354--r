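#' Segmentation parameters
#'
#' Mirrors the ROI-selection options of interactive foci-counting tools:
#' intensity threshold (manual or automatic), hole filling, watershed
#' separation of touching nuclei, and size / circularity / edge filters.
#'
#' @param threshold_mode `"manual"` or `"auto"`.
#' @param manual_threshold intensity in raster units (required in manual
#'   mode). Foreground is every pixel with value `>= threshold`.
#' @param auto_method automatic threshold algorithm, `"isodata"` (iterative
#'   intermeans, the default) or `"otsu"`.
#' @param min_area,max_area object area bounds in pixels^2 (`max_area = Inf`
#'   for unbounded).
#' @param min_circularity,max_circularity bounds on the shape descriptor
#'   `4*pi*area/perimeter^2`, both in `[0, 1]`.
#' @param exclude_edge drop objects with any pixel on the outermost image
#'   rows/columns (objects partially outside the frame).
#' @param fill_holes fill enclosed background holes after thresholding.
#' @param watershed split touching objects along distance-transform necks.
#' @return list of class `fc_seg_params`.
#' @export
fc_seg_params <- function(threshold_mode = c("auto", "manual"),
                          manual_threshold = NULL,
                          auto_method = c("isodata", "otsu"),
                          min_area = 50, max_area = Inf,
                          min_circularity = 0, max_circularity = 1,
                          exclude_edge = TRUE, fill_holes = TRUE,
                          watershed = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  auto_method <- match.arg(auto_method)
  if (min_circularity < 0 || max_circularity > 1 || min_circularity > max_circularity)
    stop("configuration error: need 0 <= min_circularity <= max_circularity <= 1",
         call. = FALSE)
  if (min_area <= 0) stop("configuration error: min_area must be > 0", call. = FALSE)
  if (max_area < min_area)
    stop("configuration error: max_area must be >= min_area", call. = FALSE)
  if (threshold_mode == "manual" && is.null(manual_threshold))
    stop("configuration error: manual threshold mode needs `manual_threshold`",
         call. = FALSE)
  structure(list(threshold_mode = threshold_mode,
                 manual_threshold = manual_threshold,
                 auto_method = auto_method,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 max_circularity = max_circularity,
                 exclude_edge = isTRUE(exclude_edge),
                 fill_holes = isTRUE(fill_holes),
                 watershed = isTRUE(watershed)),
            class = "fc_seg_params")
}

#' Iterative intermeans (isodata) automatic threshold
#'
#' Classic histogram recursion: starting from the global mean, the threshold
#' is repeatedly replaced by the average of the mean intensity below and the
#' mean intensity above it until it stabilizes.
#'
#' @param raster integer matrix.
#' @return numeric threshold in raster units (foreground is `>=` it).
#' @export
fc_isodata_threshold <- function(raster) {
  v <- as.numeric(raster)
  if (min(v) == max(v))
    stop("degenerate-image error: constant raster, no separable histogram",
         call. = FALSE)
  t_old <- -Inf
  t <- mean(v)
  for (i in 1:200) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(hi) || !length(lo)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 0.5) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Threshold a raster into a foreground mask
#'
#' Foreground is every pixel with value `>=` the threshold (so a manual
#' threshold exactly at an object's intensity keeps the object). In auto mode
#' the threshold is computed from the raster histogram by the configured
#' method and returned in the `"threshold"` attribute of the mask, so the
#' chosen value can be logged and echoed into result metadata.
#'
#' @param raster integer matrix.
#' @param params an [fc_seg_params()].
#' @param bit_depth raster bit depth (used by the Otsu method's histogram).
#' @return logical matrix with attribute `threshold`.
#' @export
fc_threshold <- function(raster, params = fc_seg_params(), bit_depth = 16L) {
  if (params$threshold_mode == "manual") {
    t <- params$manual_threshold
    if (t < 0 || t > 2^bit_depth - 1)
      stop("configuration error: manual_threshold outside the raster value range",
         call. = FALSE)
  } else if (params$auto_method == "isodata") {
    t <- fc_isodata_threshold(raster)
  } else {
    if (min(raster) == max(raster))
      stop("degenerate-image error: constant raster, no separable histogram",
           call. = FALSE)
    maxval <- 2^bit_depth - 1
    t <- EBImage::otsu(EBImage::Image(raster / maxval),
                       range = c(0, 1), levels = 2^bit_depth) * maxval
  }
  if (params$threshold_mode == "auto") {
    # bimodality guard: a pure-noise (blank) raster converges to a threshold
    # that splits one mode in half, with an intermeans distance near the
    # unimodal-Gaussian value of 1.6 total SDs; real stained images separate
    # by far more
    v <- as.numeric(raster)
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi) ||
        (mean(hi) - mean(lo)) / stats::sd(v) < 1.8)
      stop("degenerate-image error: no separable foreground/background ",
           "histogram (blank image?)", call. = FALSE)
  }
  mask <- raster >= t
  attr(mask, "threshold") <- t
  mask
}

#' Fill enclosed holes in a binary mask
#'
#' Every background region not connected to the image border becomes
#' foreground; foreground pixels are never removed, so the output is a
#' superset of the input and the operation is idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fc_fill_holes <- function(mask) {
  out <- EBImage::imageData(EBImage::fillHull(matrix(as.integer(mask), nrow(mask)))) > 0
  attributes(out) <- attributes(out)["dim"]
  out | mask
}

#' 8-connected component labeling
#'
#' Foreground labeling with the 8-connectivity convention of particle
#' analysis. Labels are renumbered 1..n in column-major first-occurrence
#' order so the result is deterministic.
#'
#' @param mask logical matrix.
#' @return integer label matrix (0 = background).
#' @export
fc_label <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.integer(mask), nrow(mask))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # bwlabel is 4-connected; union labels that touch diagonally
    a <- lab[-nr, -nc]; b <- lab[-1, -1]
    cc <- lab[-nr, -1]; d <- lab[-1, -nc]
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(cc), as.vector(d)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find_root <- function(x) {
        while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
        x
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[k, 1]); rb <- find_root(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find_root, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  renumber_labels(lab)
}

renumber_labels <- function(lab) {
  ids <- unique(as.vector(lab))
  ids <- ids[ids != 0]
  if (!length(ids)) return(lab)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  storage.mode(lab) <- "integer"
  lab
}

#' Split touching objects by a distance-transform watershed
#'
#' Seeds are prominence-filtered local maxima of the Euclidean distance
#' transform; seeds closer than `min_seed_sep` pixels are merged (the deeper
#' one survives). A connected component is split only when it holds at least
#' two seeds, so isolated convex objects are never fragmented. Every
#' foreground pixel receives exactly one label.
#'
#' @param mask logical matrix.
#' @param min_seed_sep minimum seed separation in pixels.
#' @param seed_prominence minimum distance-transform prominence of a seed.
#' @return integer label matrix (0 = background).
#' @export
fc_watershed_split <- function(mask, min_seed_sep = 4, seed_prominence = 2) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  comp <- fc_label(mask)
  dm <- EBImage::imageData(EBImage::distmap(matrix(as.integer(mask), nrow(mask))))
  peaks <- fc_find_maxima(dm, pixels = which(mask), noise_level = seed_prominence)
  if (nrow(peaks) == 0L) return(comp)
  peaks$row <- peaks$y + 1L
  peaks$col <- peaks$x + 1L
  peaks$comp <- comp[cbind(peaks$row, peaks$col)]
  # suppress seeds closer than min_seed_sep within a component: keep deeper
  peaks <- peaks[order(-peaks$peak_intensity, peaks$x, peaks$y), ]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i] || i == nrow(peaks)) next
    j <- (i + 1):nrow(peaks)
    d2 <- (peaks$x[j] - peaks$x[i])^2 + (peaks$y[j] - peaks$y[i])^2
    keep[j[peaks$comp[j] == peaks$comp[i] & d2 < min_seed_sep^2]] <- FALSE
  }
  peaks <- peaks[keep, ]
  multi <- as.integer(names(which(table(peaks$comp) >= 2)))
  if (!length(multi)) return(comp)
  # seed map: individual seeds inside multi-seed components, whole component
  # elsewhere (so single-seed components pass through unsplit)
  seeds <- comp
  seeds[comp %in% multi] <- 0L
  nseed <- max(comp)
  pm <- peaks[peaks$comp %in% multi, ]
  seeds[cbind(pm$row, pm$col)] <- nseed + seq_len(nrow(pm))
  ws <- EBImage::imageData(EBImage::propagate(dm, seeds, mask = mask))
  storage.mode(ws) <- "integer"
  renumber_labels(ws)
}

#' Shape circularity
#'
#' `4 * pi * area / perimeter^2`, capped at 1 because rasterization can push
#' the raw ratio above 1 for small objects. 1 for an ideal circle, `pi/4` for
#' an ideal square, approaching 0 for elongated shapes.
#'
#' @param area object area (pixels^2).
#' @param perimeter object perimeter (pixels); must be positive.
#' @return circularity in `[0, 1]`.
#' @export
fc_circularity <- function(area, perimeter) {
  if (any(perimeter <= 0))
    stop("computation error: perimeter must be positive", call. = FALSE)
  pmin(1, 4 * pi * area / perimeter^2)
}

# Corrected boundary-walk perimeter of the outer contour of one object.
# Moore-neighbor tracing yields the Freeman chain code; the length uses the
# Vossepoel-Smeulders corrected weights (0.980 per straight move, 1.406 per
# diagonal move, -0.091 per corner), which track the true contour length of
# smooth shapes far better than raw pixel-edge counting.
perimeter_chain <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(4 * 0.980 - 4 * 0.091) # unit square contour, corrected
  r0 <- min(rows) - 2L; c0 <- min(cols) - 2L
  h <- max(rows) - r0 + 2L; w <- max(cols) - c0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(rows - r0, cols - c0)] <- TRUE
  # clockwise Moore neighborhood starting east, in (dr, dc) screen coordinates
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  # start: first foreground pixel in column-major order; its west neighbor is
  # background, so begin the clockwise search from the west (direction 5)
  start <- which(m)[1]
  sr <- ((start - 1L) %% h) + 1L; sc <- ((start - 1L) %/% h) + 1L
  scan_from <- function(cr, cc, s0) {
    # first foreground neighbor clockwise from search-start index s0
    for (k in 0:7) {
      d <- (s0 + k) %% 8L
      if (m[cr + dr[d + 1L], cc + dc[d + 1L]]) return(d)
    }
    -1L
  }
  # start pixel is the column-major-first foreground pixel: its whole west
  # column and its north neighbor are background, so search clockwise from NW
  d0 <- scan_from(sr, sc, 5L)
  if (d0 < 0L) return(4 * 0.980 - 4 * 0.091)
  chain <- integer(8L * n + 8L)
  chain[1] <- d0
  nmoves <- 1L
  cr <- sr + dr[d0 + 1L]; cc <- sc + dc[d0 + 1L]
  dprev <- d0
  while (nmoves <= 8L * n) {
    # classic Moore tracing: resume the clockwise scan two steps back from
    # the last move direction so the contour stays hugged
    d <- scan_from(cr, cc, (dprev + 6L) %% 8L)
    if (cr == sr && cc == sc && d == d0) break # Jacob's stopping criterion
    nmoves <- nmoves + 1L
    chain[nmoves] <- d
    cr <- cr + dr[d + 1L]; cc <- cc + dc[d + 1L]
    dprev <- d
  }
  chain <- chain[seq_len(nmoves)]
  ne <- sum(chain %% 2L == 0L)
  no <- sum(chain %% 2L == 1L)
  ncorner <- sum(chain != c(chain[-1], chain[1]))
  max(0.980 * ne + 1.406 * no - 0.091 * ncorner, 1e-6)
}

#' Extract filtered ROIs from a label map
#'
#' Computes area, corrected boundary-walk perimeter, circularity, centroid
#' and border contact for every label, applies the size, circularity and
#' edge filters, and renumbers survivors 1..n in ascending original-label
#' order. The per-filter drop counts are attached as the `"dropped"`
#' attribute.
#'
#' @param labels integer label matrix.
#' @param params an [fc_seg_params()].
#' @return tibble with columns `roi_id`, `area`, `perimeter`, `circularity`,
#'   `x`, `y` (0-based centroid), `touches_border`, and `pixels` (list-column
#'   of 1-based matrix indices).
#' @export
fc_extract_rois <- function(labels, params = fc_seg_params()) {
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0L)
  empty <- tibble::tibble(
    roi_id = integer(), area = numeric(), perimeter = numeric(),
    circularity = numeric(), x = numeric(), y = numeric(),
    touches_border = logical(), pixels = list())
  drops <- c(size = 0L, circularity = 0L, edge = 0L)
  if (!length(idx)) {
    attr(empty, "dropped") <- drops
    attr(empty, "raster_dim") <- c(nr, nc)
    return(empty)
  }
  l <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  n <- max(l)
  area <- tabulate(l, nbins = n)
  cx <- rowsum(cols - 1.0, l)[, 1] / area # 0-based x
  cy <- rowsum(rows - 1.0, l)[, 1] / area
  border <- rowsum(as.numeric(rows == 1L | rows == nr | cols == 1L | cols == nc),
                   l)[, 1] > 0
  pix <- split(idx, l)
  rr <- split(rows, l)
  cs <- split(cols, l)
  perim <- vapply(seq_len(n), function(k) perimeter_chain(rr[[k]], cs[[k]]),
                  numeric(1))
  circ <- fc_circularity(area, perim)
  ok_size <- area >= params$min_area & area <= params$max_area
  ok_circ <- circ >= params$min_circularity & circ <= params$max_circularity
  ok_edge <- !(params$exclude_edge & border)
  drops["size"] <- sum(!ok_size)
  drops["circularity"] <- sum(ok_size & !ok_circ)
  drops["edge"] <- sum(ok_size & ok_circ & !ok_edge)
  keep <- which(ok_size & ok_circ & ok_edge)
  out <- tibble::tibble(
    roi_id = seq_along(keep),
    area = as.numeric(area[keep]),
    perimeter = perim[keep],
    circularity = circ[keep],
    x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
    touches_border = as.logical(border[keep]),
    pixels = unname(pix[as.character(keep)]))
  attr(out, "dropped") <- drops
  attr(out, "raster_dim") <- c(nr, nc)
  out
}

#' Segment nuclei from the ROI channel of an image
#'
#' Runs the full ROI-selection chain: threshold (manual or automatic), hole
#' filling, connected-component labeling with optional watershed separation,
#' then size / circularity / edge filtering.
#'
#' @param img an [fc_image].
#' @param params an [fc_seg_params()].
#' @return ROI tibble as from [fc_extract_rois()], with attributes
#'   `threshold` (value applied, raster units), `dropped` (per-filter drop
#'   counts) and `raster_dim`.
#' @export
fc_segment <- function(img, params = fc_seg_params()) {
  stopifnot(inherits(img, "fc_image"))
  raster <- fc_channel(img, "roi")
  mask <- fc_threshold(raster, params, bit_depth = img$bit_depth)
  thr <- attr(mask, "threshold")
  if (params$fill_holes) mask <- fc_fill_holes(mask)
  labels <- if (params$watershed) fc_watershed_split(mask) else fc_label(mask)
  rois <- fc_extract_rois(labels, params)
  attr(rois, "threshold") <- thr
  attr(rois, "source") <- img$source
  rois
}
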