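#' Foci-detection parameters
#'
#' @param noise_level_1 prominence tolerance (raster units) for foci channel
#'   1: a local maximum only counts as a focus if it rises at least this far
#'   above the region merging it with brighter signal. Suppresses
#'   background-noise maxima.
#' @param noise_level_2 tolerance for foci channel 2 (only with a `foci2`
#'   channel assigned).
#' @param cutoff_1,cutoff_2 optional absolute intensity floors; detected foci
#'   with peak intensity below the cutoff are deleted (a focus exactly at the
#'   cutoff survives).
#' @return list of class `fc_foci_params`.
#' @export
fc_foci_params <- function(noise_level_1 = 100, noise_level_2 = NULL,
                           cutoff_1 = NULL, cutoff_2 = NULL) {
  chk <- function(v, nm) {
    if (!is.null(v) && v < 0)
      stop("configuration error: ", nm, " must be >= 0", call. = FALSE)
    v
  }
  structure(list(noise_level_1 = chk(noise_level_1, "noise_level_1"),
                 noise_level_2 = chk(noise_level_2, "noise_level_2"),
                 cutoff_1 = chk(cutoff_1, "cutoff_1"),
                 cutoff_2 = chk(cutoff_2, "cutoff_2")),
            class = "fc_foci_params")
}

#' Prominence-based local-maxima detection within a pixel set
#'
#' Finds intensity peaks the way interactive "find maxima" tools do: a local
#' maximum `m` (8-connected neighborhood) is accepted if and only if the
#' connected region reachable from `m` through pixels of value
#' `> value(m) - noise_level`, restricted to the pixel set, contains no pixel
#' strictly brighter than `m`. A dimmer maximum whose flood region reaches
#' brighter signal is merged away; within such a merged group only the
#' brightest representative survives. Pixels outside the set behave as
#' `-Inf`: signal outside a nucleus can neither create nor suppress a focus
#' inside it.
#'
#' A plateau of equal-valued maximal pixels yields a single focus at the
#' plateau pixel nearest its centroid (ties broken by ascending `(x, y)`).
#'
#' @param raster numeric or integer matrix.
#' @param pixels integer vector of 1-based matrix indices delimiting the
#'   search region (e.g. one nucleus' pixel set).
#' @param noise_level prominence tolerance in raster units, `>= 0`.
#' @return tibble with columns `x`, `y` (0-based pixel coordinates) and
#'   `peak_intensity`, ordered by decreasing peak then ascending `(x, y)`.
#' @export
fc_find_maxima <- function(raster, pixels, noise_level) {
  stopifnot(noise_level >= 0)
  empty <- tibble::tibble(x = integer(), y = integer(), peak_intensity = numeric())
  if (!length(pixels)) return(empty)
  nr <- nrow(raster); nc <- ncol(raster)
  nrp <- nr + 2L
  ncp <- nc + 2L
  z <- matrix(-Inf, nrp, ncp)
  prow <- ((pixels - 1L) %% nr) + 1L
  pcol <- ((pixels - 1L) %/% nr) + 1L
  pidx <- pcol * nrp + prow + 1L # padded linear index of (prow+1, pcol+1)
  z[pidx] <- as.numeric(raster[pixels])
  offs <- c(-1L, 1L, -nrp, nrp, -nrp - 1L, -nrp + 1L, nrp - 1L, nrp + 1L)
  vals <- z[pidx]
  ismax <- rep(TRUE, length(pidx))
  for (o in offs) ismax <- ismax & vals >= z[pidx + o]
  cand <- pidx[ismax]
  if (!length(cand)) return(empty)

  # group each candidate's full equal-valued plateau (connected component of
  # pixels at the candidate's value, within the ROI); a plateau may contain
  # non-candidate pixels whose neighbors are brighter — the tolerance flood
  # below then discovers that brighter signal and rejects the plateau
  plateau <- integer(nrp * ncp)
  groups <- list()
  g <- 0L
  for (p0 in cand) {
    if (plateau[p0]) next
    g <- g + 1L
    v0 <- z[p0]
    members <- p0
    plateau[p0] <- g
    has_lower <- FALSE
    qi <- 1L
    while (qi <= length(members)) {
      nb <- members[qi] + offs
      zn <- z[nb]
      if (!has_lower && any(is.finite(zn) & zn < v0)) has_lower <- TRUE
      sel <- nb[zn == v0 & plateau[nb] == 0L]
      if (length(sel)) {
        plateau[sel] <- g
        members <- c(members, sel)
      }
      qi <- qi + 1L
    }
    # a plateau with no strictly lower in-ROI neighbor (a constant component)
    # is no peak at all
    if (has_lower) groups[[length(groups) + 1L]] <- members
  }
  if (!length(groups)) return(empty)

  gvals <- vapply(groups, function(gr) z[gr[1]], numeric(1))
  gmin <- vapply(groups, min, numeric(1))
  ord <- order(-gvals, gmin)

  visited <- integer(nrp * ncp)
  queue <- integer(length(pixels))
  res_x <- integer(0); res_y <- integer(0); res_v <- numeric(0)
  for (k in ord) {
    members <- groups[[k]]
    v <- gvals[k]
    thr <- v - noise_level
    qn <- length(members)
    queue[seq_len(qn)] <- members
    visited[members] <- k
    i <- 1L
    accepted <- TRUE
    while (i <= qn) {
      nb <- queue[i] + offs
      nv <- z[nb]
      if (any(nv > v)) { accepted <- FALSE; break }
      sel <- nb[nv > thr & visited[nb] != k]
      ns <- length(sel)
      if (ns) {
        visited[sel] <- k
        queue[(qn + 1L):(qn + ns)] <- sel
        qn <- qn + ns
      }
      i <- i + 1L
    }
    if (accepted) {
      mr <- ((members - 1L) %% nrp) # padded row - 1 = original row
      mc <- ((members - 1L) %/% nrp) # padded col - 1 = original col
      px <- mc - 1L # 0-based x
      py <- mr - 1L # 0-based y
      d2 <- (px - mean(px))^2 + (py - mean(py))^2
      sel <- order(d2, px, py)[1]
      res_x <- c(res_x, px[sel]); res_y <- c(res_y, py[sel]); res_v <- c(res_v, v)
    }
  }
  out <- tibble::tibble(x = res_x, y = res_y, peak_intensity = res_v)
  out[order(-out$peak_intensity, out$x, out$y), ]
}

#' Delete foci below an intensity cutoff
#'
#' Retains exactly the foci with `peak_intensity >= cutoff`, preserving
#' order.
#'
#' @param foci tibble with a `peak_intensity` column.
#' @param cutoff intensity floor; `NULL` or 0 keeps everything.
#' @return filtered tibble.
#' @export
fc_apply_cutoff <- function(foci, cutoff) {
  if (is.null(cutoff)) return(foci)
  foci[foci$peak_intensity >= cutoff, ]
}

#' Detect foci in every ROI and active foci channel
#'
#' Runs [fc_find_maxima()] per ROI on each assigned foci channel with that
#' channel's noise level, then applies the channel's cutoff. Raw rasters are
#' never modified; detection outside ROI pixels never occurs.
#'
#' @param img an [fc_image].
#' @param rois ROI tibble from [fc_segment()] / [fc_extract_rois()].
#' @param params an [fc_foci_params()].
#' @return tibble with columns `image`, `roi_id`, `channel` (`"foci1"` /
#'   `"foci2"`), `x`, `y`, `peak_intensity`.
#' @export
fc_detect_foci <- function(img, rois, params = fc_foci_params()) {
  stopifnot(inherits(img, "fc_image"))
  has2 <- !is.null(img$roles$foci2)
  if (!has2 && (!is.null(params$noise_level_2) || !is.null(params$cutoff_2)))
    stop("configuration error: foci2 parameters set but no foci2 channel assigned",
         call. = FALSE)
  chans <- list(foci1 = list(raster = fc_channel(img, "foci1"),
                             noise = params$noise_level_1,
                             cutoff = params$cutoff_1))
  if (has2) {
    chans$foci2 <- list(raster = fc_channel(img, "foci2"),
                        noise = params$noise_level_2 %||% params$noise_level_1,
                        cutoff = params$cutoff_2)
  }
  res <- list()
  for (ch in names(chans)) {
    cc <- chans[[ch]]
    for (i in seq_len(nrow(rois))) {
      f <- fc_find_maxima(cc$raster, rois$pixels[[i]], cc$noise)
      f <- fc_apply_cutoff(f, cc$cutoff)
      if (nrow(f)) {
        f$roi_id <- rois$roi_id[i]
        f$channel <- ch
        res[[length(res) + 1L]] <- f
      }
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(x = integer(), y = integer(), peak_intensity = numeric(),
                   roi_id = integer(), channel = character())
  out$image <- img$source
  out[, c("image", "roi_id", "channel", "x", "y", "peak_intensity")]
}
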