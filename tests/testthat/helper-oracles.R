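# Independent oracles used across the suite. These are deliberately naive
# (matrix-dilation floods, exhaustive enumeration, closed-form geometry) and
# share no code with the implementation they check.

shift_pad <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate8 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_pad(mask, dr, dc, fill = FALSE)
  }
  out
}

# Brute-force prominence maxima: for every local-maximum plateau, flood-fill
# the region reachable through pixels > (peak - tolerance) by repeated
# dilation and accept the plateau iff no strictly brighter pixel lies in it.
oracle_find_maxima <- function(raster, pixels, noise_level) {
  nr <- nrow(raster); nc <- ncol(raster)
  z <- matrix(-Inf, nr, nc)
  z[pixels] <- as.numeric(raster[pixels])
  nbmax <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbmax <- pmax(nbmax, shift_pad(z, dr, dc))
  }
  cand <- which(is.finite(z) & z >= nbmax)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (p in cand) {
    if (seen[p]) next
    v <- z[p]
    plat <- matrix(FALSE, nr, nc); plat[p] <- TRUE
    eq <- z == v
    repeat { g <- dilate8(plat) & eq; if (identical(g, plat)) break; plat <- g }
    seen[plat] <- TRUE
    nbv <- z[dilate8(plat) & !plat]
    if (!any(is.finite(nbv) & nbv < v)) next # constant component: no peak
    allowed <- z > (v - noise_level)
    reach <- plat
    repeat { g <- (dilate8(reach) & allowed) | plat
             if (identical(g, reach)) break; reach <- g }
    if (max(z[reach]) <= v) {
      pr <- which(plat, arr.ind = TRUE)
      px <- pr[, 2] - 1L; py <- pr[, 1] - 1L
      d2 <- (px - mean(px))^2 + (py - mean(py))^2
      k <- order(d2, px, py)[1]
      out[[length(out) + 1L]] <- c(x = px[k], y = py[k], peak = v)
    }
  }
  if (!length(out)) return(data.frame(x = integer(), y = integer(), peak = numeric()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$x, df$y), ]
}

# Exhaustive maximum-cardinality matching between two small point sets under
# a distance tolerance (recursion over channel-1 foci).
oracle_max_matching <- function(f1, f2, tol) {
  n1 <- nrow(f1); n2 <- nrow(f2)
  if (!n1 || !n2) return(0L)
  d <- outer(seq_len(n1), seq_len(n2), function(i, j)
    sqrt((f1$x[i] - f2$x[j])^2 + (f1$y[i] - f2$y[j])^2))
  best <- 0L
  rec <- function(i, used2, count) {
    if (count + (n1 - i + 1L) <= best) return()
    if (i > n1) { best <<- max(best, count); return() }
    for (j in seq_len(n2)) {
      if (!used2[j] && d[i, j] <= tol) {
        used2[j] <- TRUE
        rec(i + 1L, used2, count + 1L)
        used2[j] <- FALSE
      }
    }
    rec(i + 1L, used2, count)
  }
  rec(1L, logical(n2), 0L)
  best
}

# Convex-shape perimeter oracle: boundary pixels ordered by angle around the
# centroid, summed Euclidean steps (valid for convex rasterized shapes).
oracle_perimeter_convex <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  on4 <- !(shift_pad(mask, 1, 0, FALSE) & shift_pad(mask, -1, 0, FALSE) &
             shift_pad(mask, 0, 1, FALSE) & shift_pad(mask, 0, -1, FALSE))
  b <- which(mask & on4, arr.ind = TRUE)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  ang <- atan2(b[, 1] - cy, b[, 2] - cx)
  b <- b[order(ang), , drop = FALSE]
  nxt <- rbind(b[-1, , drop = FALSE], b[1, , drop = FALSE])
  sum(sqrt(rowSums((b - nxt)^2)))
}

# fixtures -------------------------------------------------------------------

disk_mask <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  g <- expand.grid(i = 1:n, j = 1:n)
  matrix((g$i - r - pad - 1)^2 + (g$j - r - pad - 1)^2 <= r^2, n, n)
}

random_raster <- function(seed, n = 32, maxv = 60) {
  withr::with_seed(seed, matrix(sample.int(maxv, n * n, replace = TRUE), n, n))
}

default_params <- function(min_area = 100, noise = 100, ...) {
  fc_params(seg = fc_seg_params(min_area = min_area),
            foci = fc_foci_params(noise_level_1 = noise), ...)
}
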