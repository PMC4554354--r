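#' Colocalization parameters
#'
#' @param tolerance maximum Euclidean distance in pixels between two foci
#'   peaks (one per channel) for them to count as colocalized, `>= 0`.
#' @param enabled run colocalization at all (requires a `foci2` channel).
#' @param export_pairs include the per-pair listing in exports.
#' @return list of class `fc_coloc_params`.
#' @export
fc_coloc_params <- function(tolerance = 2, enabled = TRUE, export_pairs = FALSE) {
  if (tolerance < 0)
    stop("configuration error: coloc tolerance must be >= 0", call. = FALSE)
  structure(list(tolerance = tolerance, enabled = isTRUE(enabled),
                 export_pairs = isTRUE(export_pairs)),
            class = "fc_coloc_params")
}

#' Match foci across two channels within one ROI
#'
#' Builds a one-to-one matching greedily in ascending pair-distance order
#' among all channel-1 x channel-2 pairs with Euclidean peak distance
#' `<= tolerance` (ties broken by ascending `(x1, y1, x2, y2)`), then lifts
#' the result to a maximum-cardinality matching by alternating-path
#' augmentation — plain distance-greedy can strand a matchable focus behind
#' an already-taken partner, undercounting colocalization. The procedure is
#' fully deterministic. Each focus appears in at most one pair; percentages
#' are per channel (`100 * n_colocalized / n_foci_c`), defined as 0 for a
#' channel without foci.
#'
#' @param foci1,foci2 tibbles with `x`, `y` columns (same ROI).
#' @param params an [fc_coloc_params()].
#' @return list with `n_foci_1`, `n_foci_2`, `n_colocalized`,
#'   `pct_colocalized_1`, `pct_colocalized_2` and a `pairs` tibble
#'   (`i1`, `i2`, row indices into the inputs, and `distance`).
#' @export
fc_match_foci <- function(foci1, foci2, params = fc_coloc_params()) {
  n1 <- nrow(foci1); n2 <- nrow(foci2)
  pairs <- tibble::tibble(i1 = integer(), i2 = integer(), distance = numeric())
  if (n1 && n2) {
    d <- outer(seq_len(n1), seq_len(n2), function(i, j)
      sqrt((foci1$x[i] - foci2$x[j])^2 + (foci1$y[i] - foci2$y[j])^2))
    ok <- which(d <= params$tolerance, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- tibble::tibble(i1 = ok[, 1], i2 = ok[, 2],
                             distance = d[ok])
      cand <- cand[order(cand$distance,
                         foci1$x[cand$i1], foci1$y[cand$i1],
                         foci2$x[cand$i2], foci2$y[cand$i2]), ]
      match1 <- rep(NA_integer_, n1) # i -> j
      match2 <- rep(NA_integer_, n2) # j -> i
      for (k in seq_len(nrow(cand))) {
        if (is.na(match1[cand$i1[k]]) && is.na(match2[cand$i2[k]])) {
          match1[cand$i1[k]] <- cand$i2[k]
          match2[cand$i2[k]] <- cand$i1[k]
        }
      }
      # the distance-greedy base can strand a matchable focus behind an
      # already-taken partner; alternating-path augmentation lifts it to a
      # maximum-cardinality matching while keeping determinism (adjacency is
      # scanned in ascending pair-distance order)
      adj <- split(cand$i2, cand$i1)
      env <- new.env()
      env$match1 <- match1; env$match2 <- match2
      augment <- function(i) {
        for (j in adj[[as.character(i)]]) {
          if (env$visited[j]) next
          env$visited[j] <- TRUE
          if (is.na(env$match2[j]) || augment(env$match2[j])) {
            env$match1[i] <- j
            env$match2[j] <- i
            return(TRUE)
          }
        }
        FALSE
      }
      for (i in which(is.na(env$match1))) {
        if (!is.null(adj[[as.character(i)]])) {
          env$visited <- logical(n2)
          augment(i)
        }
      }
      got <- which(!is.na(env$match1))
      pairs <- tibble::tibble(i1 = got, i2 = env$match1[got],
                              distance = d[cbind(got, env$match1[got])])
      pairs <- pairs[order(pairs$distance, pairs$i1), ]
    }
  }
  nco <- nrow(pairs)
  list(n_foci_1 = n1, n_foci_2 = n2, n_colocalized = nco,
       pct_colocalized_1 = if (n1) 100 * nco / n1 else 0,
       pct_colocalized_2 = if (n2) 100 * nco / n2 else 0,
       pairs = pairs)
}

#' Per-ROI colocalization table for one image
#'
#' Runs [fc_match_foci()] on the post-cutoff foci of every ROI.
#'
#' @param foci per-focus tibble from [fc_detect_foci()] (both channels).
#' @param rois ROI tibble (defines the ROI set, including foci-free ROIs).
#' @param params an [fc_coloc_params()].
#' @return list with `per_roi` tibble (one row per ROI) and `pairs` tibble
#'   (per matched pair, with ROI id and both positions).
#' @export
fc_colocalize <- function(foci, rois, params = fc_coloc_params()) {
  rows <- list(); prs <- list()
  for (i in seq_len(nrow(rois))) {
    id <- rois$roi_id[i]
    f1 <- foci[foci$roi_id == id & foci$channel == "foci1", ]
    f2 <- foci[foci$roi_id == id & foci$channel == "foci2", ]
    m <- fc_match_foci(f1, f2, params)
    rows[[i]] <- tibble::tibble(
      roi_id = id, n_foci_1 = m$n_foci_1, n_foci_2 = m$n_foci_2,
      n_colocalized = m$n_colocalized,
      pct_colocalized_1 = m$pct_colocalized_1,
      pct_colocalized_2 = m$pct_colocalized_2)
    if (nrow(m$pairs)) {
      prs[[length(prs) + 1L]] <- tibble::tibble(
        roi_id = id,
        x1 = f1$x[m$pairs$i1], y1 = f1$y[m$pairs$i1],
        x2 = f2$x[m$pairs$i2], y2 = f2$y[m$pairs$i2],
        distance = m$pairs$distance)
    }
  }
  list(per_roi = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(roi_id = integer(), n_foci_1 = integer(),
                        n_foci_2 = integer(), n_colocalized = integer(),
                        pct_colocalized_1 = numeric(), pct_colocalized_2 = numeric()),
       pairs = if (length(prs)) dplyr::bind_rows(prs) else
         tibble::tibble(roi_id = integer(), x1 = integer(), y1 = integer(),
                        x2 = integer(), y2 = integer(), distance = numeric()))
}

#' Pool per-ROI colocalization results to image level
#'
#' Percentages are recomputed from the pooled totals (not averaged over
#' ROIs), so ROIs with many foci weigh accordingly.
#'
#' @param per_roi tibble as produced by [fc_colocalize()].
#' @return one-row tibble of totals and pooled percentages.
#' @export
fc_coloc_summary <- function(per_roi) {
  n1 <- sum(per_roi$n_foci_1); n2 <- sum(per_roi$n_foci_2)
  nco <- sum(per_roi$n_colocalized)
  tibble::tibble(
    n_foci_1 = n1, n_foci_2 = n2, n_colocalized = nco,
    pct_colocalized_1 = if (n1) 100 * nco / n1 else 0,
    pct_colocalized_2 = if (n2) 100 * nco / n2 else 0)
}
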