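#' Measurement parameters
#'
#' @param area_correction_factor positive scalar multiplying the per-nucleus
#'   foci density (`foci / area * factor`); chosen relative to the typical
#'   nucleus area so corrected densities are of convenient magnitude.
#' @param percentile optional outlier exclusion: per image, nuclei whose foci
#'   count lies strictly above the nearest-rank p-th percentile are flagged
#'   and excluded from summary statistics (they stay, flagged, in the per-ROI
#'   export). Targets e.g. S-phase cells with spurious replication-induced
#'   gamma-H2AX signal. Value in `(0, 100]`, or `NULL` to disable.
#' @param intensity_channel channel role on which per-ROI intensity
#'   statistics are measured; the nuclear-stain (`"roi"`) channel by default.
#' @param pixel_size_um optional pixel edge length in micrometers; when
#'   given, densities are additionally reported per square micrometer.
#' @return list of class `fc_measure_params`.
#' @export
fc_measure_params <- function(area_correction_factor = 1000,
                              percentile = NULL,
                              intensity_channel = "roi",
                              pixel_size_um = NULL) {
  if (area_correction_factor <= 0)
    stop("configuration error: area_correction_factor must be > 0", call. = FALSE)
  if (!is.null(percentile) && (percentile <= 0 || percentile > 100))
    stop("configuration error: percentile must lie in (0, 100]", call. = FALSE)
  structure(list(area_correction_factor = area_correction_factor,
                 percentile = percentile,
                 intensity_channel = intensity_channel,
                 pixel_size_um = pixel_size_um),
            class = "fc_measure_params")
}

#' Measure area and intensity statistics of one ROI
#'
#' @param pixels integer vector of 1-based matrix indices (the ROI pixel set).
#' @param raster integer matrix the statistics are measured on.
#' @return one-row tibble with `area`, `mean_intensity`, `min_intensity`,
#'   `max_intensity`, computed over exactly the ROI's pixels.
#' @export
fc_measure_roi <- function(pixels, raster) {
  if (!length(pixels))
    stop("computation error: empty ROI pixel set", call. = FALSE)
  v <- raster[pixels]
  tibble::tibble(area = length(pixels), mean_intensity = mean(v),
                 min_intensity = min(v), max_intensity = max(v))
}

#' Area-corrected foci density
#'
#' `foci_count / area * factor` — the per-nucleus foci count normalized by
#' the nucleus' own area, rescaled by a user factor so values are of
#' convenient magnitude regardless of magnification.
#'
#' @param foci_count non-negative integer.
#' @param area nucleus area in pixels^2, `> 0`.
#' @param factor positive scalar.
#' @return density (foci per pixel^2 times `factor`).
#' @export
fc_area_corrected_count <- function(foci_count, area, factor = 1000) {
  if (any(area <= 0)) stop("computation error: area must be > 0", call. = FALSE)
  foci_count / area * factor
}

nearest_rank_percentile <- function(v, p) {
  # p-th percentile as the ceil(p/100 * n)-th order statistic
  sort(v)[max(1L, ceiling(p / 100 * length(v)))]
}

#' Flag per-ROI outliers above a nearest-rank percentile
#'
#' Computes the nearest-rank `p`-th percentile of `key` within each image and
#' sets `excluded_by_percentile = TRUE` for records strictly above it.
#' Flagged records stay in the table (so no focus is ever lost from the
#' per-ROI export) but are omitted from summary statistics downstream.
#'
#' @param records per-ROI tibble with an `image` column and the key column.
#' @param percentile value in `(0, 100]`.
#' @param key column name to filter on (default `"foci_count_1"`).
#' @return `records` with an `excluded_by_percentile` logical column.
#' @export
fc_percentile_filter <- function(records, percentile, key = "foci_count_1") {
  if (is.null(percentile)) {
    records$excluded_by_percentile <- FALSE
    return(records)
  }
  if (percentile <= 0 || percentile > 100)
    stop("configuration error: percentile must lie in (0, 100]", call. = FALSE)
  if (!nrow(records)) {
    records$excluded_by_percentile <- logical(0)
    return(records)
  }
  records |>
    dplyr::group_by(.data$image) |>
    dplyr::mutate(excluded_by_percentile =
      .data[[key]] > nearest_rank_percentile(.data[[key]], percentile)) |>
    dplyr::ungroup()
}

#' Build the per-ROI record table
#'
#' Combines ROI geometry, intensity statistics on the configured channel,
#' per-channel foci counts and area-corrected densities, then applies the
#' percentile outlier flag.
#'
#' @param img an [fc_image].
#' @param rois ROI tibble from [fc_segment()].
#' @param foci per-focus tibble from [fc_detect_foci()].
#' @param params an [fc_measure_params()].
#' @return per-ROI tibble (one row per nucleus).
#' @export
fc_measure <- function(img, rois, foci, params = fc_measure_params()) {
  raster <- fc_channel(img, params$intensity_channel)
  has2 <- !is.null(img$roles$foci2)
  stats <- if (nrow(rois))
    dplyr::bind_rows(lapply(rois$pixels, fc_measure_roi, raster = raster))
  else tibble::tibble(area = numeric(), mean_intensity = numeric(),
                      min_intensity = numeric(), max_intensity = numeric())
  count_in <- function(channel) {
    f <- foci[foci$channel == channel, ]
    as.integer(tabulate(match(f$roi_id, rois$roi_id), nbins = nrow(rois)))
  }
  out <- tibble::tibble(
    image = rep(img$source, nrow(rois)),
    roi_id = rois$roi_id,
    area = stats$area,
    mean_intensity = stats$mean_intensity,
    min_intensity = stats$min_intensity,
    max_intensity = stats$max_intensity,
    circularity = rois$circularity,
    x = rois$x, y = rois$y,
    foci_count_1 = count_in("foci1"))
  out$foci_density_1 <- if (nrow(out))
    fc_area_corrected_count(out$foci_count_1, out$area,
                            params$area_correction_factor) else numeric(0)
  if (has2) {
    out$foci_count_2 <- count_in("foci2")
    out$foci_density_2 <- if (nrow(out))
      fc_area_corrected_count(out$foci_count_2, out$area,
                              params$area_correction_factor) else numeric(0)
  }
  if (!is.null(params$pixel_size_um) && nrow(out)) {
    um2 <- params$pixel_size_um^2
    out$foci_per_um2_1 <- out$foci_count_1 / (out$area * um2)
    if (has2) out$foci_per_um2_2 <- out$foci_count_2 / (out$area * um2)
  }
  fc_percentile_filter(out, params$percentile)
}
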