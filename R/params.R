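#' Full analysis parameter bundle
#'
#' Collects every option of the pipeline — channel assignment, segmentation,
#' foci detection, measurement, colocalization, output — and enforces
#' cross-field consistency (second-channel noise/cutoff and colocalization
#' are only allowed when a `foci2` channel is assigned).
#'
#' @param assignment an [fc_assignment()].
#' @param seg an [fc_seg_params()].
#' @param foci an [fc_foci_params()].
#' @param measure an [fc_measure_params()].
#' @param coloc an [fc_coloc_params()], or `NULL` to skip colocalization.
#' @param output_formats subset of `"csv"` (canonical).
#' @return list of class `fc_params`.
#' @export
fc_params <- function(assignment = fc_assignment(), seg = fc_seg_params(),
                      foci = fc_foci_params(), measure = fc_measure_params(),
                      coloc = NULL, output_formats = "csv") {
  p <- structure(list(assignment = assignment, seg = seg, foci = foci,
                      measure = measure, coloc = coloc,
                      output_formats = output_formats),
                 class = "fc_params")
  fc_validate_params(p)
  p
}

#' Validate an analysis parameter bundle
#'
#' @param p an [fc_params()].
#' @return `p` invisibly; stops with a configuration error otherwise.
#' @export
fc_validate_params <- function(p) {
  stopifnot(inherits(p, "fc_params"))
  has2 <- !is.null(p$assignment$foci2_channel)
  if (!has2) {
    if (!is.null(p$foci$noise_level_2) || !is.null(p$foci$cutoff_2))
      stop("configuration error: foci2 noise level/cutoff set while the ",
           "foci2 channel is inactive", call. = FALSE)
    if (!is.null(p$coloc) && isTRUE(p$coloc$enabled))
      stop("configuration error: colocalization enabled while the foci2 ",
           "channel is inactive", call. = FALSE)
  }
  bad <- setdiff(p$output_formats, c("csv", "xlsx"))
  if (length(bad))
    stop("configuration error: unknown output format(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("xlsx" %in% p$output_formats)
    stop("configuration error: xlsx export is not available in this build; ",
         "use csv (it imports directly into spreadsheet software)", call. = FALSE)
  invisible(p)
}

#' Read an analysis configuration from a YAML file
#'
#' The file uses one flat, namespaced key set grouped into sections:
#' `input.*` (mode, roi_channel, foci1_channel, foci2_channel, invert,
#' channel_token), `seg.*` (threshold_mode, manual_threshold, auto_method,
#' min_area, max_area, min_circularity, max_circularity, exclude_edge,
#' fill_holes, watershed), `foci.*` (noise_level_1, noise_level_2, cutoff_1,
#' cutoff_2), `measure.*` (area_correction_factor, percentile,
#' intensity_channel, pixel_size_um), `coloc.*` (enabled, tolerance,
#' export_pairs) and `output.formats`. All keys have defaults except the
#' channel assignment and noise levels, which every analysis should state.
#'
#' @param path YAML file path.
#' @return an [fc_params()].
#' @export
fc_read_config <- function(path) {
  if (!file.exists(path)) stop("input error: config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pick <- function(section, key, default = NULL) {
    v <- y[[section]][[key]]
    if (is.null(v)) default else v
  }
  assignment <- fc_assignment(
    mode = pick("input", "mode", "multichannel_file"),
    roi_channel = pick("input", "roi_channel", 1L),
    foci1_channel = pick("input", "foci1_channel", 2L),
    foci2_channel = pick("input", "foci2_channel"),
    invert = pick("input", "invert", FALSE),
    channel_token = pick("input", "channel_token", "_c{index}"))
  seg <- fc_seg_params(
    threshold_mode = pick("seg", "threshold_mode", "auto"),
    manual_threshold = pick("seg", "manual_threshold"),
    auto_method = pick("seg", "auto_method", "isodata"),
    min_area = pick("seg", "min_area", 50),
    max_area = pick("seg", "max_area", Inf),
    min_circularity = pick("seg", "min_circularity", 0),
    max_circularity = pick("seg", "max_circularity", 1),
    exclude_edge = pick("seg", "exclude_edge", TRUE),
    fill_holes = pick("seg", "fill_holes", TRUE),
    watershed = pick("seg", "watershed", FALSE))
  foci <- fc_foci_params(
    noise_level_1 = pick("foci", "noise_level_1", 100),
    noise_level_2 = pick("foci", "noise_level_2"),
    cutoff_1 = pick("foci", "cutoff_1"),
    cutoff_2 = pick("foci", "cutoff_2"))
  measure <- fc_measure_params(
    area_correction_factor = pick("measure", "area_correction_factor", 1000),
    percentile = pick("measure", "percentile"),
    intensity_channel = pick("measure", "intensity_channel", "roi"),
    pixel_size_um = pick("measure", "pixel_size_um"))
  coloc <- if (isTRUE(pick("coloc", "enabled", FALSE)))
    fc_coloc_params(tolerance = pick("coloc", "tolerance", 2),
                    enabled = TRUE,
                    export_pairs = pick("coloc", "export_pairs", FALSE))
  fc_params(assignment = assignment, seg = seg, foci = foci,
            measure = measure, coloc = coloc,
            output_formats = pick("output", "formats", "csv"))
}

params_flat <- function(p) {
  # flatten the bundle for the run-metadata echo
  sect <- list(input = p$assignment, seg = p$seg, foci = p$foci,
               measure = p$measure, coloc = p$coloc)
  out <- list()
  for (s in names(sect)) {
    if (is.null(sect[[s]])) next
    for (k in names(sect[[s]])) {
      v <- sect[[s]][[k]]
      out[[paste(s, k, sep = ".")]] <- if (is.null(v)) NA else unclass(v)
    }
  }
  out[["output.formats"]] <- p$output_formats
  out
}
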