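#' Tidy a single-image analysis result
#'
#' One row per nucleus (the per-ROI record table).
#'
#' @param x an `fc_result`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.fc_result <- function(x, ...) x$per_roi

#' One-row summary of a single-image analysis
#'
#' @param x an `fc_result`.
#' @param ... unused.
#' @return one-row tibble (the per-image record).
#' @export
glance.fc_result <- function(x, ...) x$per_image

#' Tidy a batch analysis result
#'
#' One row per nucleus across all images.
#'
#' @param x an `fc_batch`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.fc_batch <- function(x, ...) x$per_roi

#' One-row summary of a batch analysis
#'
#' @param x an `fc_batch`.
#' @param ... unused.
#' @return one-row tibble of batch means.
#' @export
glance.fc_batch <- function(x, ...) x$batch_summary
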