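raster_to_df <- function(raster, step = 1L) {
  rows <- seq(1L, nrow(raster), by = step)
  cols <- seq(1L, ncol(raster), by = step)
  tibble::tibble(
    x = rep(cols - 1L, each = length(rows)),
    y = rep(rows - 1L, times = length(cols)),
    intensity = as.vector(raster[rows, cols]))
}

roi_outline_df <- function(rois) {
  if (!nrow(rois)) return(tibble::tibble(roi_id = integer(), x = numeric(),
                                         y = numeric()))
  dim <- attr(rois, "raster_dim")
  nr <- dim[1]
  outs <- lapply(seq_len(nrow(rois)), function(i) {
    px <- rois$pixels[[i]]
    rr <- ((px - 1L) %% nr) + 1L
    cc <- ((px - 1L) %/% nr) + 1L
    # boundary pixels: any 4-neighbor missing
    key <- paste(rr, cc)
    inside <- (paste(rr - 1L, cc) %in% key) & (paste(rr + 1L, cc) %in% key) &
      (paste(rr, cc - 1L) %in% key) & (paste(rr, cc + 1L) %in% key)
    tibble::tibble(roi_id = rois$roi_id[i], x = cc[!inside] - 1L,
                   y = rr[!inside] - 1L)
  })
  dplyr::bind_rows(outs)
}

#' QC overlay plot for a single-image result
#'
#' Shows a foci channel with the segmented nucleus outlines, numbered ROIs
#' and detected foci marked; the non-interactive stand-in for watching an
#' interactive tool select ROIs.
#'
#' @param object an `fc_result` produced with `keep_image = TRUE`.
#' @param channel which channel to show (`"foci1"`, `"foci2"`, `"roi"`).
#' @param ... unused.
#' @return a ggplot object (y axis points down, image convention).
#' @export
autoplot.fc_result <- function(object, channel = "foci1", ...) {
  if (is.null(object$image))
    stop("result was produced with keep_image = FALSE; re-run ",
         "fc_analyze_image() with keep_image = TRUE to plot", call. = FALSE)
  bg <- raster_to_df(fc_channel(object$image, channel))
  outl <- roi_outline_df(object$rois)
  foci <- object$per_focus[object$per_focus$channel ==
                             (if (channel == "roi") "foci1" else channel), ]
  p <- ggplot2::ggplot(bg, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = outl, color = "#4daf4a", size = 0.1) +
    ggplot2::geom_point(data = foci, color = "#e41a1c", shape = 3, size = 1.4) +
    ggplot2::geom_text(data = object$rois,
                       ggplot2::aes(label = .data$roi_id),
                       color = "#4daf4a", size = 3, vjust = -0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$metadata$source,
                  subtitle = sprintf("%d ROI(s), %d focus/foci shown",
                                     nrow(object$rois), nrow(foci)),
                  fill = "intensity") +
    ggplot2::theme_minimal()
  p
}

#' Dose-response plot of mean foci per nucleus
#'
#' Scatter of per-image mean foci count per nucleus against dose with the
#' least-squares line, for results of analyzing an [fc_dose_series()].
#'
#' @param df data frame with columns `dose` and `mean_foci`.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$mean_foci)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#377eb8") +
    ggplot2::labs(x = "dose (Gy)", y = "mean foci per nucleus") +
    ggplot2::theme_minimal()
}

#' Write a QC overlay PNG next to exported tables
#'
#' @param result an `fc_result` with its image retained.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path` invisibly.
#' @export
fc_write_overlay <- function(result, path, width = 900, height = 900) {
  p <- autoplot.fc_result(result)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
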