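#' Construct a multi-channel image container
#'
#' An `fc_image` bundles one or more equally sized grayscale rasters with a
#' declared bit depth and a channel-role map. Rasters are integer matrices
#' (`[row, col]`, values in `[0, 2^bit_depth - 1]`). Roles name the nuclear
#' stain used for segmentation (`roi`), the first foci channel (`foci1`) and
#' an optional second foci channel (`foci2`); at most three channels can be
#' role-bound.
#'
#' @param channels list of integer matrices, all the same dimension.
#' @param bit_depth 8 or 16.
#' @param roles named list mapping `roi`, `foci1` and optionally `foci2` to
#'   1-based channel indices. `roi` and `foci1` are mandatory and all bound
#'   indices must be distinct.
#' @param source optional source path, carried into result tables.
#' @return an object of class `fc_image`.
#' @export
fc_image <- function(channels, bit_depth = 16L, roles = list(roi = 1L, foci1 = 2L),
                     source = "<memory>") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty list of matrices", call. = FALSE)
  channels <- lapply(channels, function(ch) {
    if (!is.matrix(ch)) stop("each channel must be a matrix", call. = FALSE)
    storage.mode(ch) <- "integer"
    ch
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share identical dimensions", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  maxval <- 2L^bit_depth - 1L
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0L || rng[2] > maxval)
    stop("pixel values exceed the declared bit depth", call. = FALSE)
  roles <- validate_roles(roles, n_channels = length(channels))
  structure(
    list(channels = channels, bit_depth = as.integer(bit_depth),
         roles = roles, source = source),
    class = "fc_image"
  )
}

validate_roles <- function(roles, n_channels) {
  if (is.null(roles$roi) || is.null(roles$foci1))
    stop("channel roles 'roi' and 'foci1' must both be assigned", call. = FALSE)
  known <- c("roi", "foci1", "foci2")
  extra <- setdiff(names(roles), known)
  if (length(extra))
    stop("unknown channel role(s): ", paste(extra, collapse = ", "),
         " (at most three roles: roi, foci1, foci2)", call. = FALSE)
  roles <- roles[intersect(known, names(roles))]
  idx <- unlist(roles)
  if (anyDuplicated(idx))
    stop("configuration error: roi/foci1/foci2 must be distinct channels", call. = FALSE)
  if (any(idx < 1L | idx > n_channels))
    stop("configuration error: channel index out of range (image has ",
         n_channels, " channel(s), requested ", paste(idx, collapse = "/"), ")",
         call. = FALSE)
  lapply(roles, as.integer)
}

#' @export
print.fc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<fc_image> ", d[1], "x", d[2], " px, ", length(x$channels),
      " channel(s), ", x$bit_depth, "-bit\n", sep = "")
  cat("  roles: ", paste(names(x$roles), unlist(x$roles), sep = "=", collapse = ", "),
      "\n  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Extract the raster bound to a channel role
#' @param img an [fc_image].
#' @param role one of `"roi"`, `"foci1"`, `"foci2"`.
#' @return integer matrix.
#' @export
fc_channel <- function(img, role) {
  stopifnot(inherits(img, "fc_image"))
  idx <- img$roles[[role]]
  if (is.null(idx)) stop("role '", role, "' is not assigned", call. = FALSE)
  img$channels[[idx]]
}

read_raster_file <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bd <- if (max(vapply(pages, max, numeric(1)), 0) > 255) 16L else 8L
    # as.is keeps native integer scale; sample depth from the data range is a
    # fallback for writers that do not tag it
    attr_bd <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(attr_bd)) bd <- as.integer(attr_bd)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bd <- as.integer(info$bit.depth)
    pages <- list(round(img * (2^bd - 1)))
  } else {
    stop("format error: unsupported file format '", ext,
         "' (TIFF and PNG are supported; convert proprietary formats first)",
         call. = FALSE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L)
      stop("format error: ", path, " is a color (RGB) image; split it into ",
           "grayscale channels and use per-channel mode", call. = FALSE)
    storage.mode(p) <- "integer"
    attributes(p) <- list(dim = dim(p))
    p
  })
  list(pages = pages, bit_depth = bd)
}

#' Load a single- or multi-channel image with channel roles bound
#'
#' Two input modes are supported. In `multichannel_file` mode `path` is one
#' multi-page TIFF (or single-page TIFF/PNG) and the role entries of
#' `assignment` are 1-based page indices. In `per_channel_files` mode `path`
#' is a character vector of per-channel files (one single-plane raster each),
#' and role entries index into that vector in the given order.
#'
#' Raw pixel values are preserved bit-exactly: no contrast change, filtering
#' or rescaling is applied. If `invert = TRUE` (light-background images) every
#' pixel `v` becomes `2^bit_depth - 1 - v` so that the bright-on-dark
#' convention holds downstream.
#'
#' @param path file path (multichannel mode) or character vector of paths
#'   (per-channel mode).
#' @param assignment a list as returned by [fc_assignment()].
#' @return an [fc_image].
#' @export
fc_read_image <- function(path, assignment = fc_assignment()) {
  mode <- assignment$mode %||% "multichannel_file"
  if (mode == "multichannel_file") {
    if (length(path) != 1L) stop("multichannel_file mode expects one path", call. = FALSE)
    dec <- read_raster_file(path)
    channels <- dec$pages
    src <- path
    bd <- dec$bit_depth
  } else if (mode == "per_channel_files") {
    decs <- lapply(path, read_raster_file)
    channels <- lapply(decs, function(d) {
      if (length(d$pages) != 1L)
        stop("format error: per-channel files must be single-plane", call. = FALSE)
      d$pages[[1]]
    })
    dims <- vapply(channels, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("format error: per-channel rasters have mismatched dimensions (",
           paste(basename(path), collapse = ", "), ")", call. = FALSE)
    bd <- max(vapply(decs, function(d) d$bit_depth, integer(1)))
    src <- paste(path, collapse = ";")
  } else stop("configuration error: unknown input mode '", mode, "'", call. = FALSE)

  roles <- list(roi = assignment$roi_channel, foci1 = assignment$foci1_channel)
  if (!is.null(assignment$foci2_channel)) roles$foci2 <- assignment$foci2_channel
  img <- fc_image(channels, bit_depth = bd, roles = roles, source = src)
  if (isTRUE(assignment$invert)) img <- fc_invert(img) else img
}

#' Channel assignment for image loading
#'
#' @param mode `"multichannel_file"` (pages of one file) or
#'   `"per_channel_files"` (one file per channel, grouped by a filename token).
#' @param roi_channel,foci1_channel 1-based channel indices (mandatory roles).
#' @param foci2_channel optional second foci channel index, or `NULL`
#'   ("inactive") when only one foci channel is analyzed.
#' @param invert set `TRUE` for light-background images; channels are
#'   complemented on load.
#' @param channel_token per-channel filename token with `{index}` placeholder;
#'   `"img_c0.png"`/`"img_c1.png"` is the default convention (`"_c{index}"`,
#'   0-based on disk).
#' @return a list of class `fc_assignment`.
#' @export
fc_assignment <- function(mode = c("multichannel_file", "per_channel_files"),
                          roi_channel = 1L, foci1_channel = 2L,
                          foci2_channel = NULL, invert = FALSE,
                          channel_token = "_c{index}") {
  mode <- match.arg(mode)
  structure(list(mode = mode, roi_channel = as.integer(roi_channel),
                 foci1_channel = as.integer(foci1_channel),
                 foci2_channel = if (!is.null(foci2_channel)) as.integer(foci2_channel),
                 invert = isTRUE(invert), channel_token = channel_token),
            class = "fc_assignment")
}

#' Invert all channels of an image
#'
#' Complements every pixel (`v -> 2^bit_depth - 1 - v`); used for
#' light-background images so nuclei and foci become bright-on-dark. Applying
#' twice restores the input bit-exactly.
#'
#' @param img an [fc_image].
#' @return an [fc_image].
#' @export
fc_invert <- function(img) {
  stopifnot(inherits(img, "fc_image"))
  maxval <- as.integer(2^img$bit_depth - 1)
  img$channels <- lapply(img$channels, function(ch) maxval - ch)
  img
}

#' Enumerate analyzable images under a folder tree
#'
#' Recurses through `root` (all subfolders included) and returns image groups
#' in deterministic lexicographic order. In multichannel mode every TIFF/PNG
#' file is one group. In per-channel mode, files sharing a stem and differing
#' in the channel token (default `_c0`, `_c1`, ...) form one group; groups
#' missing a required channel index are excluded from analysis and reported
#' in the `skipped` attribute instead of being silently analyzed.
#'
#' @param root directory to scan.
#' @param assignment an [fc_assignment()]; its `mode`, channel indices and
#'   `channel_token` drive the grouping.
#' @return tibble with columns `group` (logical image id) and `paths`
#'   (list-column of file paths, channel order); attribute `skipped` is a
#'   tibble of incomplete groups with the missing token.
#' @export
fc_list_inputs <- function(root, assignment = fc_assignment()) {
  if (!dir.exists(root)) stop("input error: not a readable directory: ", root, call. = FALSE)
  files <- list.files(root, pattern = "\\.(tif|tiff|png)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  files <- sort(files, method = "radix")
  skipped <- tibble::tibble(group = character(), reason = character())
  if (assignment$mode == "multichannel_file") {
    out <- tibble::tibble(group = files, paths = as.list(files))
  } else {
    token_re <- glob_token_regex(assignment$channel_token)
    m <- regexpr(token_re, basename(files))
    has_tok <- m > 0
    stem <- character(length(files))
    chan <- integer(length(files))
    tok <- regmatches(basename(files), m)
    chan[has_tok] <- as.integer(gsub("\\D", "", tok))
    stem[has_tok] <- file.path(dirname(files),
                               sub(token_re, "", basename(files))) [has_tok]
    files <- files[has_tok]; stem <- stem[has_tok]; chan <- chan[has_tok]
    # disk channel tokens are 0-based; role indices are 1-based positions in
    # ascending token order
    need <- sort(unlist(Filter(Negate(is.null),
      list(assignment$roi_channel, assignment$foci1_channel, assignment$foci2_channel))))
    groups <- split(seq_along(files), stem)
    keep <- list(); skip <- list()
    for (g in sort(names(groups))) {
      i <- groups[[g]]
      ord <- order(chan[i])
      present <- seq_along(i)
      if (max(need) > length(i)) {
        skip[[g]] <- tibble::tibble(
          group = g,
          reason = paste0("incomplete per-channel group: found ", length(i),
                          " channel file(s), role indices require ", max(need)))
      } else {
        keep[[g]] <- tibble::tibble(group = g, paths = list(files[i][ord]))
      }
    }
    out <- if (length(keep)) dplyr::bind_rows(keep) else
      tibble::tibble(group = character(), paths = list())
    skipped <- if (length(skip)) dplyr::bind_rows(skip) else skipped
  }
  if (nrow(out) == 0L)
    warning("no analyzable images found under ", root, call. = FALSE)
  attr(out, "skipped") <- skipped
  out
}

glob_token_regex <- function(token) {
  # "_c{index}" -> "_c[0-9]+"
  parts <- strsplit(token, "{index}", fixed = TRUE)[[1]]
  esc <- vapply(parts, function(pp)
    gsub("([^A-Za-z0-9])", "\\\\\\1", pp), character(1))
  out <- paste0(esc, collapse = "[0-9]+")
  if (endsWith(token, "{index}")) out <- paste0(out, "[0-9]+")
  out
}

#' Write a raster (or multi-channel image) to TIFF
#'
#' Writes 8- or 16-bit grayscale TIFF; multi-channel images become multi-page
#' files. Loading the written file reproduces the pixel data bit-exactly.
#'
#' @param img an [fc_image] or a single integer matrix.
#' @param path output file path (`.tif`).
#' @param bit_depth used when `img` is a bare matrix.
#' @return `path`, invisibly.
#' @export
fc_write_image <- function(img, path, bit_depth = 16L) {
  if (inherits(img, "fc_image")) {
    chans <- img$channels
    bit_depth <- img$bit_depth
  } else chans <- list(img)
  maxval <- 2^bit_depth - 1
  pages <- lapply(chans, function(ch) ch / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bit_depth),
                  compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
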