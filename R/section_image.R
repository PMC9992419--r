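# The section_image container: named channel rasters + physical calibration
# + named ROI polygons/polylines. All downstream image stages consume this
# one type; pixel coordinates never leave a module boundary.

#' Construct a section image
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions `c(nx, ny)` (x index first, y-down).
#' @param pixel_size_um pixel size in micrometres per pixel (> 0)
#' @param rois list with elements `polygons` and `polylines`, each a named
#'   list of data.frames with columns `x`, `y` in micrometres.
#' @return object of class `section_image`
#' @export
section_image <- function(channels, pixel_size_um, rois = list(polygons = list(), polylines = list())) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stopf("channels must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, TRUE)) ||
      !all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE))) {
    stopf("all channels must be matrices with identical dimensions")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a single positive number")
  }
  rois$polygons <- rois$polygons %||% list()
  rois$polylines <- rois$polylines %||% list()
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, rois = rois),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "section_image: %d x %d px (%.1f x %.1f um at %.3g um/px)\n  channels: %s\n  ROIs: %d polygon(s), %d polyline(s)\n",
    d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um, x$pixel_size_um,
    paste(names(x$channels), collapse = ", "),
    length(x$rois$polygons), length(x$rois$polylines)
  ))
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])

roi_df <- function(obj) data.frame(x = as.numeric(obj$x), y = as.numeric(obj$y))

#' Write / read ROI polygons and polylines as JSON
#'
#' The interchange layout is `{"polygons": {name: {"x": [...], "y": [...]}},
#' "polylines": {...}}` with coordinates in micrometres, 0-based, y-down.
#'
#' @param rois list with `polygons` and `polylines` named lists of data.frames
#' @param path output path
#' @return `write_roi_json`: the path, invisibly; `read_roi_json`: the ROI list.
#' @export
write_roi_json <- function(rois, path) {
  pack <- function(lst) lapply(lst, function(d) list(x = d$x, y = d$y))
  jsonlite::write_json(
    list(polygons = pack(rois$polygons %||% list()), polylines = pack(rois$polylines %||% list())),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stopf("ROI file does not exist: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(lst) lapply(lst, function(d) data.frame(x = as.numeric(d$x), y = as.numeric(d$y)))
  list(polygons = unpack(raw$polygons %||% list()), polylines = unpack(raw$polylines %||% list()))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a section image as multi-page TIFF plus JSON metadata sidecar
#'
#' One TIFF page per channel. Pixel size, channel names, and the bit depth
#' are carried in a JSON sidecar file (`<path>.json`), the package's image
#' metadata convention; ROIs go to a separate ROI JSON when `roi_path` is
#' given. Integer-valued images are stored as 16-bit pages (bit-exact round
#' trip); other images as 32-bit float.
#'
#' @param img section_image
#' @param path output TIFF path
#' @param roi_path optional path for the ROI JSON
#' @return `path`, invisibly
#' @export
write_section <- function(img, path, roi_path = NULL) {
  stopifnot(inherits(img, "section_image"))
  integerish <- all(vapply(img$channels, function(m) {
    all(m >= 0) && all(m <= 65535) && all(m == round(m))
  }, TRUE))
  if (integerish) {
    pages <- lapply(img$channels, function(m) t(m) / 65535)
    bits <- 16L
  } else {
    pages <- lapply(img$channels, t)
    bits <- 32L
    rng <- range(unlist(lapply(pages, range)))
    if (rng[1] < 0 || rng[2] > 1) {
      # tiff stores float pages as-is only within [0,1]; rescale and record it
      scale <- max(rng[2], 1e-12)
      pages <- lapply(pages, function(m) pmax(m, 0) / scale)
      attr(pages, "scale") <- scale
    }
  }
  scale <- attr(pages, "scale") %||% if (bits == 16L) 65535 else 1
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(
      pixel_size_um = img$pixel_size_um,
      channels = names(img$channels),
      bits_per_sample = bits,
      intensity_scale = scale
    ),
    sidecar_path(path), digits = NA, auto_unbox = TRUE
  )
  if (!is.null(roi_path)) write_roi_json(img$rois, roi_path)
  invisible(path)
}

#' Read a section image from TIFF (+ metadata sidecar)
#'
#' Channel names and the micrometre calibration come from the sidecar written
#' by [write_section()]; for foreign TIFFs without a sidecar, `pixel_size_um`
#' must be supplied and pages are named `ch1..chk` (or by `channel_names`).
#'
#' @param path TIFF path
#' @param pixel_size_um calibration override (required when no sidecar exists)
#' @param channel_names optional channel names override
#' @param roi_path optional ROI JSON to attach
#' @return section_image
#' @export
read_section <- function(path, pixel_size_um = NULL, channel_names = NULL, roi_path = NULL) {
  if (!file.exists(path)) stopf("image file does not exist: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) stopf("failed to read TIFF '%s': %s", path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  psz <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(psz)) {
    stopf("no pixel size metadata for '%s' and no pixel_size_um override given", path)
  }
  nms <- channel_names %||% meta$channels %||% paste0("ch", seq_along(pages))
  if (length(nms) != length(pages)) {
    stopf("channel count mismatch for '%s': %d page(s), %d name(s)", path, length(pages), length(nms))
  }
  scale <- meta$intensity_scale %||% 1
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey stored with extra samples
    m <- t(p) * scale
    if (scale == 65535) m <- round(m)
    m
  })
  names(channels) <- nms
  rois <- if (!is.null(roi_path)) read_roi_json(roi_path) else list(polygons = list(), polylines = list())
  section_image(channels, psz, rois)
}

#' Write / read an RGB image as TIFF (float, one page, 3 samples)
#' @param rgb numeric array dim c(nx, ny, 3), values in [0, background_white]
#' @param path file path
#' @param background_white per-channel illumination level used for scaling
#' @return path / array
#' @export
write_rgb_tiff <- function(rgb, path, background_white = 255) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  arr <- aperm(rgb, c(2, 1, 3)) / max(background_white)
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(list(background_white = background_white),
                       sidecar_path(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rgb_tiff
#' @export
read_rgb_tiff <- function(path) {
  if (!file.exists(path)) stopf("image file does not exist: %s", path)
  arr <- tiff::readTIFF(path)
  bw <- 255
  if (file.exists(sidecar_path(path))) {
    bw <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)$background_white %||% 255
  }
  out <- aperm(arr, c(2, 1, 3)) * max(bw)
  attr(out, "background_white") <- bw
  out
}
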