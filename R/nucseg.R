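# Nuclear segmentation and per-nucleus measurement. Mirrors the standard
# Fiji workflow for these sections: global intensity threshold on the
# Hoechst channel, watershed splitting of touching nuclei, particle-style
# area filtering, then per-nucleus mean intensities in every channel.

#' Segment nuclei from a Hoechst raster
#'
#' Foreground by a global threshold (Otsu by default, computed on the
#' min-max-normalized image so the result is invariant to affine intensity
#' rescaling; a fixed threshold is available for parity with manual
#' workflows). Touching nuclei are split by watershed on the internal
#' Euclidean distance transform, with seed maxima separated by at least
#' `seed_sep_um`. Components outside the area bounds are removed and the
#' remaining labels renumbered from 1; background is 0.
#'
#' @param hoechst single-channel numeric matrix (x index first)
#' @param pixel_size_um calibration, um/px
#' @param min_area_um2,max_area_um2 retained nucleus area bounds
#' @param threshold_mode "otsu" or "fixed"
#' @param threshold fixed threshold value (required for mode "fixed")
#' @param seed_sep_um minimum separation of watershed seed maxima
#' @param ws_tolerance_px watershed flooding tolerance (distance-map units)
#' @return integer label matrix; attribute `on_border` lists labels touching
#'   the image border (retained, flagged for optional exclusion)
#' @export
segment_nuclei <- function(hoechst, pixel_size_um,
                           min_area_um2 = 8, max_area_um2 = 200,
                           threshold_mode = c("otsu", "fixed"), threshold = NULL,
                           seed_sep_um = 2, ws_tolerance_px = 0.3) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.matrix(hoechst)) stopf("hoechst must be a matrix")
  if (min_area_um2 <= 0 || min_area_um2 >= max_area_um2) {
    stopf("area bounds must satisfy 0 < min_area_um2 < max_area_um2")
  }
  rng <- range(hoechst)
  if (rng[1] == rng[2]) {
    out <- matrix(0L, nrow(hoechst), ncol(hoechst))
    attr(out, "on_border") <- integer(0)
    attr(out, "threshold") <- rng[1]
    return(out)
  }
  thr <- switch(threshold_mode,
    otsu = {
      norm <- (hoechst - rng[1]) / (rng[2] - rng[1])
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256) * (rng[2] - rng[1]) + rng[1]
    },
    fixed = {
      if (is.null(threshold) || !is.finite(threshold)) stopf("threshold_mode 'fixed' needs a finite threshold")
      threshold
    }
  )
  bw <- hoechst > thr
  if (!any(bw)) {
    out <- matrix(0L, nrow(hoechst), ncol(hoechst))
    attr(out, "on_border") <- integer(0)
    attr(out, "threshold") <- thr
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  ext <- max(1L, round(seed_sep_um / pixel_size_um))
  ws <- EBImage::watershed(dm, tolerance = ws_tolerance_px, ext = ext)
  lab <- EBImage::imageData(ws)
  storage.mode(lab) <- "integer"

  # particle-style area filter
  areas_px <- tabulate(lab[lab > 0L], nbins = max(lab))
  lo <- min_area_um2 / pixel_size_um^2
  hi <- max_area_um2 / pixel_size_um^2
  keep <- which(areas_px >= lo & areas_px <= hi)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]

  nb <- max(lab)
  border <- integer(0)
  if (nb > 0L) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- sort(edge[edge > 0L])
  }
  attr(lab, "on_border") <- border
  attr(lab, "threshold") <- thr
  lab
}

#' Measure per-nucleus properties
#'
#' One record per label: pixel-count area (um^2), unweighted pixel centroid
#' (um, 0-based, y-down), and the mean intensity over the nuclear mask for
#' every supplied channel.
#'
#' @param labels integer label matrix from [segment_nuclei()]
#' @param channels named list of matrices sharing the label geometry
#' @param pixel_size_um calibration
#' @return data.frame with columns label, x_um, y_um, area_um2, on_border,
#'   and `mean_<channel>` per channel
#' @export
measure_nuclei <- function(labels, channels, pixel_size_um) {
  if (!all(vapply(channels, function(m) identical(dim(m), dim(labels)), TRUE))) {
    stopf("channels and labels must share dimensions")
  }
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), on_border = logical(0))
    for (ch in names(channels)) out[[paste0("mean_", ch)]] <- numeric(0)
    return(out)
  }
  idx <- which(labels > 0L)
  l <- labels[idx]
  nx <- nrow(labels)
  i <- ((idx - 1L) %% nx) + 1L
  j <- ((idx - 1L) %/% nx) + 1L
  area_px <- tabulate(l, nbins = nlab)
  sx <- rowsum(as.numeric(i), l)[, 1]
  sy <- rowsum(as.numeric(j), l)[, 1]
  out <- data.frame(
    label = seq_len(nlab),
    x_um = (sx / area_px - 0.5) * pixel_size_um,
    y_um = (sy / area_px - 0.5) * pixel_size_um,
    area_um2 = area_px * pixel_size_um^2,
    on_border = seq_len(nlab) %in% (attr(labels, "on_border") %||% integer(0))
  )
  for (ch in names(channels)) {
    s <- rowsum(as.numeric(channels[[ch]][idx]), l)[, 1]
    out[[paste0("mean_", ch)]] <- s / area_px
  }
  out
}

#' Classify nuclei by a run-level intensity threshold
#'
#' The same threshold must be applied to every image of a comparison set, so
#' the threshold is a run-level parameter here, never fitted per image. The
#' flag is `mean intensity > threshold`.
#'
#' @param records data.frame from [measure_nuclei()]
#' @param channel channel name (its `mean_<channel>` column must exist)
#' @param threshold finite run-level threshold
#' @param flag name of the logical flag column to set (default `<channel>_pos`)
#' @return records with the flag column added
#' @export
classify_by_threshold <- function(records, channel, threshold, flag = paste0(channel, "_pos")) {
  col <- paste0("mean_", channel)
  if (!col %in% names(records)) stopf("channel '%s' absent from records", channel)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stopf("threshold must be a single numeric value")
  }
  records[[flag]] <- records[[col]] > threshold
  records
}
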