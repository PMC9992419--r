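# Euclidean-distance-map depth profiling: distance of each cell to the
# nearest tendon surface, normalized to the section's maximum depth, binned
# into four quartiles (Q1 outermost), with enrichment ratios that equal 1
# under spatially uniform placement.

#' Build the Euclidean distance map for a section
#'
#' Pixel value = Euclidean distance (um) to the nearest point of either
#' surface polyline; exactly zero on rasterized polyline pixels. The
#' polylines are densely resampled (quarter-pixel steps) before
#' rasterization, so distances agree with exact point-to-segment geometry to
#' within a pixel of discretization. Distances are kept in floating point;
#' they are not quantized to an integer bit depth.
#'
#' @param nx,ny raster dimensions (x first)
#' @param anterior_polyline,posterior_polyline surface polylines (um, >= 2 vertices)
#' @param pixel_size_um calibration
#' @return numeric matrix of distances in um
#' @export
build_edm <- function(nx, ny, anterior_polyline, posterior_polyline, pixel_size_um) {
  rasterize_line <- function(line) {
    p <- as.matrix(line[, c("x", "y")])
    if (nrow(p) < 2L) stopf("surface polyline needs at least 2 vertices")
    pts <- do.call(rbind, lapply(seq_len(nrow(p) - 1L), function(k) {
      L <- sqrt(sum((p[k + 1L, ] - p[k, ])^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / (pixel_size_um / 4)) + 1L))
      cbind(p[k, 1] + t * (p[k + 1L, 1] - p[k, 1]), p[k, 2] + t * (p[k + 1L, 2] - p[k, 2]))
    }))
    i <- pmin(pmax(ceiling(pts[, 1] / pixel_size_um), 1L), nx)
    j <- pmin(pmax(ceiling(pts[, 2] / pixel_size_um), 1L), ny)
    if (any(pts[, 1] < 0 | pts[, 1] > nx * pixel_size_um |
            pts[, 2] < 0 | pts[, 2] > ny * pixel_size_um)) {
      stopf("surface polyline extends outside the raster bounds")
    }
    unique(i + (j - 1L) * nx)
  }
  m <- matrix(1, nx, ny)
  m[rasterize_line(anterior_polyline)] <- 0
  m[rasterize_line(posterior_polyline)] <- 0
  as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(m)))) * pixel_size_um
}

#' Assign per-nucleus depth and normalized depth
#'
#' Depth = mean EDM value over the nucleus mask; `d_norm = depth / EDM_max`
#' where `EDM_max` is the maximum EDM over in-ROI pixels (over the whole
#' raster when no polygon is given). `d_norm` is clamped to [0, 1]: nuclei
#' partially outside the ROI can average marginally past the in-ROI maximum.
#'
#' @param records nucleus records (must carry `label`)
#' @param labels label matrix matching the EDM geometry
#' @param edm distance raster from [build_edm()]
#' @param roi_polygon optional fascicle polygon restricting `EDM_max`
#' @param pixel_size_um calibration (needed when `roi_polygon` is given)
#' @return records with `depth_um` and `d_norm` columns; attribute
#'   `edm_max_um` carries the normalizing maximum
#' @export
assign_depth <- function(records, labels, edm, roi_polygon = NULL, pixel_size_um = NULL) {
  if (!identical(dim(labels), dim(edm))) stopf("labels and edm must share dimensions")
  edm_max <- if (is.null(roi_polygon)) {
    max(edm)
  } else {
    if (is.null(pixel_size_um)) stopf("pixel_size_um required with roi_polygon")
    msk <- polygon_mask(nrow(edm), ncol(edm), roi_polygon, pixel_size_um)
    if (!any(msk)) stopf("ROI polygon covers no pixels")
    max(edm[msk])
  }
  if (edm_max <= 0) stopf("EDM_max is zero; surfaces cover the whole raster")
  idx <- which(labels > 0L)
  l <- labels[idx]
  nlab <- max(0L, max(labels))
  depth <- rep(NA_real_, nlab)
  if (length(idx)) {
    s <- rowsum(as.numeric(edm[idx]), l)
    depth[as.integer(rownames(s))] <- s[, 1] / tabulate(l, nbins = nlab)[as.integer(rownames(s))]
  }
  records$depth_um <- depth[records$label]
  records$d_norm <- pmin(pmax(records$depth_um / edm_max, 0), 1)
  attr(records, "edm_max_um") <- edm_max
  records
}

#' Quartile bin of a normalized depth
#'
#' Q1 = [0, 0.25) is the outermost increment, Q4 = [0.75, 1] (closed upper
#' edge) the innermost.
#' @param d_norm numeric in [0, 1]
#' @return integer 1..4
#' @export
depth_quartile <- function(d_norm) {
  as.integer(pmin(pmax(floor(d_norm * 4) + 1, 1), 4))
}

#' Per-section quartile depth profile
#'
#' Counts positive and negative cells per depth quartile and forms enrichment
#' ratios: the % positive within a quartile divided by the whole-section %
#' positive (1 in every quartile under spatial uniformity). The alternative
#' normalization — the fraction of the positive population falling in each
#' quartile, divided by the fraction of all cells in that quartile — is
#' available via `normalization = "population_share"`.
#'
#' @param records records with `d_norm` and the positivity flag
#' @param flag positivity flag column (default "gfp_pos")
#' @param section_id identifier
#' @param edm_max_um optional maximum depth to report
#' @param normalization "within_quartile_pct" (default) or "population_share"
#' @return data.frame with one row per quartile: section_id, quartile, n_pos,
#'   n_neg, pct_pos, ratio_pos, ratio_neg
#' @export
quartile_profile <- function(records, flag = "gfp_pos", section_id = NA_character_,
                             edm_max_um = attr(records, "edm_max_um") %||% NA_real_,
                             normalization = c("within_quartile_pct", "population_share")) {
  normalization <- match.arg(normalization)
  if (nrow(records) == 0L) stopf("empty record set")
  if (!flag %in% names(records)) stopf("flag column '%s' absent", flag)
  if (!"d_norm" %in% names(records)) stopf("records lack d_norm; run assign_depth first")
  q <- depth_quartile(records$d_norm)
  pos <- records[[flag]]
  n_pos_q <- vapply(1:4, function(k) sum(q == k & pos), 0L)
  n_neg_q <- vapply(1:4, function(k) sum(q == k & !pos), 0L)
  n_q <- n_pos_q + n_neg_q
  n_pos <- sum(pos); n_neg <- sum(!pos); n <- length(pos)
  pct_pos_q <- ifelse(n_q > 0, 100 * n_pos_q / n_q, NA_real_)
  pct_pos_whole <- 100 * n_pos / n
  if (normalization == "within_quartile_pct") {
    ratio_pos <- pct_pos_q / pct_pos_whole
    ratio_neg <- ifelse(n_q > 0, (100 * n_neg_q / n_q) / (100 * n_neg / n), NA_real_)
  } else {
    # share of each population in the quartile relative to share of all cells
    ratio_pos <- ifelse(n_q > 0, (n_pos_q / n_pos) / (n_q / n), NA_real_)
    ratio_neg <- ifelse(n_q > 0, (n_neg_q / n_neg) / (n_q / n), NA_real_)
  }
  data.frame(
    section_id = section_id,
    quartile = paste0("Q", 1:4),
    edm_max_um = edm_max_um,
    n_pos = n_pos_q, n_neg = n_neg_q,
    pct_pos = pct_pos_q,
    ratio_pos = ratio_pos,
    ratio_neg = ratio_neg,
    stringsAsFactors = FALSE
  )
}

#' Test depth uniformity across quartiles (ANOVA + Tukey on ratios)
#'
#' Per population (positive/negative), one-way ANOVA across the four
#' quartiles on per-animal mean enrichment ratios. Animals with an empty
#' quartile (missing ratio) are excluded with a warning.
#'
#' @param profiles data.frame of quartile profiles with an `animal_id` column
#'   (rbind of [quartile_profile()] outputs, possibly several sections per
#'   animal; sections are averaged within animal first)
#' @return list with elements `pos` and `neg`, each a [compare_groups()] report
#' @export
test_uniformity <- function(profiles) {
  if (!"animal_id" %in% names(profiles)) stopf("profiles need an animal_id column")
  one <- function(col) {
    agg <- stats::aggregate(profiles[[col]],
                            by = list(animal_id = profiles$animal_id, quartile = profiles$quartile),
                            FUN = mean)
    bad <- unique(agg$animal_id[!is.finite(agg$x)])
    if (length(bad)) {
      warnf("excluding animal(s) with empty quartile: %s", paste(bad, collapse = ", "))
      agg <- agg[!agg$animal_id %in% bad, ]
    }
    if (length(unique(agg$animal_id)) < 2L) stopf("need >= 2 animals with complete profiles")
    vals <- split(agg$x, agg$quartile)
    compare_groups(vals)
  }
  list(pos = one("ratio_pos"), neg = one("ratio_neg"))
}
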