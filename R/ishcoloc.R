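# Duplex ISH quantification: stain vectors estimated from single-colour
# controls, optical-density colour deconvolution, aggregation on a 50 x 50
# um grid inside the tendon ROI, and Spearman rank correlation of the
# per-unit stain intensities.

od_transform <- function(rgb, background_white) {
  I0 <- rep(background_white, length.out = 3L)
  d <- dim(rgb)
  od <- array(0, d)
  for (cch in 1:3) {
    od[, , cch] <- -log10(pmin(pmax(rgb[, , cch], 1), I0[cch]) / I0[cch])
  }
  od
}

#' Estimate stain optical-density vectors from single-colour controls
#'
#' Per control image, pixel optical densities are `-log10(clip(I, 1, I0) /
#' I0)` (the clip guards the log on 8-bit-scaled images); the stain vector is
#' the unit-normalized mean OD direction over pixels whose OD norm exceeds
#' `od_floor`. The three vectors are assembled column-wise (green stain, red
#' stain, counterstain).
#'
#' @param controls named list of RGB arrays: green, red, counterstain (the
#'   counterstain control may be omitted, in which case its vector is the
#'   normalized cross product of the two stain vectors)
#' @param background_white illumination level I0 (> 0, scalar or length 3)
#' @param od_floor minimum OD norm for a pixel to count as stained
#' @param cond_bound maximum acceptable matrix condition number
#' @return object of class `stain_matrix`: list with `M` (3x3, unit columns)
#'   and `cond`
#' @export
estimate_stain_vectors <- function(controls, background_white = 255,
                                   od_floor = 0.05, cond_bound = 50) {
  if (any(rep(background_white, length.out = 3L) <= 0)) stopf("background_white must be > 0")
  one <- function(rgb, name) {
    od <- od_transform(rgb, background_white)
    v <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
    nrm <- sqrt(rowSums(v^2))
    sel <- nrm > od_floor
    if (!any(sel)) stopf("control '%s' has no stained pixels above the OD floor", name)
    dir <- colMeans(v[sel, , drop = FALSE])
    dir / sqrt(sum(dir^2))
  }
  g <- one(controls$green, "green")
  r <- one(controls$red, "red")
  cs <- if (!is.null(controls$counterstain)) {
    one(controls$counterstain, "counterstain")
  } else {
    x <- c(g[2] * r[3] - g[3] * r[2], g[3] * r[1] - g[1] * r[3], g[1] * r[2] - g[2] * r[1])
    x <- abs(x)  # OD components are non-negative
    x / sqrt(sum(x^2))
  }
  M <- cbind(green = g, red = r, counterstain = cs)
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > cond_bound) {
    stopf("stain vectors are near-collinear (condition number %.3g > %.3g)", cond, cond_bound)
  }
  structure(list(M = M, cond = cond), class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("stain_matrix (condition number", format(x$cond, digits = 4), ")\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Colour-deconvolve an RGB image into stain-amount rasters
#'
#' Per pixel, `A = M^-1 OD`; negative amounts are clipped to zero. Larger
#' output values mean stronger staining (the OD representation is already
#' "inverted" relative to brightfield intensity).
#'
#' @param rgb RGB array (nx x ny x 3)
#' @param stain_matrix a `stain_matrix` (or bare 3x3 matrix with unit columns)
#' @param background_white illumination level I0
#' @return named list of matrices: csf1r (green stain), csf1 (red stain),
#'   counterstain
#' @export
deconvolve <- function(rgb, stain_matrix, background_white = 255) {
  M <- if (inherits(stain_matrix, "stain_matrix")) stain_matrix$M else stain_matrix
  Minv <- tryCatch(solve(M), error = function(e) stopf("stain matrix is singular"))
  od <- od_transform(rgb, background_white)
  d <- dim(rgb)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  A <- Minv %*% odm
  # clip negatives and snap sub-numerical-noise amounts to exact zero, so
  # unstained pixels are structural zeros rather than rank-scrambling jitter
  A[A < 1e-9 * max(abs(A))] <- 0
  list(
    csf1r = matrix(A[1, ], d[1], d[2]),
    csf1 = matrix(A[2, ], d[1], d[2]),
    counterstain = matrix(A[3, ], d[1], d[2])
  )
}

#' Aggregate channel intensities on a physical grid inside the ROI
#'
#' Axis-aligned square units of `unit_um` (default 50 um) anchored at the
#' ROI bounding-box origin. A unit is included iff at least `min_coverage`
#' of its pixels fall inside the ROI polygon; per-unit means are computed
#' over in-ROI pixels only.
#'
#' @param channels named list of matrices (e.g. deconvolved stains + hoechst)
#' @param roi_polygon tendon region of interest
#' @param pixel_size_um calibration
#' @param unit_um grid unit edge length (physical)
#' @param min_coverage minimum in-ROI pixel fraction for unit inclusion
#' @return data.frame: unit_row, unit_col, area_px, and `mean_<channel>`
#' @export
grid_intensities <- function(channels, roi_polygon, pixel_size_um,
                             unit_um = 50, min_coverage = 0.5) {
  if (!polygon_is_simple(roi_polygon)) stopf("ROI polygon is not simple")
  d <- dim(channels[[1]])
  nx <- d[1]; ny <- d[2]
  pc <- pixel_centers(nx, ny, pixel_size_um)
  x0 <- min(roi_polygon$x); y0 <- min(roi_polygon$y)
  ux <- floor((pc$x - x0) / unit_um)
  uy <- floor((pc$y - y0) / unit_um)
  inb <- outer(ux >= 0, uy >= 0, "&")
  xs <- rep(pc$x, times = ny); ys <- rep(pc$y, each = nx)
  in_roi <- matrix(points_in_polygon(xs, ys, roi_polygon), nx, ny)
  sel <- which(inb & in_roi)
  if (length(sel) == 0L) stopf("ROI polygon covers no pixels")
  i <- ((sel - 1L) %% nx) + 1L
  j <- ((sel - 1L) %/% nx) + 1L
  key <- ux[i] * 1e6 + uy[j]
  fk <- factor(key)
  area_px <- as.vector(table(fk))
  per_unit_px <- (unit_um / pixel_size_um)^2
  out <- data.frame(
    unit_col = as.numeric(levels(fk)) %/% 1e6,
    unit_row = as.numeric(levels(fk)) %% 1e6,
    area_px = area_px
  )
  for (ch in names(channels)) {
    s <- rowsum(as.numeric(channels[[ch]][sel]), fk)[, 1]
    out[[paste0("mean_", ch)]] <- s / area_px
  }
  keep <- out$area_px / per_unit_px >= min_coverage
  if (!any(keep)) {
    warnf("ROI smaller than one %g um unit; returning the single best-covered unit", unit_um)
    keep <- out$area_px == max(out$area_px)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$unit_row, out$unit_col), , drop = FALSE]
}

#' Spearman rank correlation of two grid channels
#'
#' Tie-corrected ranks; exact p-value for n <= 10 untied units, asymptotic
#' otherwise. A constant channel has no defined rank correlation and yields
#' `NA`.
#'
#' @param table [grid_intensities()] output
#' @param channel_a,channel_b channel names (without the `mean_` prefix)
#' @return list: rho, p, n_units
#' @export
coloc_spearman <- function(table, channel_a, channel_b) {
  a <- table[[paste0("mean_", channel_a)]]
  b <- table[[paste0("mean_", channel_b)]]
  if (is.null(a) || is.null(b)) stopf("channel absent from grid table")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 5L) stopf("need >= 5 grid units")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n_units = n))
  }
  ties <- anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = (n <= 10L) && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n_units = n)
}

#' Aggregate per-section Spearman results
#'
#' Arithmetic mean of per-section rho and of per-section p, matching the
#' "mean rho / mean p" convention used for reporting these correlations.
#'
#' @param results list of [coloc_spearman()] outputs
#' @return list: mean_rho, mean_p, n_sections
#' @export
aggregate_spearman <- function(results) {
  rho <- vapply(results, function(r) r$rho, numeric(1))
  p <- vapply(results, function(r) r$p, numeric(1))
  list(mean_rho = mean(rho, na.rm = TRUE), mean_p = mean(p, na.rm = TRUE),
       n_sections = sum(is.finite(rho)))
}
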