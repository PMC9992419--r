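# Synthetic duplex chromogenic ISH generator. Brightfield RGB is formed by
# Beer-Lambert mixing of three stains (green probe = Csf1r, red probe =
# Csf1, nuclear counterstain) so that colour deconvolution with the
# generating matrix is exact in the noise-free limit. A tunable parameter
# controls how often each macrophage is placed adjacent to a Csf1-high
# fibroblast, emulating the observation that only a subset of fibroblasts
# express Csf1 and that macrophages sit next to them.

default_stain_od_matrix <- function() {
  cols <- cbind(
    green       = c(0.68, 0.12, 0.72),  # green chromogen absorbs red + blue
    red         = c(0.10, 0.76, 0.64),  # red chromogen absorbs green + blue
    counterstain = c(0.62, 0.70, 0.35)  # nuclear counterstain
  )
  sweep(cols, 2, sqrt(colSums(cols^2)), "/")
}

#' Specification of a synthetic duplex ISH section
#'
#' @inheritParams section_spec
#' @param csf1_high_fraction fraction of fibroblasts expressing Csf1
#' @param coloc_kappa probability that each macrophage is placed within
#'   `adjacency_radius_um` of a Csf1-high fibroblast (0 = uniform placement)
#' @param adjacency_radius_um adjacency radius for colocalized placement
#' @param puncta_per_expression_unit mean puncta per unit expression
#' @param punctum_od,punctum_radius_um,punctum_spread_um optical density,
#'   radius and spatial spread of individual puncta
#' @param counterstain_od optical-density amplitude of nuclear counterstain
#' @param stain_od_matrix 3x3 matrix of unit-norm optical-density column
#'   vectors (green stain, red stain, counterstain)
#' @param background_white RGB illumination level I0 (scalar or length 3)
#' @param rgb_noise_sd additive RGB noise SD (0 = noise-free forward model)
#' @return object of class `ish_spec`
#' @export
ish_spec <- function(width_um = 800, height_um = 450, pixel_size_um = 0.5,
                     fascicle_polygon = NULL,
                     anterior_polyline = NULL, posterior_polyline = NULL,
                     cell_density_per_mm2 = 2200,
                     macrophage_fraction = 0.06,
                     csf1_high_fraction = 0.30,
                     coloc_kappa = 0.9,
                     adjacency_radius_um = 15,
                     puncta_per_expression_unit = 12,
                     punctum_od = 0.25, punctum_radius_um = 1.2, punctum_spread_um = 2.5,
                     counterstain_od = 0.35,
                     nucleus_major_um = 8, nucleus_minor_um = 4, orientation_jitter_deg = 8,
                     stain_od_matrix = default_stain_od_matrix(),
                     background_white = 255,
                     rgb_noise_sd = 0,
                     row_pitch_um = 8, along_row_pitch_um = 8, lateral_jitter_um = 2,
                     seed = 1L) {
  if (is.null(fascicle_polygon)) {
    band <- fascicle_band_polygon(width_um - 160, height_um - 160, x0 = 80, y0 = 80)
    fascicle_polygon <- band$polygon
    anterior_polyline <- anterior_polyline %||% band$anterior
    posterior_polyline <- posterior_polyline %||% band$posterior
  }
  if (exists("band", inherits = FALSE)) rm(band)
  spec <- structure(as.list(environment()), class = "ish_spec")
  spec$peritenon_band_um <- 0
  validate_ish_spec(spec)
  spec
}

validate_ish_spec <- function(spec) {
  if (spec$coloc_kappa < 0 || spec$coloc_kappa > 1) stopf("coloc_kappa must lie in [0, 1]")
  if (spec$csf1_high_fraction < 0 || spec$csf1_high_fraction > 1) {
    stopf("csf1_high_fraction must lie in [0, 1]")
  }
  M <- spec$stain_od_matrix
  if (!is.matrix(M) || !all(dim(M) == 3L)) stopf("stain_od_matrix must be 3x3")
  if (any(abs(sqrt(colSums(M^2)) - 1) > 1e-8)) {
    stopf("stain_od_matrix columns must have unit Euclidean norm")
  }
  if (!polygon_is_simple(spec$fascicle_polygon)) stopf("fascicle_polygon is not simple")
  invisible(spec)
}

paint_disks <- function(m, x, y, r, amp, psz) {
  nx <- nrow(m); ny <- ncol(m)
  for (k in seq_along(x)) {
    idx <- ellipse_pixels(x[k], y[k], r, r, 0, nx, ny, psz)
    if (length(idx)) m[idx] <- m[idx] + amp
  }
  m
}

#' Generate a synthetic duplex ISH image
#'
#' Cells are placed inside the fascicle: fibroblasts (a `csf1_high_fraction`
#' subset expressing Csf1) on the linear-array lattice, macrophages either
#' adjacent to a random Csf1-high fibroblast (probability `coloc_kappa`) or
#' uniformly. Each expressing cell sheds Poisson-many puncta (small optical-
#' density disks); all nuclei receive counterstain. RGB is formed per pixel
#' as `I_c = I0_c * 10^-(M A)_c`.
#'
#' @param spec ish_spec
#' @return list: `rgb` (array nx x ny x 3, float), `amounts` (named list of
#'   the three true stain-amount rasters), `truth` (per-cell table with class,
#'   position, csf1_high flag, stain load), `stain_matrix`, `background_white`
#' @export
generate_duplex_ish <- function(spec) {
  validate_ish_spec(spec)
  nx <- round(spec$width_um / spec$pixel_size_um)
  ny <- round(spec$height_um / spec$pixel_size_um)
  psz <- spec$pixel_size_um
  I0 <- rep(spec$background_white, length.out = 3L)

  with_seed(spec$seed, {
    area_mm2 <- polygon_area(spec$fascicle_polygon) / 1e6
    n <- rpois(1L, spec$cell_density_per_mm2 * area_mm2)
    is_mac <- rbinom(n, 1L, spec$macrophage_fraction) == 1L
    n_mac <- sum(is_mac); n_fib <- n - n_mac
    cand <- placement_candidates(spec)
    inside <- points_in_polygon(cand$x, cand$y, spec$fascicle_polygon)
    cand <- cand[inside, , drop = FALSE]
    if (n > nrow(cand)) stopf("cell density exceeds lattice capacity")
    pick <- sample.int(nrow(cand), n)
    fib_idx <- pick[seq_len(n_fib)]
    fx <- cand$x[fib_idx]; fy <- cand$y[fib_idx]
    csf1_high <- rbinom(n_fib, 1L, spec$csf1_high_fraction) == 1L

    # macrophage placement: adjacent to a Csf1-high fibroblast w.p. kappa
    mx <- cand$x[pick[n_fib + seq_len(n_mac)]]
    my <- cand$y[pick[n_fib + seq_len(n_mac)]]
    hi <- which(csf1_high)
    if (n_mac > 0 && length(hi) > 0 && spec$coloc_kappa > 0) {
      adjacent <- runif(n_mac) < spec$coloc_kappa
      for (k in which(adjacent)) {
        for (try in 1:25) {
          j <- hi[sample.int(length(hi), 1L)]
          r <- runif(1L, 2, spec$adjacency_radius_um)
          th <- runif(1L, 0, 2 * pi)
          px <- fx[j] + r * cos(th); py <- fy[j] + r * sin(th)
          if (points_in_polygon(px, py, spec$fascicle_polygon)) {
            mx[k] <- px; my[k] <- py
            break
          }
        }
      }
    }

    x <- c(fx, mx); y <- c(fy, my)
    cls <- rep(c("fibroblast", "macrophage"), c(n_fib, n_mac))
    high <- c(csf1_high, rep(FALSE, n_mac))
    theta <- rnorm(n, 0, spec$orientation_jitter_deg)

    A <- list(
      csf1r = matrix(0, nx, ny),
      csf1 = matrix(0, nx, ny),
      counterstain = matrix(0, nx, ny)
    )
    load <- numeric(n)
    shed <- function(target, cx, cy) {
      k <- rpois(1L, spec$puncta_per_expression_unit)
      if (k > 0) {
        ox <- rnorm(k, 0, spec$punctum_spread_um)
        oy <- rnorm(k, 0, spec$punctum_spread_um)
        A[[target]] <<- paint_disks(A[[target]], cx + ox, cy + oy,
                                    spec$punctum_radius_um, spec$punctum_od, psz)
      }
      k * spec$punctum_od
    }
    for (k in seq_len(n)) {
      if (cls[k] == "macrophage") {
        load[k] <- shed("csf1r", x[k], y[k])
      } else if (high[k]) {
        load[k] <- shed("csf1", x[k], y[k])
      }
    }
    a <- spec$nucleus_major_um / 2; b <- spec$nucleus_minor_um / 2
    for (k in seq_len(n)) {
      idx <- ellipse_pixels(x[k], y[k], a, b, theta[k], nx, ny, psz)
      if (length(idx)) A$counterstain[idx] <- A$counterstain[idx] + spec$counterstain_od
    }

    M <- spec$stain_od_matrix
    rgb <- array(0, dim = c(nx, ny, 3L))
    for (cch in 1:3) {
      od <- M[cch, 1] * A$csf1r + M[cch, 2] * A$csf1 + M[cch, 3] * A$counterstain
      rgb[, , cch] <- I0[cch] * 10^(-od)
      if (spec$rgb_noise_sd > 0) {
        rgb[, , cch] <- pmin(pmax(rgb[, , cch] + rnorm(nx * ny, 0, spec$rgb_noise_sd), 0), I0[cch])
      }
    }
    truth <- data.frame(
      cell_id = seq_len(n), x_um = x, y_um = y, class = cls,
      csf1_high = high, stain_load = load, stringsAsFactors = FALSE
    )
    list(rgb = rgb, amounts = A, truth = truth,
         stain_matrix = M, background_white = I0)
  })
}

#' Generate the three single-colour control images for a spec
#'
#' Same forward model restricted to one stain at a time (green probe only,
#' red probe only, counterstain only), as used on control sections to
#' estimate the deconvolution baselines.
#'
#' @param spec ish_spec
#' @return named list of RGB arrays: green, red, counterstain
#' @export
generate_ish_controls <- function(spec) {
  mk <- function(drop_to, dseed) {
    s <- spec
    s$seed <- spec$seed + dseed
    if (drop_to == "green") {       # macrophage Csf1r puncta only
      s$csf1_high_fraction <- 0
      s$counterstain_od <- 0
    } else if (drop_to == "red") {  # Csf1 puncta only
      s$macrophage_fraction <- 0
      s$counterstain_od <- 0
    } else {                         # counterstain only
      s$macrophage_fraction <- 0
      s$csf1_high_fraction <- 0
    }
    generate_duplex_ish(s)$rgb
  }
  list(green = mk("green", 1L), red = mk("red", 2L), counterstain = mk("counterstain", 3L))
}
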