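# Synthetic tendon-section generator. Emulates sagittal cryosections of
# postnatal mouse tendon: an elongated fascicle bordered by a cell-dense
# peritenon band, nuclei arranged in linear arrays with elongated shapes, a
# sparse GFP+ macrophage population, and (optionally) EdU labelling with
# population-specific rates. Every cell carries ground truth so that the
# measurement stages can be tested by parameter recovery.

#' Build an elongated fascicle polygon with anterior/posterior surfaces
#'
#' The fascicle is modelled as a horizontal band with gently undulating
#' surfaces (so the distance map is non-trivial). Returns the closed polygon
#' together with the two open surface polylines used for depth mapping.
#'
#' @param length_um,thickness_um band extent
#' @param x0,y0 position of the band's top-left corner (um)
#' @param wave_amp_um amplitude of the surface undulation
#' @param wave_periods number of undulation periods along the band
#' @param n_vertices vertices per surface
#' @return list with `polygon`, `anterior`, `posterior` data.frames (x, y)
#' @export
fascicle_band_polygon <- function(length_um, thickness_um, x0 = 0, y0 = 0,
                                  wave_amp_um = 8, wave_periods = 2, n_vertices = 25) {
  xs <- seq(x0, x0 + length_um, length.out = n_vertices)
  ph <- 2 * pi * wave_periods * (xs - x0) / length_um
  top <- data.frame(x = xs, y = y0 + wave_amp_um * sin(ph))
  bot <- data.frame(x = xs, y = y0 + thickness_um + wave_amp_um * sin(ph + pi / 3))
  poly <- rbind(top, bot[rev(seq_len(n_vertices)), ])
  list(polygon = poly, anterior = top, posterior = bot)
}

default_channel_models <- function() {
  list(
    fibroblast = list(hoechst = c(mean = 180, sd = 15), gfp = c(mean = 8, sd = 4)),
    macrophage = list(hoechst = c(mean = 180, sd = 15), gfp = c(mean = 180, sd = 20))
  )
}

#' Specification of a synthetic tendon section
#'
#' Defaults are free parameters of the generator (the study images carry no
#' per-nucleus intensity statistics); the packaged [preset()]s override the
#' measured quantities (macrophage fraction, EdU rates, density, geometry).
#'
#' @param width_um,height_um physical image extent
#' @param pixel_size_um micrometres per pixel
#' @param fascicle_polygon simple closed polygon (data.frame x, y in um)
#' @param anterior_polyline,posterior_polyline tendon surface polylines; when
#'   `NULL` they are taken from the polygon's top and bottom vertex chains
#' @param peritenon_band_um width of the out-of-ROI cell band around the fascicle
#' @param cell_density_per_mm2 target total cell density inside the fascicle
#' @param macrophage_fraction proportion of fascicle cells that are macrophages
#' @param edu_fraction_macrophage,edu_fraction_fibroblast EdU labelling
#'   probabilities; an EdU channel is rendered iff either is > 0
#' @param depth_bias macrophage placement bias: 0 = uniform across depth, > 0 =
#'   surface-biased (weight `exp(-depth_bias * depth / max depth)`); fibroblast
#'   placement is always depth-uniform
#' @param nucleus_major_um,nucleus_minor_um,orientation_jitter_deg nucleus geometry
#' @param channel_models per class x channel intensity mean/sd (see
#'   `tenomac:::default_channel_models`)
#' @param edu_model intensity models for EdU-labelled / unlabelled nuclei
#' @param channel_background additive background level per channel
#' @param background_sd additive Gaussian pixel noise SD
#' @param peritenon_density_per_mm2,peritenon_macrophage_fraction composition
#'   of the peritenon band (macrophage-rich, as in the peritenon surrounding
#'   the fascicle)
#' @param row_pitch_um,along_row_pitch_um,lateral_jitter_um linear-array
#'   placement lattice (rows parallel to the tendon axis with jitter)
#' @param seed integer seed; generation is bit-reproducible given the spec
#' @return object of class `section_spec`
#' @export
section_spec <- function(width_um = 800, height_um = 400, pixel_size_um = 0.5,
                         fascicle_polygon = NULL,
                         anterior_polyline = NULL, posterior_polyline = NULL,
                         peritenon_band_um = 40,
                         cell_density_per_mm2 = 2000,
                         macrophage_fraction = 0.05,
                         edu_fraction_macrophage = 0,
                         edu_fraction_fibroblast = 0,
                         depth_bias = 0,
                         nucleus_major_um = 8, nucleus_minor_um = 4,
                         orientation_jitter_deg = 8,
                         channel_models = default_channel_models(),
                         edu_model = list(pos = c(mean = 200, sd = 15), neg = c(mean = 8, sd = 4)),
                         channel_background = c(hoechst = 6, gfp = 4, edu = 4),
                         background_sd = 6,
                         peritenon_density_per_mm2 = NULL,
                         peritenon_macrophage_fraction = 0.3,
                         row_pitch_um = 8, along_row_pitch_um = 8, lateral_jitter_um = 2,
                         seed = 1L) {
  if (is.null(fascicle_polygon)) {
    band <- fascicle_band_polygon(width_um - 160, height_um - 200, x0 = 80, y0 = 100)
    fascicle_polygon <- band$polygon
    anterior_polyline <- anterior_polyline %||% band$anterior
    posterior_polyline <- posterior_polyline %||% band$posterior
  }
  if (is.null(anterior_polyline) || is.null(posterior_polyline)) {
    stopf("anterior/posterior surface polylines are required with a custom fascicle polygon")
  }
  if (exists("band", inherits = FALSE)) rm(band)
  spec <- structure(as.list(environment()), class = "section_spec")
  spec$peritenon_density_per_mm2 <- peritenon_density_per_mm2 %||% (1.5 * cell_density_per_mm2)
  validate_section_spec(spec)
  spec
}

validate_section_spec <- function(spec) {
  fr <- c(spec$macrophage_fraction, spec$edu_fraction_macrophage,
          spec$edu_fraction_fibroblast, spec$peritenon_macrophage_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (spec$pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (spec$cell_density_per_mm2 <= 0) stopf("cell density must be > 0")
  if (spec$depth_bias < 0) stopf("depth_bias must be >= 0")
  if (!polygon_is_simple(spec$fascicle_polygon)) {
    stopf("fascicle_polygon is not a simple polygon")
  }
  if (spec$nucleus_minor_um / spec$pixel_size_um < 2) {
    stopf("pixel size %.3g um makes the nucleus minor axis < 2 px (unresolvable)", spec$pixel_size_um)
  }
  invisible(spec)
}

# Candidate placement lattice: axis-parallel rows with lateral jitter
# (reproduces the linear-array texture of tendon without modelling collagen).
# Jitter draws are made for the full lattice before any selection so that
# the sampling recipe is reproducible from its documented order of draws.
placement_candidates <- function(spec) {
  xr <- range(spec$fascicle_polygon$x)
  yr <- range(spec$fascicle_polygon$y)
  b <- spec$peritenon_band_um
  gx <- seq(xr[1] - b + spec$along_row_pitch_um / 2, xr[2] + b, by = spec$along_row_pitch_um)
  gy <- seq(yr[1] - b + spec$row_pitch_um / 2, yr[2] + b, by = spec$row_pitch_um)
  cx <- rep(gx, times = length(gy))
  cy <- rep(gy, each = length(gx))
  n <- length(cx)
  jx <- runif(n, -spec$lateral_jitter_um, spec$lateral_jitter_um)
  jy <- runif(n, -spec$lateral_jitter_um / 2, spec$lateral_jitter_um / 2)
  x <- cx + jx
  y <- cy + jy
  # clamp to the image frame with half-nucleus margin
  m <- spec$nucleus_major_um / 2 + 1
  keep <- x > m & x < spec$width_um - m & y > m & y < spec$height_um - m
  data.frame(x = x[keep], y = y[keep])
}

#' Draw the ground-truth cell table for a section spec
#'
#' Sampling recipe (all draws under `with_seed(spec$seed)` in this order):
#' 1. `n_fascicle ~ Poisson(density * fascicle area in mm^2)`
#' 2. per-cell class `~ Bernoulli(macrophage_fraction)`
#' 3. lattice jitter (x then y, uniform) over the full placement lattice
#' 4. fascicle positions: macrophage positions are sampled without
#'    replacement from the in-polygon candidates weighted by
#'    `exp(-depth_bias * depth / max depth)` (uniform when `depth_bias = 0`);
#'    fibroblast positions are then sampled uniformly from the remaining
#'    candidates, so only the macrophage population is depth-biased
#' 5. `n_peritenon ~ Poisson(peritenon density * band area)`; band candidates
#'    sampled uniformly; peritenon class draws
#' 6. EdU labels `~ Bernoulli(rate(class))` (fascicle then peritenon)
#' 7. nucleus orientations `~ Normal(0, orientation_jitter_deg)`
#'
#' @param spec section_spec
#' @return data.frame: cell_id, x_um, y_um, class, edu_label, true_depth_um,
#'   compartment (fascicle/peritenon)
#' @export
sample_cells <- function(spec) {
  validate_section_spec(spec)
  with_seed(spec$seed, {
    area_mm2 <- polygon_area(spec$fascicle_polygon) / 1e6
    n_fas <- rpois(1L, spec$cell_density_per_mm2 * area_mm2)
    is_mac <- rbinom(n_fas, 1L, spec$macrophage_fraction) == 1L
    cand <- placement_candidates(spec)
    inside <- points_in_polygon(cand$x, cand$y, spec$fascicle_polygon)
    fas_cand <- cand[inside, , drop = FALSE]
    if (n_fas > nrow(fas_cand)) {
      stopf("cell density %.0f/mm2 exceeds the placement lattice capacity for this geometry",
            spec$cell_density_per_mm2)
    }
    w <- rep(1, nrow(fas_cand))
    if (spec$depth_bias > 0) {
      d <- pmin(dist_to_polyline(fas_cand$x, fas_cand$y, spec$anterior_polyline),
                dist_to_polyline(fas_cand$x, fas_cand$y, spec$posterior_polyline))
      w <- exp(-spec$depth_bias * d / max(d))
    }
    n_mac_fas <- sum(is_mac)
    pick_mac <- sample.int(nrow(fas_cand), n_mac_fas, prob = w)
    rest <- setdiff(seq_len(nrow(fas_cand)), pick_mac)
    pick_fib <- if (n_fas - n_mac_fas > 0) rest[sample.int(length(rest), n_fas - n_mac_fas)] else integer(0)
    pick <- integer(n_fas)
    pick[is_mac] <- pick_mac
    pick[!is_mac] <- pick_fib
    fx <- fas_cand$x[pick]; fy <- fas_cand$y[pick]

    # peritenon band: outside the fascicle, within band distance of its boundary
    ring <- rbind(spec$fascicle_polygon, spec$fascicle_polygon[1L, ])
    out_cand <- cand[!inside, , drop = FALSE]
    near <- dist_to_polyline(out_cand$x, out_cand$y, ring) <= spec$peritenon_band_um
    peri_cand <- out_cand[near, , drop = FALSE]
    band_area_mm2 <- nrow(peri_cand) * spec$row_pitch_um * spec$along_row_pitch_um / 1e6
    n_peri <- min(rpois(1L, spec$peritenon_density_per_mm2 * band_area_mm2), nrow(peri_cand))
    ppick <- if (n_peri > 0) sample.int(nrow(peri_cand), n_peri) else integer(0)
    peri_mac <- rbinom(n_peri, 1L, spec$peritenon_macrophage_fraction) == 1L

    cls <- c(ifelse(is_mac, "macrophage", "fibroblast"),
             ifelse(peri_mac, "macrophage", "fibroblast"))
    x <- c(fx, peri_cand$x[ppick])
    y <- c(fy, peri_cand$y[ppick])
    p_edu <- ifelse(cls == "macrophage", spec$edu_fraction_macrophage, spec$edu_fraction_fibroblast)
    edu <- rbinom(length(x), 1L, p_edu) == 1L
    depth <- pmin(dist_to_polyline(x, y, spec$anterior_polyline),
                  dist_to_polyline(x, y, spec$posterior_polyline))
    data.frame(
      cell_id = seq_along(x),
      x_um = x, y_um = y,
      class = cls,
      edu_label = edu,
      true_depth_um = depth,
      compartment = rep(c("fascicle", "peritenon"), c(n_fas, n_peri)),
      orientation_deg = rnorm(length(x), 0, spec$orientation_jitter_deg),
      stringsAsFactors = FALSE
    )
  })
}

# Flat pixel indices of an ellipse (centre um, half-axes um, angle deg).
ellipse_pixels <- function(cx, cy, a, b, theta_deg, nx, ny, psz) {
  th <- theta_deg * pi / 180
  ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  i0 <- max(1L, floor((cx - ex) / psz)); i1 <- min(nx, ceiling((cx + ex) / psz) + 1L)
  j0 <- max(1L, floor((cy - ey) / psz)); j1 <- min(ny, ceiling((cy + ey) / psz) + 1L)
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  px <- (rep(ii, times = length(jj)) - 0.5) * psz - cx
  py <- (rep(jj, each = length(ii)) - 0.5) * psz - cy
  u <- (px * cos(th) + py * sin(th)) / a
  v <- (-px * sin(th) + py * cos(th)) / b
  keep <- (u * u + v * v) <= 1
  idx <- rep(ii, times = length(jj)) + (rep(jj, each = length(ii)) - 1L) * nx
  idx[keep]
}

#' Generate a synthetic multi-channel tendon section
#'
#' Renders every ground-truth cell as a filled ellipse (Hoechst in all nuclei;
#' GFP bright in macrophage nuclei; EdU bright in labelled nuclei, rendered at
#' fixed high SNR), adds Gaussian background noise, and quantizes each channel
#' to 16-bit integer levels as the acquiring scanner would. The EdU channel is
#' present iff either EdU labelling fraction is positive.
#'
#' @param spec section_spec
#' @return list with `image` (a [section_image] whose ROIs carry the fascicle
#'   polygon and the two surface polylines), `truth` (ground-truth cell
#'   table), and `truth_labels` (integer raster of rendered nucleus ids)
#' @export
generate_section <- function(spec) {
  validate_section_spec(spec)
  truth <- sample_cells(spec)
  nx <- round(spec$width_um / spec$pixel_size_um)
  ny <- round(spec$height_um / spec$pixel_size_um)
  psz <- spec$pixel_size_um
  has_edu <- spec$edu_fraction_macrophage > 0 || spec$edu_fraction_fibroblast > 0
  ch_names <- c("hoechst", "gfp", if (has_edu) "edu")

  with_seed(spec$seed + 101L, {
    n <- nrow(truth)
    pix <- vector("list", n)
    a <- spec$nucleus_major_um / 2
    b <- spec$nucleus_minor_um / 2
    for (k in seq_len(n)) {
      pix[[k]] <- ellipse_pixels(truth$x_um[k], truth$y_um[k], a, b,
                                 truth$orientation_deg[k], nx, ny, psz)
    }
    labels <- matrix(0L, nx, ny)
    for (k in seq_len(n)) labels[pix[[k]]] <- k

    cell_value <- function(channel) {
      vapply(seq_len(n), function(k) {
        if (channel == "edu") {
          m <- if (truth$edu_label[k]) spec$edu_model$pos else spec$edu_model$neg
        } else {
          m <- spec$channel_models[[truth$class[k]]][[channel]]
        }
        max(0, rnorm(1L, m[["mean"]], m[["sd"]]))
      }, numeric(1))
    }
    channels <- lapply(ch_names, function(ch) {
      bg <- spec$channel_background[[ch]] %||% 4
      m <- matrix(bg + rnorm(nx * ny, 0, spec$background_sd), nx, ny)
      vals <- cell_value(ch)
      for (k in seq_len(n)) {
        id <- pix[[k]]
        if (length(id)) m[id] <- pmax(m[id], vals[k] + rnorm(length(id), 0, spec$background_sd / 2))
      }
      matrix(pmin(pmax(round(m), 0), 65535), nx, ny)
    })
    names(channels) <- ch_names

    img <- section_image(
      channels, psz,
      rois = list(
        polygons = list(fascicle = spec$fascicle_polygon),
        polylines = list(anterior = spec$anterior_polyline, posterior = spec$posterior_polyline)
      )
    )
    list(image = img, truth = truth, truth_labels = labels)
  })
}
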