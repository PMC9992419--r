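# Independent oracle implementations used to cross-check the package's
# geometry and statistics, plus small fixture builders. These deliberately
# re-derive results from first principles rather than calling the code paths
# they verify.

# Ray-casting point-in-polygon (even-odd rule), independent of mgcv.
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly$x[i]; yi <- poly$y[i]
      xj <- poly$x[j]; yj <- poly$y[j]
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Brute-force min distance from one point to every segment of the polylines.
oracle_seg_dist <- function(x, y, lines) {
  best <- Inf
  for (line in lines) {
    p <- as.matrix(line[, c("x", "y")])
    for (k in seq_len(nrow(p) - 1L)) {
      a <- p[k, ]; b <- p[k + 1L, ]
      d <- b - a
      L2 <- sum(d^2)
      t <- if (L2 == 0) 0 else min(1, max(0, sum((c(x, y) - a) * d) / L2))
      q <- a + t * d
      best <- min(best, sqrt(sum((c(x, y) - q)^2)))
    }
  }
  best
}

# Textbook one-way ANOVA F statistic from the definitional sums of squares.
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits.
oracle_mw_exact_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  splits <- utils::combn(n, length(a))
  u_all <- apply(splits, 2, function(ix) sum(seq_len(n)[ix]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small, fast section spec for unit tests (not a packaged study preset).
small_section_spec <- function(seed = 1L, ...) {
  geo <- fascicle_band_polygon(500, 200, x0 = 60, y0 = 80, wave_amp_um = 6)
  args <- utils::modifyList(
    list(
      width_um = 620, height_um = 360,
      fascicle_polygon = geo$polygon,
      anterior_polyline = geo$anterior, posterior_polyline = geo$posterior,
      cell_density_per_mm2 = 1500, macrophage_fraction = 0.08,
      seed = seed
    ),
    list(...)
  )
  do.call(section_spec, args)
}

# Section spec with widely separated nuclei (no touching pairs).
sparse_section_spec <- function(seed = 1L, ...) {
  small_section_spec(
    seed = seed,
    ...,
    cell_density_per_mm2 = 300,
    row_pitch_um = 20, along_row_pitch_um = 20, lateral_jitter_um = 1
  )
}

small_ish_spec <- function(seed = 1L, ...) {
  ish_spec(width_um = 500, height_um = 340, seed = seed, ...)
}

run_section_pipeline <- function(spec, gfp_threshold = 60, edu_threshold = 100, ...) {
  gen <- generate_section(spec)
  lab <- segment_nuclei(gen$image$channels$hoechst, spec$pixel_size_um, ...)
  r <- measure_nuclei(lab, gen$image$channels, spec$pixel_size_um)
  r <- classify_by_threshold(r, "gfp", gfp_threshold)
  if ("edu" %in% names(gen$image$channels)) r <- classify_by_threshold(r, "edu", edu_threshold)
  r <- flag_in_roi(r, spec$fascicle_polygon)
  list(gen = gen, labels = lab, records = r)
}

# Match detections to ground-truth centroids within a radius; returns F1.
detection_f1 <- function(records, truth, radius_um = 3) {
  if (nrow(records) == 0L || nrow(truth) == 0L) return(0)
  used <- rep(FALSE, nrow(records))
  tp <- 0L
  for (k in seq_len(nrow(truth))) {
    d <- sqrt((records$x_um - truth$x_um[k])^2 + (records$y_um - truth$y_um[k])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= radius_um) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  prec <- tp / nrow(records)
  rec <- tp / nrow(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Accessor for sample selection via the package-internal filter helper.
select_samples_acc <- function(em, f) {
  tenomac:::select_samples(em, population = f$population, tissue = f$tissue, age = f$age)
}
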