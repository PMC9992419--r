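phantom_lines <- function(y1 = 10.25, y2 = 110.25, x_max = 100) {
  list(anterior = data.frame(x = c(0.25, x_max), y = c(y1, y1)),
       posterior = data.frame(x = c(0.25, x_max), y = c(y2, y2)))
}

test_that("parallel-surface phantom: midline depth equals the half-gap exactly", {
  ln <- phantom_lines()
  edm <- build_edm(240, 260, ln$anterior, ln$posterior, 0.5)
  # pixel centred on a surface line has distance zero
  expect_equal(edm[100, 21], 0)
  expect_equal(edm[100, 221], 0)
  # midline pixel: exactly half the 100 um gap
  expect_equal(edm[100, 121], 50)
})

test_that("EDM matches brute-force point-to-segment distance within one pixel", {
  geo <- fascicle_band_polygon(400, 160, x0 = 40, y0 = 60, wave_amp_um = 10)
  psz <- 0.5
  edm <- build_edm(960, 560, geo$anterior, geo$posterior, psz)
  set.seed(21)
  ii <- sample(960, 200, replace = TRUE)
  jj <- sample(560, 200, replace = TRUE)
  surfaces <- list(geo$anterior, geo$posterior)
  for (k in seq_len(200)) {
    x <- (ii[k] - 0.5) * psz
    y <- (jj[k] - 0.5) * psz
    expect_lt(abs(edm[ii[k], jj[k]] - oracle_seg_dist(x, y, surfaces)), psz)
  }
})

test_that("EDM is symmetric under swapping the two surfaces and rejects out-of-bounds lines", {
  ln <- phantom_lines()
  e1 <- build_edm(240, 260, ln$anterior, ln$posterior, 0.5)
  e2 <- build_edm(240, 260, ln$posterior, ln$anterior, 0.5)
  expect_identical(e1, e2)
  far <- data.frame(x = c(0, 500), y = c(10, 10))
  expect_error(build_edm(240, 260, far, ln$posterior, 0.5), "outside the raster")
})

test_that("depth assignment: surface and midline nuclei, brute-force mask means", {
  # surfaces span the full raster width so the midline is the deepest point
  ln <- phantom_lines(x_max = 119.75)
  edm <- build_edm(240, 260, ln$anterior, ln$posterior, 0.5)
  lab <- matrix(0L, 240, 260)
  lab[100, 121] <- 1L   # point-like nucleus at the midline (deepest point)
  lab[100, 21] <- 2L    # nucleus on the anterior surface
  lab[50:52, 60:62] <- 3L
  rec <- data.frame(label = 1:3)
  rec <- assign_depth(rec, lab, edm)
  expect_equal(rec$d_norm[1], 1)
  expect_lt(rec$depth_um[2], 0.5 / 2)  # zero within half a pixel
  expect_equal(rec$depth_um[3], mean(edm[50:52, 60:62]), tolerance = 1e-12)
  expect_error(assign_depth(rec, lab, edm * 0), "EDM_max")
})

test_that("quartile binning and enrichment ratios on constructed uniformity", {
  rec <- data.frame(
    label = 1:8,
    d_norm = rep(c(0.1, 0.3, 0.6, 0.9), each = 2),
    gfp_pos = rep(c(TRUE, FALSE), 4)
  )
  pr <- quartile_profile(rec)
  expect_equal(pr$pct_pos, rep(50, 4))
  expect_equal(pr$ratio_pos, rep(1, 4))
  expect_equal(pr$ratio_neg, rep(1, 4))
  # closed upper edge: d_norm = 1 goes to Q4
  expect_identical(depth_quartile(1), 4L)
  expect_identical(depth_quartile(0.25), 2L)
  expect_error(quartile_profile(rec[0, ]), "empty")
})

test_that("count-weighted mean of enrichment ratios is exactly 1", {
  out <- run_section_pipeline(small_section_spec(seed = 14))
  spec <- small_section_spec(seed = 14)
  edm <- build_edm(nrow(out$labels), ncol(out$labels),
                   spec$anterior_polyline, spec$posterior_polyline, 0.5)
  r <- assign_depth(out$records, out$labels, edm,
                    roi_polygon = spec$fascicle_polygon, pixel_size_um = 0.5)
  pr <- quartile_profile(r[r$in_roi, ])
  nq <- pr$n_pos + pr$n_neg
  expect_equal(sum(nq * pr$ratio_pos) / sum(nq), 1, tolerance = 1e-12)
})

test_that("uniformity ANOVA: exact-null ratios give p = 1; F matches hand formula", {
  prof1 <- data.frame(animal_id = rep(c("a", "b", "c"), each = 4),
                      quartile = rep(paste0("Q", 1:4), 3),
                      ratio_pos = 1, ratio_neg = 1)
  rep0 <- test_uniformity(prof1)
  expect_equal(rep0$pos$anova$p, 1, tolerance = 1e-9)

  set.seed(31)
  prof2 <- prof1
  prof2$ratio_pos <- c(1.4, 1.1, 0.9, 0.6) [match(prof2$quartile, paste0("Q", 1:4))] + rnorm(12, 0, 0.05)
  rep1 <- test_uniformity(prof2)
  byq <- split(prof2$ratio_pos, prof2$quartile)
  expect_equal(rep1$pos$anova$F, oracle_anova_F(byq), tolerance = 1e-9)
})

test_that("surface-biased macrophage placement enriches Q1 over Q4", {
  profs <- do.call(rbind, lapply(1:4, function(s) {
    spec <- small_section_spec(seed = 500 + s, depth_bias = 5,
                               macrophage_fraction = 0.35)
    out <- run_section_pipeline(spec)
    edm <- build_edm(nrow(out$labels), ncol(out$labels),
                     spec$anterior_polyline, spec$posterior_polyline, 0.5)
    r <- assign_depth(out$records, out$labels, edm,
                      roi_polygon = spec$fascicle_polygon, pixel_size_um = 0.5)
    pr <- quartile_profile(r[r$in_roi, ], section_id = s)
    pr$animal_id <- paste0("A", s)
    pr
  }))
  q1 <- mean(profs$ratio_pos[profs$quartile == "Q1"])
  q4 <- mean(profs$ratio_pos[profs$quartile == "Q4"])
  expect_gt(q1, 1)
  expect_gt(q1, q4)
  rep1 <- test_uniformity(profs)
  expect_lt(rep1$pos$anova$p, 0.05)
})
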