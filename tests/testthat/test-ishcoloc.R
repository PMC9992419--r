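test_that("Beer-Lambert forward model basis cases", {
  spec <- small_ish_spec()
  M <- diag(3)
  # single pure pixel: A = (1, 0, 0), identity matrix, I0 = 255
  A <- c(1, 0, 0)
  I <- 255 * 10^(-(M %*% A))
  expect_equal(as.vector(I), c(25.5, 255, 255))
  # blank slide: zero amounts reproduce the illumination level
  blank <- small_ish_spec(cell_density_per_mm2 = 1e-9)
  gen <- generate_duplex_ish(blank)
  expect_equal(max(abs(gen$rgb - 255)), 0)
})

test_that("stain vectors are recovered from noise-free single-colour controls", {
  spec <- small_ish_spec(seed = 3)
  ctrl <- generate_ish_controls(spec)
  sm <- estimate_stain_vectors(ctrl, spec$background_white)
  expect_lt(max(abs(sm$M - spec$stain_od_matrix)), 1e-3)
  expect_error(estimate_stain_vectors(list(green = array(255, c(4, 4, 3)), red = ctrl$red,
                                           counterstain = ctrl$counterstain), 255),
               "no stained pixels")
  expect_error(estimate_stain_vectors(list(green = ctrl$green, red = ctrl$green,
                                           counterstain = ctrl$counterstain), 255),
               "near-collinear")
})

test_that("deconvolution inverts the noise-free forward model to 1e-6", {
  spec <- small_ish_spec(seed = 5)
  gen <- generate_duplex_ish(spec)
  ctrl <- generate_ish_controls(spec)
  sm <- estimate_stain_vectors(ctrl, spec$background_white)
  dec <- deconvolve(gen$rgb, sm, spec$background_white)
  rel <- function(a, b) max(abs(a - b)) / max(b)
  expect_lt(rel(dec$csf1r, gen$amounts$csf1r), 1e-6)
  expect_lt(rel(dec$csf1, gen$amounts$csf1), 1e-6)
  expect_lt(rel(dec$counterstain, gen$amounts$counterstain), 1e-6)
  # white pixels carry zero amounts; pure-stain pixels load exactly one raster
  white <- which(gen$amounts$csf1r + gen$amounts$csf1 + gen$amounts$counterstain == 0)
  expect_equal(max(dec$csf1r[white], dec$csf1[white], dec$counterstain[white]), 0,
               tolerance = 1e-9)
  expect_error(deconvolve(gen$rgb, matrix(1, 3, 3), 255), "singular")
})

test_that("grid aggregation: constant fields, brute-force means, edge-unit rule", {
  roi <- data.frame(x = c(0, 120, 120, 0), y = c(0, 0, 120, 120))
  const <- matrix(7.5, 300, 300)  # 150 x 150 um at 0.5 um/px
  tab <- grid_intensities(list(a = const), roi, 0.5, unit_um = 50)
  # 120 um square: 4 fully covered units, edge slivers (20 um) excluded
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$mean_a == 7.5))

  set.seed(9)
  noisy <- matrix(runif(300 * 300), 300, 300)
  tab2 <- grid_intensities(list(a = noisy), roi, 0.5, unit_um = 50)
  u <- tab2[2, ]
  ii <- which((floor(((seq_len(300) - 0.5) * 0.5) / 50)) == u$unit_col)
  jj <- which((floor(((seq_len(300) - 0.5) * 0.5) / 50)) == u$unit_row)
  px <- expand.grid(i = ii, j = jj)
  keep <- px$i * 0.5 - 0.25 <= 120 & px$j * 0.5 - 0.25 <= 120
  expect_equal(u$mean_a, mean(noisy[cbind(px$i, px$j)]), tolerance = 1e-12)

  tiny <- data.frame(x = c(0, 30, 30, 0), y = c(0, 0, 30, 30))
  expect_warning(t3 <- grid_intensities(list(a = const), tiny, 0.5, unit_um = 50),
                 "smaller than one")
  expect_identical(nrow(t3), 1L)
})

test_that("Spearman correlation: identity, antitone, and monotone-transform invariance", {
  tab <- data.frame(mean_a = c(3, 1, 4, 1.5, 9, 2.6), mean_b = c(3, 1, 4, 1.5, 9, 2.6))
  expect_equal(coloc_spearman(tab, "a", "b")$rho, 1)
  tab$mean_b <- -tab$mean_a
  expect_equal(coloc_spearman(tab, "a", "b")$rho, -1)
  tab$mean_b <- exp(tab$mean_a)  # strictly monotone transform
  expect_equal(coloc_spearman(tab, "a", "b")$rho, 1)
  tab$mean_b <- 5
  expect_true(is.na(coloc_spearman(tab, "a", "b")$rho))
  expect_error(coloc_spearman(tab[1:3, ], "a", "b"), ">= 5")
})

test_that("uniform macrophage placement matches a Monte-Carlo uniform null", {
  spec <- small_ish_spec(seed = 7, coloc_kappa = 0, macrophage_fraction = 0.15)
  gen <- generate_duplex_ish(spec)
  tr <- gen$truth
  hi <- tr[tr$csf1_high, ]
  mac <- tr[tr$class == "macrophage", ]
  nearest <- vapply(seq_len(nrow(mac)), function(k) {
    min(sqrt((hi$x_um - mac$x_um[k])^2 + (hi$y_um - mac$y_um[k])^2))
  }, 0)
  # Monte-Carlo null: uniform points in the same polygon
  set.seed(99)
  bb <- list(x = range(spec$fascicle_polygon$x), y = range(spec$fascicle_polygon$y))
  ux <- runif(5000, bb$x[1], bb$x[2]); uy <- runif(5000, bb$y[1], bb$y[2])
  ok <- points_in_polygon(ux, uy, spec$fascicle_polygon)
  ux <- ux[ok][1:1000]; uy <- uy[ok][1:1000]
  null_d <- vapply(seq_along(ux), function(k) {
    min(sqrt((hi$x_um - ux[k])^2 + (hi$y_um - uy[k])^2))
  }, 0)
  expect_gt(suppressWarnings(ks.test(nearest, null_d)$p.value), 0.05)
})

test_that("grid Spearman statistics are stable across pixel sizes", {
  rho <- vapply(c(0.5, 0.25), function(psz) {
    spec <- ish_spec(seed = 11, pixel_size_um = psz)
    gen <- generate_duplex_ish(spec)
    dec <- deconvolve(gen$rgb, spec$stain_od_matrix, spec$background_white)
    tab <- grid_intensities(list(csf1r = dec$csf1r, csf1 = dec$csf1),
                            spec$fascicle_polygon, psz)
    coloc_spearman(tab, "csf1r", "csf1")$rho
  }, 0)
  expect_lt(abs(rho[1] - rho[2]), 0.02)
})
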